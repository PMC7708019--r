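# Independent oracles, deliberately written from first principles and kept
# free of the package's implementation paths.

# Manhattan distance by explicit double loop.
naive_manhattan <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(m[i, ] - m[j, ]))
    }
  }
  d
}

# Complete-linkage agglomeration recomputed from the max-pairwise definition
# at every step (no Lance-Williams shortcut). Ties broken by the pair whose
# smallest member index is lowest, then the other cluster's smallest index.
# Returns per-step heights and the member sets fused at each step.
oracle_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  fused <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        m1 <- min(min(clusters[[i]]), min(clusters[[j]]))
        m2 <- max(min(clusters[[i]]), min(clusters[[j]]))
        key <- c(h, m1, m2)
        if (is.null(best) ||
            key[1] < best$key[1] ||
            (key[1] == best$key[1] &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(key = key, i = i, j = j)
        }
      }
    }
    heights[step] <- best$key[1]
    fused[[step]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$i]] <- fused[[step]]
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, fused = fused)
}

# Member sets created at each merge of a linkage_tree (hclust codes).
tree_member_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  resolve <- function(code) if (code < 0) -code else sets[[code]]
  for (s in seq_len(nrow(tree$merge))) {
    sets[[s]] <- sort(c(resolve(tree$merge[s, 1]),
                        resolve(tree$merge[s, 2])))
  }
  sets
}

# Adjusted Rand index straight from the contingency-table formula.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Canonical partition signature (invariant to label permutation).
partition_signature <- function(labels, ids) {
  groups <- split(sort(ids), labels[order(ids)])
  paste(sort(vapply(groups, paste, character(1), collapse = ",")),
        collapse = "|")
}
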