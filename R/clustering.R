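# Whole-brain Manhattan distances and complete-linkage (farthest-neighbor)
# agglomeration. The agglomeration is implemented from the max-pairwise
# definition via the Lance-Williams complete-linkage update, with a
# deterministic tie-break; the merge-height curve is the cluster-count
# diagnostic.

#' Manhattan distance matrix between subjects
#'
#' The imaging phenotypic distance between two subjects is the sum of
#' absolute voxel-wise differences of their (residualized) GM densities over
#' the brain mask. Metric axioms (symmetry, zero diagonal, non-negativity,
#' triangle inequality) are asserted on every build.
#'
#' @param vm A `voxel_matrix` (rows = subjects).
#' @param validate Assert the metric axioms (default `TRUE`).
#' @return A symmetric n x n matrix of class `vbm_dist` with subject ids as
#'   dimnames.
#' @examples
#' m <- rbind(a = c(0, 0, 0), b = c(1, -2, 0.5))
#' manhattan_distance_matrix(m)["a", "b"] # 3.5
#' @export
manhattan_distance_matrix <- function(vm, validate = TRUE) {
  m <- unclass(vm)
  stopifnot(is.matrix(m), nrow(m) >= 2)
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-finite value at subject ",
         rownames(m)[bad[1]] %||% bad[1], ", voxel ", bad[2])
  }
  d <- as.matrix(dist(m, method = "manhattan"))
  dimnames(d) <- list(rownames(m), rownames(m))
  if (validate) validate_distance_matrix(d)
  structure(d, class = c("vbm_dist", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_distance_matrix <- function(d, tol = 1e-9) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric")
  if (max(abs(diag(d))) > tol) stop("distance matrix has nonzero diagonal")
  if (min(d) < -tol) stop("distance matrix has negative entries")
  n <- nrow(d)
  for (k in seq_len(n)) {   # d[i,j] <= d[i,k] + d[k,j] for all i, j
    slack <- min(outer(d[, k], d[k, ], `+`) - d)
    if (slack < -tol * max(1, max(d))) {
      stop("triangle inequality violated through point ", k)
    }
  }
  invisible(d)
}

# Tie-break key for a candidate fusion {A, B}: (smallest member index over
# both clusters, smallest member index of the other cluster). Lower keys
# fuse first among equal linkage heights.
pair_key <- function(ma, mb) {
  a1 <- min(ma); b1 <- min(mb)
  c(min(a1, b1), max(a1, b1))
}

#' Complete-linkage agglomerative clustering
#'
#' Starts from n singleton clusters and repeatedly fuses the pair of
#' clusters A, B whose farthest-neighbor distance
#' `max(d(a, b) : a in A, b in B)` is smallest, recording each fusion
#' height. The working inter-cluster distance is maintained by the
#' Lance-Williams complete-linkage update `d(A+B, C) = max(d(A,C), d(B,C))`,
#' which is exactly the max-pairwise distance by induction. When several
#' candidate fusions share the minimal height, the pair whose smallest
#' member index is lowest (then the other cluster's smallest index) is
#' fused, making the tree deterministic.
#'
#' @param d A distance matrix ([manhattan_distance_matrix()] output, a
#'   symmetric matrix, or a `dist`).
#' @return An object of class `linkage_tree`: list with `merge` (an
#'   (n-1) x 2 matrix in `hclust` encoding: negative = singleton, positive =
#'   earlier merge), `height` (non-decreasing fusion heights), `size`
#'   (cluster size created by each merge), `labels` and `n`.
#' @examples
#' d <- manhattan_distance_matrix(cbind(x = c(0, 1, 5, 7)))
#' complete_linkage(d)$height # 1, 2, 7
#' @export
complete_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2) stop("need at least 2 subjects to cluster")
  labels <- rownames(d) %||% as.character(seq_len(n))

  work <- unclass(d)
  diag(work) <- Inf
  active <- rep(TRUE, n)
  members <- lapply(seq_len(n), identity)  # original indices per slot
  code <- -seq_len(n)                      # hclust-style cluster codes
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  size <- integer(n - 1)

  for (step in seq_len(n - 1)) {
    act <- which(active)
    sub <- work[act, act, drop = FALSE]
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {                  # deterministic tie-break
      keys <- t(apply(cand, 1, function(rc) {
        pair_key(members[[act[rc[1]]]], members[[act[rc[2]]]])
      }))
      ord <- order(keys[, 1], keys[, 2])
      cand <- cand[ord, , drop = FALSE]
    }
    i <- act[cand[1, 1]]; j <- act[cand[1, 2]]

    # order the recorded pair by smallest original member index
    first_i <- min(members[[i]]) < min(members[[j]])
    merge[step, ] <- if (first_i) c(code[i], code[j]) else c(code[j], code[i])
    height[step] <- h
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    size[step] <- length(members[[i]])
    code[i] <- step
    active[j] <- FALSE

    upd <- pmax(work[i, ], work[j, ])      # Lance-Williams complete linkage
    work[i, ] <- upd
    work[, i] <- upd
    work[i, i] <- Inf
    work[j, ] <- Inf
    work[, j] <- Inf
  }

  structure(list(merge = merge, height = height, size = size,
                 labels = labels, n = n),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat("Complete-linkage tree over", x$n, "subjects;",
      length(x$height), "merges, final height",
      format(max(x$height), digits = 4), "\n")
  invisible(x)
}

#' Convert a linkage tree to an `hclust` object
#'
#' Allows use of standard dendrogram tooling (`plot`, `stats::cutree`, ...).
#'
#' @param x A `linkage_tree`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  ord <- integer(0)
  expand <- function(code) {
    if (code < 0) return(-code)
    c(expand(x$merge[code, 1]), expand(x$merge[code, 2]))
  }
  ord <- expand(nrow(x$merge))
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "complete",
                 call = match.call(), dist.method = "manhattan"),
            class = "hclust")
}

#' Merge-height curve (cluster-count diagnostic)
#'
#' Emits, for every fusion, the number of clusters remaining after the
#' fusion and the complete-linkage height at which it happened, ordered by
#' decreasing cluster count. On real cohorts the curve stays flat while
#' coherent clusters merge and rises when mergers become forced; the bend is
#' the usual guide for choosing the cluster count.
#'
#' @param tree A `linkage_tree`.
#' @return A tibble with columns `n_clusters` and `height`.
#' @export
merge_metric_curve <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  tibble::tibble(n_clusters = tree$n - seq_along(tree$height),
                 height = tree$height)
}

#' Heuristic knee of the merge-height curve
#'
#' Suggests a cluster count as the number of clusters remaining just before
#' the largest jump in merge height — the point where coherent clusters run
#' out and forced mergers begin. This is a heuristic aid only; the cluster
#' count remains an analyst's choice.
#'
#' @param tree A `linkage_tree`.
#' @param max_k Restrict the search to `n_clusters <= max_k` (default: no
#'   restriction).
#' @return Suggested number of clusters (integer).
#' @export
suggest_k <- function(tree, max_k = Inf) {
  cv <- merge_metric_curve(tree)
  cv <- cv[cv$n_clusters <= max_k, , drop = FALSE]
  if (nrow(cv) < 2) return(cv$n_clusters[1])
  gaps <- diff(cv$height)   # gap i: height jump of the next merge after i
  cv$n_clusters[which.max(gaps)]
}

#' Cut a linkage tree into k clusters
#'
#' Undoes the last k-1 merges; clusters are numbered 1..k by increasing
#' smallest member index. Clusters smaller than `min_cluster_size` (default
#' 7) are flagged non-reportable — they are kept in the output, only marked,
#' because small clusters are usually outliers or too small for meaningful
#' statistics.
#'
#' @param tree A `linkage_tree`.
#' @param k Number of clusters (1 <= k <= n).
#' @param min_cluster_size Reportability threshold (default 7).
#' @return A tibble with one row per subject: `id`, `cluster`,
#'   `cluster_size`, `reportable`.
#' @export
cut_clusters <- function(tree, k, min_cluster_size = 7) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- tree$n
  if (k < 1 || k > n) stop("k must be in [1, ", n, "], got ", k)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  roots <- integer(n - 1)  # root after each merge, for code resolution
  for (step in seq_len(n - k)) {
    pr <- tree$merge[step, ]
    a <- if (pr[1] < 0) -pr[1] else roots[pr[1]]
    b <- if (pr[2] < 0) -pr[2] else roots[pr[2]]
    ra <- find(a); rb <- find(b)
    keep <- min(ra, rb)
    parent[max(ra, rb)] <- keep
    roots[step] <- keep
  }
  root_of <- vapply(seq_len(n), find, integer(1))
  cl <- as.integer(factor(root_of, levels = sort(unique(root_of))))
  sizes <- tabulate(cl)
  tibble::tibble(id = tree$labels, cluster = cl,
                 cluster_size = sizes[cl],
                 reportable = sizes[cl] >= min_cluster_size)
}

#' Tidy the merge list of a linkage tree
#'
#' @param x A `linkage_tree`.
#' @param ... Unused.
#' @return One row per merge: `step`, `cluster_a`, `cluster_b` (hclust
#'   codes), `height`, `new_size`, `n_clusters` remaining after the merge.
#' @method tidy linkage_tree
#' @export
tidy.linkage_tree <- function(x, ...) {
  tibble::tibble(step = seq_along(x$height),
                 cluster_a = x$merge[, 1], cluster_b = x$merge[, 2],
                 height = x$height, new_size = x$size,
                 n_clusters = x$n - seq_along(x$height))
}

#' @rdname tidy.linkage_tree
#' @method glance linkage_tree
#' @export
glance.linkage_tree <- function(x, ...) {
  tibble::tibble(n = x$n, n_merges = length(x$height),
                 max_height = max(x$height),
                 monotone = !is.unsorted(x$height))
}

#' Plot the merge-height curve
#'
#' @param object A `linkage_tree`.
#' @param max_k Show only `n_clusters <= max_k` (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot linkage_tree
#' @export
autoplot.linkage_tree <- function(object, max_k = Inf, ...) {
  cv <- merge_metric_curve(object)
  cv <- cv[cv$n_clusters <= max_k, , drop = FALSE]
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$n_clusters, y = .data$height)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "number of clusters",
                  y = "complete-linkage merge height",
                  title = "Merge-height curve") +
    ggplot2::theme_minimal()
}

#' Write / read a linkage tree as a 4-column merge table
#'
#' Plain-text export (`cluster_a cluster_b height new_size`, hclust codes)
#' compatible with common dendrogram tooling.
#'
#' @param tree A `linkage_tree`.
#' @param path Output file.
#' @param labels Subject labels (read side).
#' @return `write_merge_table()` returns `path` invisibly;
#'   `read_merge_table()` a `linkage_tree`.
#' @export
write_merge_table <- function(tree, path) {
  df <- data.frame(a = tree$merge[, 1], b = tree$merge[, 2],
                   height = tree$height, size = tree$size)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_merge_table
#' @export
read_merge_table <- function(path, labels = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  n <- nrow(df) + 1L
  structure(list(merge = cbind(as.integer(df$a), as.integer(df$b)),
                 height = df$height, size = as.integer(df$size),
                 labels = labels %||% as.character(seq_len(n)), n = n),
            class = "linkage_tree")
}
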