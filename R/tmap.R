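# Voxel-wise two-sample t-maps between cluster unions, with a plug-in FDR
# estimate at a fixed |t| threshold.

#' Voxel-wise two-sample t-map
#'
#' Computes, at every masked voxel, the two-sample t statistic between the
#' rows named in `group_a` and `group_b`, with sign convention
#' `mean(A) - mean(B)` (positive t = higher density in A). The default is
#' the pooled-variance Student test (df = n_a + n_b - 2), the classical VBM
#' choice; `var_equal = FALSE` gives the Welch form with per-voxel df.
#' Voxels with zero variance in both groups get t = 0 and are counted in
#' `n_degenerate`.
#'
#' @param vm A `voxel_matrix` (typically residualized).
#' @param group_a,group_b Disjoint sets of subject ids, each of size >= 2.
#' @param var_equal Pooled-variance Student t (default `TRUE`) or Welch.
#' @return An object of class `tmap`: list with `t` (per masked voxel),
#'   `df`, `n_a`, `n_b`, `sign_convention`, `n_degenerate` and mask
#'   geometry.
#' @export
two_sample_tmap <- function(vm, group_a, group_b, var_equal = TRUE) {
  stopifnot(inherits(vm, "voxel_matrix"))
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap: ", paste(intersect(group_a, group_b),
                                   collapse = ", "))
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 subjects")
  }
  missing <- setdiff(c(group_a, group_b), rownames(vm))
  if (length(missing)) stop("subjects absent from voxel matrix: ",
                            paste(missing, collapse = ", "))
  a <- unclass(vm)[group_a, , drop = FALSE]
  b <- unclass(vm)[group_b, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums((a - rep(ma, each = na))^2) / (na - 1)
  vb <- colSums((b - rep(mb, each = nb))^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    df[!is.finite(df)] <- na + nb - 2
  }
  degen <- se == 0 | !is.finite(se)
  tv <- ifelse(degen, 0, (ma - mb) / se)
  structure(
    list(t = tv, df = df, n_a = na, n_b = nb,
         group_a = group_a, group_b = group_b,
         sign_convention = "mean(A) - mean(B)",
         var_equal = var_equal,
         n_degenerate = sum(degen),
         mask_dim = attr(vm, "mask_dim"),
         voxel_index = attr(vm, "voxel_index")),
    class = "tmap"
  )
}

#' @export
print.tmap <- function(x, ...) {
  cat("Voxel-wise t-map: ", length(x$t), " voxels, n = ", x$n_a, " vs ",
      x$n_b, ", df = ", x$df[1],
      if (x$var_equal) " (pooled)" else " (Welch, per voxel)",
      "; sign: ", x$sign_convention, "\n", sep = "")
  if (x$n_degenerate > 0) {
    cat(x$n_degenerate, "zero-variance voxel(s) set to t = 0\n")
  }
  invisible(x)
}

#' Plug-in FDR estimate at a |t| threshold
#'
#' Estimates the false-discovery rate among voxels exceeding `|t| > thr` as
#' `min(1, m * p_thr / r)` where `m` is the number of masked voxels,
#' `p_thr` the two-sided tail probability of the t distribution at `thr`,
#' and `r` the observed number of exceedances. This treats all voxels as
#' null when bounding the expected false-positive count, so the estimate is
#' conservative. Returns `NA` (not 0) when no voxel exceeds the threshold.
#'
#' @param tmap A [two_sample_tmap()] result.
#' @param thr Threshold on |t| (default 3).
#' @return Estimated FDR in \[0, 1\], or `NA` if there are no exceedances.
#' @export
fdr_at_threshold <- function(tmap, thr = 3) {
  stopifnot(inherits(tmap, "tmap"), thr > 0)
  m <- length(tmap$t)
  p_thr <- 2 * pt(thr, tmap$df, lower.tail = FALSE)
  r <- sum(abs(tmap$t) > thr)
  if (r == 0) {
    message("no voxels exceed |t| > ", thr, "; FDR not applicable")
    return(NA_real_)
  }
  min(1, sum(p_thr) / r)   # sum over voxels = m * p_thr for pooled df
}

#' Tidy / summarize a t-map
#'
#' @param x A `tmap`.
#' @param ... Unused.
#' @return `tidy()`: tibble `voxel`, `t`, `df`. `glance()`: one-row tibble
#'   with group sizes, df, degenerate-voxel count and the |t| > 3
#'   exceedance count.
#' @method tidy tmap
#' @export
tidy.tmap <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$t), t = x$t, df = x$df)
}

#' @rdname tidy.tmap
#' @method glance tmap
#' @export
glance.tmap <- function(x, ...) {
  tibble::tibble(n_voxels = length(x$t), n_a = x$n_a, n_b = x$n_b,
                 df = x$df[1], n_degenerate = x$n_degenerate,
                 n_exceed_3 = sum(abs(x$t) > 3),
                 fdr_at_3 = suppressMessages(fdr_at_threshold(x, 3)))
}

# Re-embed the t vector as a 3D array (0 outside the mask).
tmap_array <- function(tmap) {
  a <- array(0, dim = tmap$mask_dim)
  a[tmap$voxel_index] <- tmap$t
  a
}

#' Write a t-map as NIfTI plus a JSON sidecar
#'
#' Writes the t volume (0 outside the mask) as NIfTI-1, the mask alongside,
#' and a sidecar JSON recording df, group sizes and ids, the sign
#' convention, the variance model and an FDR table at |t| thresholds 2, 3
#' and 4.
#'
#' @param tmap A `tmap`.
#' @param path Output path for the t volume (`.nii` or `.nii.gz`); the
#'   sidecar replaces the extension with `.json`, the mask gets
#'   `_mask.nii.gz`.
#' @return Invisibly, the sidecar path.
#' @export
write_tmap <- function(tmap, path) {
  stopifnot(inherits(tmap, "tmap"))
  arr <- tmap_array(tmap)
  RNifti::writeNifti(arr, path, datatype = "float")
  mask <- array(0L, dim = tmap$mask_dim)
  mask[tmap$voxel_index] <- 1L
  base <- sub("\\.nii(\\.gz)?$", "", path)
  RNifti::writeNifti(mask, paste0(base, "_mask.nii"))
  fdr_tab <- lapply(c(2, 3, 4), function(th) {
    list(threshold = th,
         fdr = suppressMessages(fdr_at_threshold(tmap, th)))
  })
  sidecar <- list(df = tmap$df[1], n_a = tmap$n_a, n_b = tmap$n_b,
                  group_a = tmap$group_a, group_b = tmap$group_b,
                  sign_convention = tmap$sign_convention,
                  variance_model = if (tmap$var_equal) "pooled" else "welch",
                  n_degenerate = tmap$n_degenerate,
                  fdr_at = fdr_tab)
  sidecar_path <- paste0(base, ".json")
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(sidecar_path)
}

#' Read a t-map written by [write_tmap()]
#'
#' @param path Path to the t volume.
#' @return A `tmap` (t values at float32 precision).
#' @export
read_tmap <- function(path) {
  arr <- RNifti::readNifti(path)
  base <- sub("\\.nii(\\.gz)?$", "", path)
  mask <- RNifti::readNifti(paste0(base, "_mask.nii"))
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  idx <- which(array(as.logical(mask), dim = dim(mask)))
  structure(
    list(t = as.numeric(arr)[idx],
         df = rep(side$df, length(idx)),
         n_a = side$n_a, n_b = side$n_b,
         group_a = side$group_a, group_b = side$group_b,
         sign_convention = side$sign_convention,
         var_equal = identical(side$variance_model, "pooled"),
         n_degenerate = side$n_degenerate,
         mask_dim = dim(mask), voxel_index = idx),
    class = "tmap"
  )
}

#' Orthogonal-slice plot of a t-map
#'
#' Mid-volume axial, coronal and sagittal slices of the t volume.
#'
#' @param object A `tmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tmap
#' @export
autoplot.tmap <- function(object, ...) {
  arr <- tmap_array(object)
  dm <- dim(arr)
  mid <- ceiling(dm / 2)
  slice_df <- function(plane, mat) {
    tibble::tibble(plane = plane,
                   i = rep(seq_len(nrow(mat)), ncol(mat)),
                   j = rep(seq_len(ncol(mat)), each = nrow(mat)),
                   t = as.vector(mat))
  }
  df <- dplyr::bind_rows(
    slice_df("axial", arr[, , mid[3]]),
    slice_df("coronal", arr[, mid[2], ]),
    slice_df("sagittal", arr[mid[1], , ])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey95",
                                  high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Voxel-wise t-map (mid slices)",
                  subtitle = paste("sign:", object$sign_convention)) +
    ggplot2::theme_minimal()
}
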