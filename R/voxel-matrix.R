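# Subjects x masked-voxels matrices and NIfTI I/O.

#' Flatten masked volumes into a subjects-by-voxels matrix
#'
#' Row `i` holds the in-mask voxels of subject `i` in column-major
#' (Fortran) voxel order, i.e. the order of `which(mask)`. This ordering is
#' part of the contract: [embed_voxel_matrix()] inverts it exactly.
#'
#' @param volumes Named list of numeric 3D arrays on a common grid.
#' @param mask Logical 3D array with at least one `TRUE` voxel.
#' @return A numeric matrix of class `voxel_matrix` with subject ids as row
#'   names and attributes `mask_dim`, `voxel_index` (the `which(mask)`
#'   linear indices) and `is_residual` (`FALSE`).
#' @examples
#' msk <- array(FALSE, c(4, 4, 4)); msk[2:3, 2:3, 2] <- TRUE
#' vols <- list(a = array(1, c(4, 4, 4)), b = array(2, c(4, 4, 4)))
#' dim(extract_voxel_matrix(vols, msk))
#' @export
extract_voxel_matrix <- function(volumes, mask) {
  stopifnot(is.list(volumes), length(volumes) >= 1, is.logical(mask),
            length(dim(mask)) == 3)
  if (!any(mask)) stop("brain mask is empty (no TRUE voxels)")
  if (is.null(names(volumes))) {
    names(volumes) <- sprintf("s%03d", seq_along(volumes))
  }
  idx <- which(mask)
  for (nm in names(volumes)) {
    dv <- dim(volumes[[nm]])
    if (is.null(dv) || !identical(as.integer(dv), as.integer(dim(mask)))) {
      stop("subject '", nm, "': volume grid (",
           paste(dv, collapse = "x"), ") does not match mask grid (",
           paste(dim(mask), collapse = "x"), ")")
    }
  }
  m <- do.call(rbind, lapply(volumes, function(v) v[idx]))
  rownames(m) <- names(volumes)
  new_voxel_matrix(m, mask, is_residual = FALSE)
}

new_voxel_matrix <- function(m, mask = NULL, is_residual = FALSE) {
  structure(m,
            mask_dim = if (is.null(mask)) NULL else dim(mask),
            voxel_index = if (is.null(mask)) NULL else which(mask),
            is_residual = is_residual,
            class = c("voxel_matrix", class(matrix())))
}

#' Re-embed voxel-matrix rows into 3D volumes
#'
#' Inverse of [extract_voxel_matrix()]: writes each row back to its voxels
#' (column-major mask order); out-of-mask voxels are `fill`.
#'
#' @param vm A `voxel_matrix`.
#' @param fill Value for voxels outside the mask (default 0).
#' @return A named list of 3D arrays.
#' @export
embed_voxel_matrix <- function(vm, fill = 0) {
  stopifnot(inherits(vm, "voxel_matrix"))
  dm <- attr(vm, "mask_dim")
  idx <- attr(vm, "voxel_index")
  out <- lapply(seq_len(nrow(vm)), function(i) {
    a <- array(fill, dim = dm)
    a[idx] <- vm[i, ]
    a
  })
  names(out) <- rownames(vm)
  out
}

#' Data-driven brain mask from control subjects
#'
#' For real data without a supplied mask: keeps voxels whose mean GM density
#' across the given volumes exceeds `mean_thresh` and whose variance is
#' positive.
#'
#' @param volumes Named list of 3D arrays (typically normal controls).
#' @param mean_thresh Minimum mean density (default 0.1).
#' @return A logical 3D array.
#' @export
make_brain_mask <- function(volumes, mean_thresh = 0.1) {
  stopifnot(length(volumes) >= 2)
  dm <- dim(volumes[[1]])
  s <- array(0, dm); s2 <- array(0, dm)
  for (v in volumes) {
    stopifnot(identical(dim(v), dm))
    s <- s + v; s2 <- s2 + v^2
  }
  n <- length(volumes)
  mu <- s / n
  vv <- s2 / n - mu^2
  mu > mean_thresh & vv > 1e-12
}

#' Write / read GM volumes as NIfTI-1
#'
#' `write_volumes()` writes one `.nii.gz` file per subject (named by subject
#' id) plus `mask.nii.gz`; `read_volumes()` reads every `*.nii`/`*.nii.gz`
#' in a directory back into a named list of arrays.
#'
#' @param volumes Named list of 3D arrays.
#' @param mask Logical 3D array.
#' @param dir Output directory (created if needed).
#' @return `write_volumes()` returns the written file paths invisibly;
#'   `read_volumes()` a named list of 3D arrays.
#' @export
write_volumes <- function(volumes, mask, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(volumes)) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(volumes[[nm]], p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(array(as.integer(mask), dim = dim(mask)), mp)
  invisible(c(paths, mp))
}

#' @rdname write_volumes
#' @export
read_volumes <- function(dir) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  files <- files[!grepl("^mask\\.", basename(files))]
  if (length(files) == 0) stop("no NIfTI volumes found in ", dir)
  vols <- lapply(files, function(f) {
    a <- RNifti::readNifti(f)
    array(as.numeric(a), dim = dim(a))
  })
  names(vols) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  vols
}
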