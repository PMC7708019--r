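# Voxel-wise confound regression: fit on normal controls, apply everywhere.
# The model at each voxel is density ~ 1 + age + sex + field + education.

covariate_order <- c("intercept", "age", "sex", "field_strength", "education")

# Design matrix in the documented covariate order; errors list missing ids.
confound_design <- function(covariates, ids) {
  need <- c("id", "age", "sex", "field_strength", "education")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("covariate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  rows <- match(ids, covariates$id)
  if (anyNA(rows)) {
    stop("covariates missing for subject(s): ",
         paste(ids[is.na(rows)], collapse = ", "))
  }
  cv <- covariates[rows, ]
  if (!all(is.finite(cv$age)) || !all(is.finite(cv$sex)) ||
      !all(is.finite(cv$field_strength)) || !all(is.finite(cv$education))) {
    stop("non-finite covariate values")
  }
  x <- cbind(intercept = 1, age = cv$age, sex = cv$sex,
             field_strength = cv$field_strength, education = cv$education)
  rownames(x) <- ids
  x
}

#' Fit the voxel-wise confound model on normal controls
#'
#' Ordinary least squares of GM density on (intercept, age, sex, scanner
#' field strength, education) at every masked voxel, using only the rows
#' named in `nc_ids`. All voxels share one design matrix, so the fit is a
#' single QR solve; the result is identical to fitting each voxel
#' independently.
#'
#' @param vm A `voxel_matrix` (raw densities).
#' @param covariates Tibble with columns `id`, `age`, `sex`,
#'   `field_strength`, `education`.
#' @param nc_ids Subject ids to fit on (the normal controls); at least 6, so
#'   there are more observations than parameters.
#' @return An object of class `confound_model`: list with `coefficients`
#'   (n_voxels x 5), `covariate_order`, `n_fit`, and mask geometry carried
#'   over from `vm`.
#' @export
fit_confound_model <- function(vm, covariates, nc_ids) {
  stopifnot(inherits(vm, "voxel_matrix"))
  if (length(nc_ids) == 0) stop("`nc_ids` is empty")
  if (!all(nc_ids %in% rownames(vm))) {
    stop("nc_ids absent from voxel matrix: ",
         paste(setdiff(nc_ids, rownames(vm)), collapse = ", "))
  }
  if (length(nc_ids) < 6) stop("need at least 6 control subjects to fit ",
                               "5 coefficients")
  x <- confound_design(covariates, nc_ids)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("rank-deficient confound design; collinear covariate(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, vm[nc_ids, , drop = FALSE])   # 5 x V
  structure(
    list(coefficients = t(beta), covariate_order = covariate_order,
         n_fit = length(nc_ids), mask_dim = attr(vm, "mask_dim"),
         voxel_index = attr(vm, "voxel_index")),
    class = "confound_model"
  )
}

#' Residualize GM densities against the control-fitted confound model
#'
#' Subtracts the model prediction from every subject's row (controls
#' included, so all rows live on one scale before distances are computed).
#'
#' @param vm A `voxel_matrix` of raw densities.
#' @param model A [fit_confound_model()] result fitted on the same mask.
#' @param covariates Covariate tibble covering every row of `vm`.
#' @return A `voxel_matrix` of residuals (`is_residual = TRUE`).
#' @export
residualize <- function(vm, model, covariates) {
  stopifnot(inherits(vm, "voxel_matrix"), inherits(model, "confound_model"))
  if (!identical(attr(vm, "voxel_index"), model$voxel_index)) {
    stop("voxel matrix and confound model use different masks")
  }
  x <- confound_design(covariates, rownames(vm))
  pred <- x %*% t(model$coefficients)      # n x V
  res <- unclass(vm) - pred
  out <- new_voxel_matrix(res, mask = NULL, is_residual = TRUE)
  attr(out, "mask_dim") <- attr(vm, "mask_dim")
  attr(out, "voxel_index") <- attr(vm, "voxel_index")
  out
}

#' @export
print.confound_model <- function(x, ...) {
  cat("Voxel-wise confound model (", nrow(x$coefficients), " voxels, ",
      x$n_fit, " control subjects)\n", sep = "")
  cat("terms:", paste(x$covariate_order, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a voxel-wise confound model
#'
#' @param x A `confound_model`.
#' @param ... Unused.
#' @return One row per voxel-term pair: `voxel` (index into the mask order),
#'   `term`, `estimate`.
#' @method tidy confound_model
#' @export
tidy.confound_model <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    voxel = rep(seq_len(nrow(co)), times = ncol(co)),
    term = rep(x$covariate_order, each = nrow(co)),
    estimate = as.vector(co)
  )
}

#' @rdname tidy.confound_model
#' @method glance confound_model
#' @export
glance.confound_model <- function(x, ...) {
  tibble::tibble(n_voxels = nrow(x$coefficients), n_fit = x$n_fit,
                 n_terms = length(x$covariate_order))
}
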