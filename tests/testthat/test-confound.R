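# Voxel matrix extraction and the NC-fitted confound model.

make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(id = sprintf("s%03d", seq_len(n)),
                 age = round(runif(n, 55, 90)),
                 sex = rbinom(n, 1, 0.5),
                 field_strength = rbinom(n, 1, 0.5),
                 education = round(rnorm(n, 16, 2)))
}

# Forward-simulate densities from known coefficients on a tiny mask.
planted_matrix <- function(cov, beta, noise_sd = 0, n_vox = 5, seed = 2) {
  set.seed(seed)
  x <- cbind(1, cov$age, cov$sex, cov$field_strength, cov$education)
  mu <- x %*% beta   # beta: 5 x n_vox
  m <- mu + matrix(rnorm(length(mu), 0, noise_sd), nrow(mu))
  rownames(m) <- cov$id
  msk <- array(FALSE, c(n_vox, 1, 1)); msk[seq_len(n_vox), 1, 1] <- TRUE
  vols <- lapply(seq_len(nrow(m)), function(i) {
    a <- array(0, c(n_vox, 1, 1)); a[msk] <- m[i, ]; a
  })
  names(vols) <- cov$id
  extract_voxel_matrix(vols, msk)
}

test_that("extract_voxel_matrix honors the shape contract and round-trips", {
  msk <- array(FALSE, c(4, 4, 4)); msk[2:3, 2:3, 2:3] <- FALSE
  msk[c(1, 5, 9, 20, 33)] <- TRUE
  vols <- list(a = array(runif(64), c(4, 4, 4)),
               b = array(runif(64), c(4, 4, 4)))
  vm <- extract_voxel_matrix(vols, msk)
  expect_equal(dim(vm), c(2, 5))
  expect_equal(rownames(vm), c("a", "b"))
  expect_equal(vm["a", ], vols$a[which(msk)])
  back <- embed_voxel_matrix(vm)
  expect_equal(back$a[msk], vols$a[msk])
  expect_equal(back$b[msk], vols$b[msk])
  expect_true(all(back$a[!msk] == 0))
})

test_that("empty masks and mismatched grids are rejected with the subject named", {
  msk <- array(FALSE, c(4, 4, 4))
  vols <- list(a = array(0, c(4, 4, 4)))
  expect_error(extract_voxel_matrix(vols, msk), "empty")
  msk[1] <- TRUE
  vols$bad <- array(0, c(5, 4, 4))
  expect_error(extract_voxel_matrix(vols, msk), "bad")
})

test_that("noiseless OLS recovers planted coefficients exactly, residuals vanish", {
  cov <- make_covariates(20)
  beta <- cbind(c(0.5, -0.002, -0.01, 0.005, 0.001),
                c(0.4, 0.001, 0.02, 0, -0.002),
                c(0.6, 0, 0, 0, 0))
  vm <- planted_matrix(cov, beta, noise_sd = 0, n_vox = 3)
  model <- fit_confound_model(vm, cov, cov$id)
  expect_equal(model$coefficients, t(beta), ignore_attr = TRUE,
               tolerance = 1e-10)
  res <- residualize(vm, model, cov)
  expect_true(max(abs(res)) < 1e-10)
  expect_true(attr(res, "is_residual"))
})

test_that("NC residuals are orthogonal to every covariate and mean-zero", {
  cov <- make_covariates(30, seed = 4)
  beta <- matrix(rnorm(5 * 6, 0, 0.01), 5, 6)
  vm <- planted_matrix(cov, beta, noise_sd = 0.05, n_vox = 6, seed = 5)
  model <- fit_confound_model(vm, cov, cov$id)
  res <- residualize(vm, model, cov)
  x <- cbind(1, cov$age, cov$sex, cov$field_strength, cov$education)
  dots <- t(x) %*% unclass(res)
  expect_lt(max(abs(dots)), 1e-8)
  expect_lt(max(abs(colMeans(unclass(res)))), 1e-10)
  # per-voxel fit equals independent lm fits
  lm_beta <- sapply(seq_len(ncol(vm)), function(v) {
    unname(coef(lm(unclass(vm)[, v] ~ cov$age + cov$sex +
                     cov$field_strength + cov$education)))
  })
  expect_equal(unname(model$coefficients), unname(t(lm_beta)),
               tolerance = 1e-8)
})

test_that("refitting on NC residuals gives null coefficients; variance shrinks", {
  cov <- make_covariates(25, seed = 8)
  beta <- matrix(rnorm(5 * 4, 0, 0.01), 5, 4)
  vm <- planted_matrix(cov, beta, noise_sd = 0.03, n_vox = 4, seed = 9)
  model <- fit_confound_model(vm, cov, cov$id)
  res <- residualize(vm, model, cov)
  refit <- fit_confound_model(res, cov, cov$id)
  expect_lt(max(abs(refit$coefficients)), 1e-8)
  raw_var <- apply(unclass(vm), 2, var)
  res_var <- apply(unclass(res), 2, var)
  expect_true(all(res_var <= raw_var + 1e-12))
})

test_that("planted regional atrophy survives residualization untouched", {
  gs <- c(10, 10, 10)
  msk <- ellipsoid_mask(gs)
  region <- spherical_region(gs, c(5, 5, 5), 2, msk)
  tpl <- phenotype_template("atro", region, 0.1, 20, 0, 0, c(0, 1, 0))
  tpl_nc <- phenotype_template("none", region, 0, 10, 0, 0, c(1, 0, 0))
  cfg <- cohort_config(40, list(tpl_nc, tpl), gs, brain_mask = msk,
                       voxel_noise_sd = 0, rng_seed = 6)
  ch <- simulate_cohort(cfg)
  vm <- extract_voxel_matrix(ch$volumes, ch$mask)
  nc_ids <- ch$subjects$id[ch$subjects$baseline_dx == 1]
  model <- fit_confound_model(vm, ch$subjects, nc_ids)
  res <- residualize(vm, model, ch$subjects)
  atro_ids <- ch$subjects$id[ch$subjects$true_subtype == "atro"]
  in_region <- region[msk]
  inside <- colMeans(unclass(res)[atro_ids, in_region, drop = FALSE])
  outside <- colMeans(unclass(res)[atro_ids, !in_region, drop = FALSE])
  expect_equal(mean(inside), -0.1, tolerance = 1e-6)
  expect_lt(max(abs(outside)), 1e-6)
})

test_that("misaligned covariates change residuals; rank deficiency is caught", {
  cov <- make_covariates(20, seed = 12)
  beta <- matrix(rnorm(5 * 3, 0, 0.01), 5, 3)
  vm <- planted_matrix(cov, beta, noise_sd = 0.02, n_vox = 3, seed = 13)
  model <- fit_confound_model(vm, cov, cov$id)
  res <- residualize(vm, model, cov)
  shuffled <- cov
  shuffled[, c("age", "education")] <- shuffled[sample(nrow(cov)),
                                                c("age", "education")]
  res_shuf <- residualize(vm, model, shuffled)
  expect_gt(max(abs(unclass(res) - unclass(res_shuf))), 1e-6)

  collinear <- cov
  collinear$education <- 2 * collinear$age
  expect_error(fit_confound_model(vm, collinear, cov$id), "collinear")
  expect_error(residualize(vm, model, cov[-1, ]), "missing for subject")
  expect_error(fit_confound_model(vm, cov, cov$id[1:3]), "at least 6")
})
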