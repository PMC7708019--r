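# Synthetic cohorts with planted atrophy subtypes. Every downstream stage
# (residualization, clustering, characterization, t-maps) is exercisable on
# these cohorts with known ground truth.

#' Ellipsoidal brain mask on a regular voxel grid
#'
#' Builds a centered ellipsoidal mask whose semi-axes are `radius_frac` times
#' half the grid extent in each dimension. This is the default stand-in for a
#' real brain mask in synthetic cohorts.
#'
#' @param grid_shape Integer vector of length 3, voxels per dimension (all
#'   >= 4).
#' @param radius_frac Semi-axis length as a fraction of half the grid extent
#'   (default 0.9).
#' @return A logical 3D array; `TRUE` marks in-brain voxels.
#' @examples
#' m <- ellipsoid_mask(c(8, 8, 8))
#' sum(m)
#' @export
ellipsoid_mask <- function(grid_shape, radius_frac = 0.9) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4))
  ctr <- (grid_shape + 1) / 2
  semi <- radius_frac * (grid_shape - 1) / 2
  ax <- (seq_len(grid_shape[1]) - ctr[1]) / semi[1]
  ay <- (seq_len(grid_shape[2]) - ctr[2]) / semi[2]
  az <- (seq_len(grid_shape[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  r2 <= 1
}

#' Spherical atrophy region inside a grid
#'
#' Convenience builder for planted-atrophy masks: a ball of radius `radius`
#' (voxels) centered at `center` (voxel coordinates), intersected with
#' `within` when given.
#'
#' @param grid_shape Integer vector of length 3.
#' @param center Numeric length-3 voxel coordinate of the ball center.
#' @param radius Ball radius in voxels.
#' @param within Optional logical array (e.g. the brain mask) to intersect
#'   with.
#' @return A logical 3D array.
#' @export
spherical_region <- function(grid_shape, center, radius, within = NULL) {
  stopifnot(length(grid_shape) == 3, length(center) == 3, radius > 0)
  ax <- (seq_len(grid_shape[1]) - center[1])^2
  ay <- (seq_len(grid_shape[2]) - center[2])^2
  az <- (seq_len(grid_shape[3]) - center[3])^2
  r2 <- outer(outer(ax, ay, `+`), az, `+`)
  out <- r2 <= radius^2
  if (!is.null(within)) out <- out & within
  out
}

#' Define a planted structural phenotype
#'
#' A phenotype template describes one synthetic disease subtype: where gray
#' matter is lost (`atrophy_mask`), how much (`severity`, in GM-density
#' units), the ADAS-cog trajectory it induces, the baseline diagnosis mixture
#' and an optional per-month hazard of clinical progression during follow-up.
#'
#' @param name Template label (also the ground-truth subtype label).
#' @param atrophy_mask Logical 3D array marking the atrophic region.
#' @param severity Mean GM-density reduction inside the region (>= 0).
#' @param adas_baseline_mean Mean baseline ADAS-cog score (points).
#' @param adas_slope_mean Mean ADAS progression slope (points/month).
#' @param adas_slope_sd Between-subject SD of the slope (points/month, >= 0).
#' @param diagnosis_mix Length-3 probability vector over baseline diagnosis
#'   (NC, MCI, AD); must sum to 1 within 1e-12.
#' @param conversion_hazard Per-month probability of progressing one clinical
#'   stage (NC to MCI, MCI to AD) during follow-up (default 0).
#' @return An object of class `phenotype_template`.
#' @examples
#' msk <- ellipsoid_mask(c(8, 8, 8))
#' tpl <- phenotype_template("ad_like", spherical_region(c(8, 8, 8), c(4, 4, 4), 2, msk),
#'   severity = 0.1, adas_baseline_mean = 30, adas_slope_mean = 0.5,
#'   adas_slope_sd = 0.1, diagnosis_mix = c(0, 0.2, 0.8))
#' @export
phenotype_template <- function(name, atrophy_mask, severity,
                               adas_baseline_mean, adas_slope_mean,
                               adas_slope_sd, diagnosis_mix,
                               conversion_hazard = 0) {
  stopifnot(is.character(name), length(name) == 1,
            is.logical(atrophy_mask), length(dim(atrophy_mask)) == 3,
            severity >= 0, adas_slope_sd >= 0,
            is.finite(adas_baseline_mean), is.finite(adas_slope_mean),
            length(diagnosis_mix) == 3, all(diagnosis_mix >= 0),
            conversion_hazard >= 0, conversion_hazard <= 1)
  if (abs(sum(diagnosis_mix) - 1) > 1e-12) {
    stop("`diagnosis_mix` must sum to 1 (got ", sum(diagnosis_mix), ")")
  }
  structure(
    list(name = name, atrophy_mask = atrophy_mask, severity = severity,
         adas_baseline_mean = adas_baseline_mean,
         adas_slope_mean = adas_slope_mean, adas_slope_sd = adas_slope_sd,
         diagnosis_mix = setNames(as.numeric(diagnosis_mix),
                                  c("NC", "MCI", "AD")),
         conversion_hazard = conversion_hazard),
    class = "phenotype_template"
  )
}

#' Configure a synthetic cohort
#'
#' Collects everything [simulate_cohort()] needs: cohort size, voxel grid,
#' the planted phenotype templates, linear confound coefficients, noise
#' levels and the random seed. Defaults emulate an elderly memory-clinic
#' cohort: age ~ Normal(73, 7^2) truncated to \[55, 90\], sex and scanner
#' field strength Bernoulli(0.5), education ~ Normal(16, 2^2) years, and
#' APOE e4 carrier rates of 27.3% / 49.3% / 66.7% in NC / MCI / AD.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param templates List of [phenotype_template()] objects (>= 1).
#' @param grid_shape Voxel grid (default `c(24, 24, 24)`; all dims >= 4).
#' @param brain_mask Logical 3D array; defaults to [ellipsoid_mask()] on
#'   `grid_shape`.
#' @param confound_coeffs Named numeric vector `c(age=, sex=, education=,
#'   field=)`: additive GM-density effect per covariate unit.
#' @param voxel_noise_sd SD of additive voxel noise (GM-density units, >= 0).
#' @param adas_noise_sd SD of per-visit ADAS measurement noise (points, >= 0).
#' @param template_probs Sampling probabilities over templates (default
#'   uniform).
#' @param apoe_carrier_prob Per-diagnosis probability of carrying at least
#'   one APOE e4 allele, ordered (NC, MCI, AD).
#' @param apoe_hom_given_carrier Per-diagnosis probability of homozygosity
#'   given carriership, ordered (NC, MCI, AD).
#' @param noise_smooth_sd Optional SD (voxels) of isotropic Gaussian
#'   smoothing applied to the voxel noise field; 0 (default) leaves the noise
#'   spatially independent.
#' @param rng_seed Integer seed; the cohort is a pure function of the config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, templates,
                          grid_shape = c(24L, 24L, 24L),
                          brain_mask = NULL,
                          confound_coeffs = c(age = -0.002, sex = -0.01,
                                              education = 0.001,
                                              field = 0.005),
                          voxel_noise_sd = 0.02,
                          adas_noise_sd = 2,
                          template_probs = NULL,
                          apoe_carrier_prob = c(NC = 0.273, MCI = 0.493,
                                                AD = 0.667),
                          apoe_hom_given_carrier = c(NC = 0.094, MCI = 0.216,
                                                     AD = 0.309),
                          noise_smooth_sd = 0,
                          rng_seed = 1L) {
  stopifnot(n_subjects >= 2, length(grid_shape) == 3, all(grid_shape >= 4),
            voxel_noise_sd >= 0, adas_noise_sd >= 0, noise_smooth_sd >= 0,
            length(templates) >= 1,
            all(vapply(templates, inherits, logical(1), "phenotype_template")),
            all(c("age", "sex", "education", "field") %in%
                  names(confound_coeffs)))
  if (is.null(brain_mask)) brain_mask <- ellipsoid_mask(grid_shape)
  stopifnot(is.logical(brain_mask), all(dim(brain_mask) == grid_shape),
            sum(brain_mask) >= 1)
  if (is.null(template_probs)) {
    template_probs <- rep(1 / length(templates), length(templates))
  }
  stopifnot(length(template_probs) == length(templates),
            abs(sum(template_probs) - 1) < 1e-8)
  for (tpl in templates) {
    if (!all(dim(tpl$atrophy_mask) == grid_shape)) {
      stop("template '", tpl$name, "': atrophy mask grid does not match ",
           "`grid_shape`")
    }
    if (!any(tpl$atrophy_mask)) {
      stop("template '", tpl$name, "': atrophy mask is empty")
    }
    if (any(tpl$atrophy_mask & !brain_mask)) {
      stop("template '", tpl$name, "': atrophy mask extends outside the ",
           "brain mask")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), grid_shape = grid_shape,
         brain_mask = brain_mask, templates = templates,
         confound_coeffs = confound_coeffs,
         voxel_noise_sd = voxel_noise_sd, adas_noise_sd = adas_noise_sd,
         template_probs = template_probs,
         apoe_carrier_prob = apoe_carrier_prob,
         apoe_hom_given_carrier = apoe_hom_given_carrier,
         noise_smooth_sd = noise_smooth_sd,
         rng_seed = as.integer(rng_seed)),
    class = "cohort_config"
  )
}

# Smooth radial GM baseline: 0.3 at the mask edge rising to 0.7 centrally.
# Values stay well inside [0, 1] so clipping is driven by noise only.
gm_baseline_map <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  semi <- (grid_shape - 1) / 2
  ax <- (seq_len(grid_shape[1]) - ctr[1]) / semi[1]
  ay <- (seq_len(grid_shape[2]) - ctr[2]) / semi[2]
  az <- (seq_len(grid_shape[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  0.3 + 0.4 * exp(-r2 / 0.5)
}

# Separable Gaussian smoothing of a 3D array (used for optional spatially
# correlated noise).
smooth3d <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  for (d in 1:3) {
    x <- apply(x, setdiff(1:3, d), function(v) {
      stats::filter(c(rev(v[seq_len(half)]), v, rev(tail(v, half))),
                    k, sides = 2)[(half + 1):(half + length(v))]
    })
    x <- aperm(x, order(c(d, setdiff(1:3, d))))
  }
  x
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate one ADAS-cog trajectory
#'
#' Draws a per-subject progression slope from
#' Normal(`adas_slope_mean`, `adas_slope_sd`^2) and emits visit scores
#' `adas(month) = baseline + slope * month + noise`, floored at 0 (ADAS
#' scores cannot be negative).
#'
#' @param baseline Baseline ADAS score (points).
#' @param slope_mean,slope_sd Slope distribution (points/month).
#' @param noise_sd Per-visit measurement noise SD (points).
#' @param months Visit schedule (default `c(0, 12, 24, 36)`).
#' @return A tibble with columns `month`, `adas` and the drawn `slope`
#'   (constant per subject).
#' @examples
#' simulate_adas(20, 0.5, 0, 0) # exact line: 20, 26, 32, 38
#' @export
simulate_adas <- function(baseline, slope_mean, slope_sd = 0, noise_sd = 0,
                          months = c(0, 12, 24, 36)) {
  stopifnot(is.finite(baseline), is.finite(slope_mean), slope_sd >= 0,
            noise_sd >= 0, length(months) >= 1)
  slope <- rnorm(1, slope_mean, slope_sd)
  adas <- pmax(0, baseline + slope * months + rnorm(length(months), 0, noise_sd))
  tibble::tibble(month = months, adas = adas, slope = slope)
}

# One-stage-at-a-time clinical progression under a per-month hazard.
simulate_dx_path <- function(baseline_dx, hazard, months) {
  dx <- integer(length(months))
  dx[1] <- baseline_dx
  for (i in seq_along(months)[-1]) {
    cur <- dx[i - 1]
    gap <- months[i] - months[i - 1]
    if (cur < 3 && runif(1) < 1 - (1 - hazard)^gap) cur <- cur + 1L
    dx[i] <- cur
  }
  dx
}

#' Simulate a synthetic cohort with planted atrophy subtypes
#'
#' Generates, for each subject, a GM density volume
#' `v(x) = baseline(x) + b_age*age + b_sex*sex + b_edu*education +
#' b_field*field - severity * atrophy_mask(x) + noise`, clipped to \[0, 1\],
#' together with demographics, APOE e4 genotype and a longitudinal
#' ADAS/diagnosis trajectory driven by the subject's (hidden) template. The
#' result is fully determined by the config, including its `rng_seed`.
#'
#' @param config A [cohort_config()].
#' @return A list with elements:
#'   * `subjects`: tibble, one row per subject (`id`, `true_subtype`,
#'     `baseline_dx` coded NC = 1 / MCI = 2 / AD = 3, `age`, `sex`
#'     (0 = male, 1 = female), `education`, `field_strength` (0 = 1.5T,
#'     1 = 3T), `apoe4_count`).
#'   * `visits`: long tibble (`id`, `month`, `adas`, `dx`).
#'   * `volumes`: named list of 3D arrays (GM density in \[0, 1\]).
#'   * `mask`: the brain mask (logical 3D array).
#'   * `clip_fraction`: fraction of in-mask voxel values clipped to \[0, 1\].
#' @examples
#' msk <- ellipsoid_mask(c(8, 8, 8))
#' tpl <- phenotype_template("flat", msk, 0, 10, 0, 0, c(1, 0, 0))
#' ch <- simulate_cohort(cohort_config(4, list(tpl), c(8, 8, 8),
#'                                     rng_seed = 7))
#' ch$subjects
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$rng_seed)
  n <- config$n_subjects
  gs <- config$grid_shape
  mask <- config$brain_mask
  base <- gm_baseline_map(gs)
  cc <- config$confound_coeffs

  tpl_idx <- sample.int(length(config$templates), n, replace = TRUE,
                        prob = config$template_probs)
  ids <- sprintf("s%03d", seq_len(n))
  age <- rtruncnorm1(n, 73, 7, 55, 90)
  sex <- rbinom(n, 1, 0.5)
  education <- rnorm(n, 16, 2)
  field <- rbinom(n, 1, 0.5)

  baseline_dx <- integer(n)
  apoe4 <- integer(n)
  for (i in seq_len(n)) {
    mix <- config$templates[[tpl_idx[i]]]$diagnosis_mix
    baseline_dx[i] <- sample.int(3, 1, prob = mix)
    carrier <- runif(1) < config$apoe_carrier_prob[baseline_dx[i]]
    apoe4[i] <- if (!carrier) 0L else {
      if (runif(1) < config$apoe_hom_given_carrier[baseline_dx[i]]) 2L else 1L
    }
  }

  volumes <- vector("list", n)
  names(volumes) <- ids
  n_clipped <- 0
  for (i in seq_len(n)) {
    tpl <- config$templates[[tpl_idx[i]]]
    drift <- cc["age"] * age[i] + cc["sex"] * sex[i] +
      cc["education"] * education[i] + cc["field"] * field[i]
    vol <- base + drift - tpl$severity * tpl$atrophy_mask
    if (config$voxel_noise_sd > 0) {
      eps <- array(rnorm(prod(gs), 0, config$voxel_noise_sd), dim = gs)
      if (config$noise_smooth_sd > 0) eps <- smooth3d(eps, config$noise_smooth_sd)
      vol <- vol + eps
    }
    n_clipped <- n_clipped + sum(vol[mask] < 0 | vol[mask] > 1)
    vol[vol < 0] <- 0
    vol[vol > 1] <- 1
    vol[!mask] <- 0
    volumes[[i]] <- vol
  }

  months <- c(0, 12, 24, 36)
  visits <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- config$templates[[tpl_idx[i]]]
    traj <- simulate_adas(tpl$adas_baseline_mean, tpl$adas_slope_mean,
                          tpl$adas_slope_sd, config$adas_noise_sd, months)
    dx <- simulate_dx_path(baseline_dx[i], tpl$conversion_hazard, months)
    visits[[i]] <- tibble::tibble(id = ids[i], month = months,
                                  adas = traj$adas, dx = dx)
  }

  subjects <- tibble::tibble(
    id = ids,
    true_subtype = vapply(config$templates[tpl_idx], `[[`, character(1),
                          "name"),
    baseline_dx = baseline_dx,
    age = age, sex = sex, education = education, field_strength = field,
    apoe4_count = apoe4
  )

  list(subjects = subjects,
       visits = dplyr::bind_rows(visits),
       volumes = volumes,
       mask = mask,
       clip_fraction = n_clipped / (n * sum(mask)))
}

#' Reference synthetic study designs
#'
#' Ready-made cohort configurations used throughout the package's examples
#' and validation:
#'
#' * `example_subtype_config()` — three well-separated phenotype templates
#'   (atrophy severity 0.12 = 6x the voxel noise SD of 0.02) whose diagnosis
#'   mixtures land the resulting clusters in the NC, MCI and AD bands; the
#'   benchmark for planted-subtype recovery.
#' * `example_category_config()` — twelve templates, four per diagnosis
#'   category, with within-category ADAS-slope spread kept small relative to
#'   the between-category gaps (NC near 0, MCI near 0.19, AD near 0.5
#'   points/month) so that category-level slope CIs emulate the ordered,
#'   non-overlapping intervals seen in elderly memory-cohort analyses.
#'   Atrophy regions are non-overlapping balls on a symmetric lattice
#'   inside the ellipsoidal mask.
#'
#' @param n_subjects Cohort size (defaults: 120 and 240).
#' @param grid_shape Voxel grid (default `c(16, 16, 16)`).
#' @param rng_seed Seed for [simulate_cohort()].
#' @return A [cohort_config()].
#' @export
example_subtype_config <- function(n_subjects = 120,
                                   grid_shape = c(16L, 16L, 16L),
                                   rng_seed = 1L) {
  msk <- ellipsoid_mask(grid_shape)
  r <- 3.5 * min(grid_shape / 16)   # atrophy ball sized on a 16^3 grid
  tpls <- list(
    phenotype_template("nc_like",
                       spherical_region(grid_shape, grid_shape * c(0.3, 0.5, 0.5),
                                        r, msk),
                       severity = 0.12, adas_baseline_mean = 8,
                       adas_slope_mean = 0, adas_slope_sd = 0.02,
                       diagnosis_mix = c(0.85, 0.15, 0),
                       conversion_hazard = 0.002),
    phenotype_template("mci_like",
                       spherical_region(grid_shape, grid_shape * c(0.7, 0.5, 0.5),
                                        r, msk),
                       severity = 0.12, adas_baseline_mean = 17,
                       adas_slope_mean = 0.19, adas_slope_sd = 0.05,
                       diagnosis_mix = c(0.1, 0.85, 0.05),
                       conversion_hazard = 0.01),
    phenotype_template("ad_like",
                       spherical_region(grid_shape, grid_shape * c(0.5, 0.7, 0.5),
                                        r, msk),
                       severity = 0.12, adas_baseline_mean = 30,
                       adas_slope_mean = 0.5, adas_slope_sd = 0.08,
                       diagnosis_mix = c(0.02, 0.18, 0.8),
                       conversion_hazard = 0.01)
  )
  cohort_config(n_subjects, tpls, grid_shape, brain_mask = msk,
                rng_seed = rng_seed)
}

#' @rdname example_subtype_config
#' @export
example_category_config <- function(n_subjects = 240,
                                    grid_shape = c(16L, 16L, 16L),
                                    rng_seed = 1L) {
  msk <- ellipsoid_mask(grid_shape)
  offs <- rbind(c(3, 3, 0), c(-3, 3, 0), c(3, -3, 0), c(-3, -3, 0),
                c(3, 0, 3), c(-3, 0, 3), c(3, 0, -3), c(-3, 0, -3),
                c(0, 3, 3), c(0, -3, 3), c(0, 3, -3), c(0, -3, -3))
  scale <- grid_shape / 16      # lattice designed on a 16^3 grid
  centers <- sweep(offs * rep(scale, each = nrow(offs)), 2,
                   (grid_shape + 1) / 2, `+`)
  mixes <- list(c(0.85, 0.15, 0), c(0.1, 0.85, 0.05), c(0.02, 0.18, 0.8))
  base_adas <- c(8, 17, 30)
  slope_means <- list(c(-0.02, 0, 0.01, 0.02),
                      c(0.15, 0.17, 0.21, 0.23),
                      c(0.42, 0.47, 0.53, 0.58))
  names_cat <- c("nc", "mci", "ad")
  tpls <- list()
  for (cat_i in 1:3) {
    for (rep_i in 1:4) {
      idx <- (cat_i - 1) * 4 + rep_i
      tpls[[idx]] <- phenotype_template(
        sprintf("%s_%d", names_cat[cat_i], rep_i),
        spherical_region(grid_shape, centers[idx, ], 2.8 * min(scale), msk),
        severity = 0.12, adas_baseline_mean = base_adas[cat_i],
        adas_slope_mean = slope_means[[cat_i]][rep_i],
        adas_slope_sd = 0.05, diagnosis_mix = mixes[[cat_i]])
    }
  }
  cohort_config(n_subjects, tpls, grid_shape, brain_mask = msk,
                rng_seed = rng_seed)
}
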