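# Shared synthetic fixtures, built in code at test time.

# Three well-separated phenotype templates (severity = 6x the default noise
# SD) whose diagnosis mixtures put the resulting clusters into the NC, MCI
# and AD bands respectively.
three_templates <- function(gs, msk) {
  list(
    phenotype_template("nc_like",
                       spherical_region(gs, gs * c(0.3, 0.5, 0.5), 2.5, msk),
                       severity = 0.12, adas_baseline_mean = 8,
                       adas_slope_mean = 0, adas_slope_sd = 0.02,
                       diagnosis_mix = c(0.8, 0.2, 0),
                       conversion_hazard = 0.002),
    phenotype_template("mci_like",
                       spherical_region(gs, gs * c(0.7, 0.5, 0.5), 2.5, msk),
                       severity = 0.12, adas_baseline_mean = 17,
                       adas_slope_mean = 0.19, adas_slope_sd = 0.05,
                       diagnosis_mix = c(0.2, 0.7, 0.1),
                       conversion_hazard = 0.01),
    phenotype_template("ad_like",
                       spherical_region(gs, gs * c(0.5, 0.7, 0.5), 2.5, msk),
                       severity = 0.12, adas_baseline_mean = 30,
                       adas_slope_mean = 0.5, adas_slope_sd = 0.08,
                       diagnosis_mix = c(0.05, 0.25, 0.7),
                       conversion_hazard = 0.01)
  )
}

small_cohort_config <- function(n = 60, gs = c(16, 16, 16), seed = 42, ...) {
  msk <- ellipsoid_mask(gs)
  cohort_config(n, three_templates(gs, msk), gs, brain_mask = msk,
                rng_seed = seed, ...)
}

# A flat single-template config: no atrophy contrast, NC-only diagnoses.
flat_cohort_config <- function(n, gs = c(12, 12, 12), seed = 1, ...) {
  msk <- ellipsoid_mask(gs)
  tpl <- phenotype_template("flat", msk, severity = 0,
                            adas_baseline_mean = 10, adas_slope_mean = 0,
                            adas_slope_sd = 0, diagnosis_mix = c(1, 0, 0))
  cohort_config(n, list(tpl), gs, brain_mask = msk, rng_seed = seed, ...)
}

# Cluster labels aligned to the subject table order.
aligned_labels <- function(subjects, assignment) {
  assignment$cluster[match(subjects$id, assignment$id)]
}
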