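# Cluster characterization statistics, checked against printed worked
# examples and closed-form oracles.

test_that("weighted-average diagnosis reproduces worked examples", {
  expect_equal(round(average_diagnosis(18, 22, 0), 2), 1.55)
  expect_equal(round(average_diagnosis(17, 15, 4), 2), 1.64)
  expect_equal(average_diagnosis(17, 15, 4), 59 / 36)
  expect_equal(average_diagnosis(5, 0, 0), 1)
  expect_equal(average_diagnosis(0, 0, 9), 3)
  expect_error(average_diagnosis(0, 0, 0), "empty")
})

test_that("category bands use exact fractions and partition [1, 3]", {
  expect_equal(as.character(categorize_cluster(1.55)), "NC")
  expect_equal(as.character(categorize_cluster(2)), "MCI")
  expect_equal(as.character(categorize_cluster(7 / 3)), "AD")
  expect_equal(as.character(categorize_cluster(5 / 3)), "MCI")
  expect_equal(as.character(categorize_cluster(5 / 3 - 1e-9)), "NC")
  expect_error(categorize_cluster(0.5), "outside")
  # no gaps, no overlaps across a fine grid
  grid <- seq(1, 3, by = 1e-3)
  cats <- categorize_cluster(grid)
  expect_false(anyNA(cats))
  expect_equal(sum(rle(as.character(cats))$lengths > 0), 3)
})

test_that("ADAS slopes match exact lines and the closed-form OLS oracle", {
  expect_equal(adas_slope(c(0, 12, 24, 36), c(10, 12, 14, 16)), 1 / 6)
  expect_equal(adas_slope(c(0, 36), c(20, 20)), 0)
  m <- c(0, 12, 24, 36); y <- c(10, 15, 12, 19)
  oracle <- sum((m - mean(m)) * (y - mean(y))) / sum((m - mean(m))^2)
  expect_equal(adas_slope(m, y), oracle)
  expect_equal(adas_slope(m, y), unname(coef(lm(y ~ m))[2]))
  # < 2 usable visits: flagged NA, not an error
  expect_true(is.na(adas_slope(0, 10)))
  expect_true(is.na(adas_slope(c(0, 12), c(10, NA))))
  vis <- tibble::tibble(id = c("a", "a", "b"), month = c(0, 12, 0),
                        adas = c(10, 13, 20))
  sl <- adas_slopes(vis)
  expect_equal(sl$adas_slope[sl$id == "a"], 0.25)
  expect_true(is.na(sl$adas_slope[sl$id == "b"]))
})

test_that("declining status counts only forward transitions from baseline", {
  subj <- tibble::tibble(id = sprintf("p%d", 1:8),
                         baseline_dx = c(2, 2, 2, 2, 2, 2, 2, 2))
  vis <- tidyr::expand_grid(id = subj$id, month = c(0, 12, 24, 36)) |>
    dplyr::mutate(dx = 2)
  expect_equal(declining_status_rate(subj, vis), 0)
  vis$dx[vis$id %in% c("p1", "p2") & vis$month == 24] <- 3
  expect_equal(declining_status_rate(subj, vis), 25)
  # reversion (dx lower than baseline) never counts
  vis$dx[vis$id == "p3" & vis$month == 36] <- 1
  expect_equal(declining_status_rate(subj, vis), 25)
  # a subject with no follow-up counts as non-declining
  vis2 <- vis[!(vis$id == "p4" & vis$month > 0), ]
  expect_equal(declining_status_rate(subj, vis2), 25)
})

test_that("APOE prevalence reproduces the printed per-diagnosis rates", {
  expect_equal(round(apoe_prevalence(rep(0:2, c(311, 106, 11))), 1), 27.3)
  expect_equal(round(apoe_prevalence(rep(0:2, c(381, 290, 80))), 1), 49.3)
  expect_equal(round(apoe_prevalence(rep(0:2, c(94, 130, 58))), 1), 66.7)
  expect_equal(apoe_prevalence(c(0, 0, 0)), 0)
})

test_that("chi-squared association matches the direct formula and flags degenerate tables", {
  tab <- rbind(c(311, 106, 11), c(381, 290, 80), c(94, 130, 58))
  res <- apoe_diagnosis_association(tab)
  expect_equal(res$df, 4)
  expect_lt(res$p_value, 0.001)
  # independence: a table exactly proportional to its margins
  ind <- outer(c(10, 20, 30), c(1, 2, 3))
  res_ind <- apoe_diagnosis_association(ind)
  expect_equal(res_ind$statistic, 0)
  expect_equal(res_ind$p_value, 1)
  # random table vs the sum((O-E)^2/E) hand formula
  set.seed(9)
  r <- matrix(rpois(9, 20) + 1, 3, 3)
  e <- outer(rowSums(r), colSums(r)) / sum(r)
  expect_equal(apoe_diagnosis_association(r)$statistic,
               sum((r - e)^2 / e))
  expect_error(apoe_diagnosis_association(rbind(c(0, 0, 0), c(1, 2, 3),
                                                c(4, 5, 6))), "zero row")
})

test_that("category slope CIs match the closed-form t interval", {
  mk_summary <- function(slopes, category = "AD") {
    tibble::tibble(cluster = seq_along(slopes), n = 10,
                   mean_adas_slope = slopes,
                   category = factor(category, levels = c("NC", "MCI", "AD")),
                   reportable = TRUE)
  }
  # two clusters: CI = mean +/- t_{0.975,1} * sd/sqrt(2)
  ci <- category_slope_ci(mk_summary(c(0.1, 0.3)))
  expect_equal(ci$mean_slope, 0.2)
  half <- qt(0.975, 1) * sd(c(0.1, 0.3)) / sqrt(2)
  expect_equal(ci$ci_lo, 0.2 - half)
  expect_equal(ci$ci_hi, 0.2 + half)
  expect_equal(qt(0.975, 1), 12.7062, tolerance = 1e-4)
  # identical slopes: degenerate zero-width interval
  ci0 <- category_slope_ci(mk_summary(c(0.25, 0.25, 0.25)))
  expect_equal(ci0$ci_lo, 0.25)
  expect_equal(ci0$ci_hi, 0.25)
  # single cluster: NA interval with a warning
  expect_warning(ci1 <- category_slope_ci(mk_summary(0.4)), "< 2")
  expect_true(is.na(ci1$ci_lo))
})

test_that("the t interval covers the true mean at the nominal rate", {
  set.seed(41)
  mu <- 0.3
  hits <- replicate(1000, {
    slopes <- rnorm(6, mu, 0.1)
    half <- qt(0.975, 5) * sd(slopes) / sqrt(6)
    abs(mean(slopes) - mu) <= half
  })
  # binomial 3 SE band around 0.95 with 1000 replicates
  expect_lt(abs(mean(hits) - 0.95), 3 * sqrt(0.95 * 0.05 / 1000))
})

test_that("cluster summaries reconcile counts and are subject-order invariant", {
  cfg <- small_cohort_config(n = 40, gs = c(10, 10, 10), seed = 33)
  ch <- simulate_cohort(cfg)
  assignment <- tibble::tibble(
    id = ch$subjects$id,
    cluster = as.integer(factor(ch$subjects$true_subtype)),
    reportable = TRUE
  )
  cs <- summarize_clusters(ch$subjects, ch$visits, assignment)
  expect_equal(cs$n, cs$females + cs$males)
  expect_equal(cs$n, cs$n_nc + cs$n_mci + cs$n_ad)
  expect_true(all(cs$apoe_prevalence >= 0 & cs$apoe_prevalence <= 100))
  expect_true(all(cs$declining_status >= 0 & cs$declining_status <= 100))
  expect_true(all(cs$average_diagnosis >= 1 & cs$average_diagnosis <= 3))
  # permuting subject order changes nothing
  perm <- sample(nrow(ch$subjects))
  cs2 <- summarize_clusters(ch$subjects[perm, ], ch$visits,
                            assignment[sample(nrow(assignment)), ])
  expect_equal(cs, cs2)
  # report formatting rounds to the documented precision
  fmt <- format_cluster_summary(cs)
  expect_equal(fmt$average_diagnosis, round(cs$average_diagnosis, 2))
  expect_equal(fmt$apoe_prevalence, round(cs$apoe_prevalence, 1))
})

test_that("adjusted Rand index agrees with the contingency-table formula", {
  set.seed(51)
  for (rep in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
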