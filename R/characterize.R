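# Per-cluster clinical characterization: weighted-average diagnosis and its
# three-band categorization, APOE e4 prevalence, declining-status rate,
# per-subject ADAS-cog slopes and category-level slope confidence intervals.

#' Weighted-average diagnosis of a cluster
#'
#' Clinical status is coded NC = 1, MCI = 2, AD = 3; the cluster average is
#' `(1*n_nc + 2*n_mci + 3*n_ad) / n`.
#'
#' @param n_nc,n_mci,n_ad Baseline diagnosis counts (vectorized).
#' @return Average diagnosis in \[1, 3\].
#' @examples
#' average_diagnosis(18, 22, 0) # 1.55
#' @export
average_diagnosis <- function(n_nc, n_mci, n_ad) {
  stopifnot(all(n_nc >= 0), all(n_mci >= 0), all(n_ad >= 0))
  n <- n_nc + n_mci + n_ad
  if (any(n < 1)) stop("empty cluster: diagnosis counts sum to 0")
  (n_nc + 2 * n_mci + 3 * n_ad) / n
}

#' Categorize a cluster by its average diagnosis
#'
#' The interval \[1, 3\] is split into three equal bands: NC below 5/3, MCI
#' from 5/3 up to (but excluding) 7/3, AD at 7/3 and above. Exact fractions
#' are used, with ties going to the higher band.
#'
#' @param avg Average diagnosis values in \[1, 3\] (vectorized).
#' @return Factor with levels NC, MCI, AD.
#' @examples
#' categorize_cluster(c(1.55, 2, 7 / 3))
#' @export
categorize_cluster <- function(avg) {
  if (any(avg < 1 - 1e-12 | avg > 3 + 1e-12)) {
    stop("average diagnosis outside [1, 3]")
  }
  factor(ifelse(avg < 5 / 3, "NC", ifelse(avg < 7 / 3, "MCI", "AD")),
         levels = c("NC", "MCI", "AD"))
}

#' Per-subject ADAS progression slope
#'
#' `adas_slope()` is the OLS slope of ADAS score on month for one subject;
#' `adas_slopes()` maps it over a long visit table. Subjects with fewer
#' than 2 usable visits get `NA` (they stay in their cluster but are
#' excluded from slope statistics).
#'
#' @param month,adas Visit months and scores for one subject.
#' @return `adas_slope()`: slope in points/month (or `NA`).
#' @examples
#' adas_slope(c(0, 12, 24, 36), c(10, 12, 14, 16)) # 1/6
#' @export
adas_slope <- function(month, adas) {
  ok <- is.finite(month) & is.finite(adas)
  month <- month[ok]; adas <- adas[ok]
  if (length(month) < 2 || length(unique(month)) < 2) return(NA_real_)
  sum((month - mean(month)) * (adas - mean(adas))) /
    sum((month - mean(month))^2)
}

#' @rdname adas_slope
#' @param visits Long tibble with columns `id`, `month`, `adas`.
#' @return `adas_slopes()`: tibble `id`, `adas_slope`, `n_visits`.
#' @export
adas_slopes <- function(visits) {
  stopifnot(all(c("id", "month", "adas") %in% names(visits)))
  visits |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      adas_slope = adas_slope(.data$month, .data$adas),
      n_visits = sum(is.finite(.data$adas)),
      .groups = "drop"
    )
}

#' Percentage of subjects with worsening clinical status
#'
#' A subject declines when any follow-up diagnosis code exceeds the
#' baseline code — i.e. only NC-to-MCI/AD and MCI-to-AD transitions count
#' (AD cannot worsen on this scale). Subjects with no follow-up visits
#' count as non-declining.
#'
#' @param baseline_dx Named-by-`id` or positional baseline codes, or a
#'   subjects tibble with `id`, `baseline_dx`.
#' @param visits Long tibble with `id`, `month`, `dx`.
#' @return Percentage in \[0, 100\].
#' @export
declining_status_rate <- function(baseline_dx, visits) {
  if (is.data.frame(baseline_dx)) {
    subj <- baseline_dx
  } else {
    subj <- tibble::tibble(id = names(baseline_dx), baseline_dx = baseline_dx)
  }
  stopifnot(all(c("id", "baseline_dx") %in% names(subj)),
            all(c("id", "month", "dx") %in% names(visits)))
  dec <- visits |>
    dplyr::filter(.data$month > 0, is.finite(.data$dx)) |>
    dplyr::inner_join(subj[, c("id", "baseline_dx")], by = "id") |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(declined = any(.data$dx > .data$baseline_dx),
                     .groups = "drop")
  n_dec <- sum(dec$declined[match(subj$id, dec$id)], na.rm = TRUE)
  100 * n_dec / nrow(subj)
}

#' APOE e4 prevalence (at least one allele)
#'
#' @param apoe4_count Integer allele counts (0, 1 or 2).
#' @return Percentage of carriers.
#' @examples
#' apoe_prevalence(rep(c(0, 1, 2), c(311, 106, 11))) # 27.3% after rounding
#' @export
apoe_prevalence <- function(apoe4_count) {
  stopifnot(length(apoe4_count) >= 1, all(apoe4_count %in% 0:2))
  100 * mean(apoe4_count >= 1)
}

#' Chi-squared test of APOE-diagnosis association
#'
#' Pearson chi-squared test of independence (no continuity correction) on a
#' 3 x 3 table of baseline diagnosis (rows) by APOE e4 allele count
#' (columns), df = 4.
#'
#' @param tab 3 x 3 matrix of non-negative integer counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
apoe_diagnosis_association <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(3, 3)), all(tab >= 0),
            all(abs(tab - round(tab)) < 1e-9))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero row or column margin")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' Per-cluster summary table
#'
#' One row per cluster with the standard characterization columns:
#' composition (sex and baseline-diagnosis counts), average diagnosis and
#' its category, APOE e4 prevalence, declining-status rate, mean education /
#' baseline ADAS / age, and the mean and SD of per-subject ADAS slopes.
#' Sex is coded 0 = male, 1 = female.
#'
#' @param subjects Subjects tibble (`id`, `baseline_dx`, `age`, `sex`,
#'   `education`, `apoe4_count`).
#' @param visits Long visit tibble (`id`, `month`, `adas`, `dx`).
#' @param assignment [cut_clusters()] output (`id`, `cluster`,
#'   `reportable`).
#' @return A tibble, one row per cluster, ordered by cluster id.
#' @export
summarize_clusters <- function(subjects, visits, assignment) {
  stopifnot(all(subjects$id %in% assignment$id))
  slopes <- adas_slopes(visits)
  base_adas <- visits |>
    dplyr::filter(.data$month == 0) |>
    dplyr::select("id", baseline_adas = "adas")
  df <- subjects |>
    dplyr::inner_join(assignment, by = "id") |>
    dplyr::left_join(slopes, by = "id") |>
    dplyr::left_join(base_adas, by = "id")

  per_cluster <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      females = sum(.data$sex == 1),
      males = sum(.data$sex == 0),
      n_nc = sum(.data$baseline_dx == 1),
      n_mci = sum(.data$baseline_dx == 2),
      n_ad = sum(.data$baseline_dx == 3),
      average_diagnosis = average_diagnosis(n_nc, n_mci, n_ad),
      apoe_prevalence = apoe_prevalence(.data$apoe4_count),
      mean_education = mean(.data$education),
      mean_baseline_adas = mean(.data$baseline_adas, na.rm = TRUE),
      mean_age = mean(.data$age),
      mean_adas_slope = mean(.data$adas_slope, na.rm = TRUE),
      sd_adas_slope = sd(.data$adas_slope, na.rm = TRUE),
      reportable = .data$reportable[1],
      .groups = "drop"
    )
  decl <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(~ tibble::tibble(
      declining_status = declining_status_rate(.x, visits)
    )) |>
    dplyr::ungroup()
  per_cluster |>
    dplyr::left_join(decl, by = "cluster") |>
    dplyr::mutate(category = categorize_cluster(.data$average_diagnosis)) |>
    dplyr::select("cluster", "n", "females", "males", "n_nc", "n_mci",
                  "n_ad", "average_diagnosis", "category",
                  "apoe_prevalence", "declining_status", "mean_education",
                  "mean_baseline_adas", "mean_age", "mean_adas_slope",
                  "sd_adas_slope", "reportable") |>
    dplyr::arrange(.data$cluster)
}

#' Category-level confidence intervals for mean ADAS slopes
#'
#' For each diagnosis category (NC, MCI, AD), a two-sided 95% t-interval for
#' the mean of the reportable clusters' mean ADAS slopes, unweighted, with
#' (number of clusters - 1) degrees of freedom. Categories with fewer than
#' 2 reportable clusters get an `NA` interval with a warning.
#'
#' @param cluster_summary [summarize_clusters()] output.
#' @param level Confidence level (default 0.95).
#' @return A tibble: `category`, `n_clusters`, `mean_slope`, `ci_lo`,
#'   `ci_hi`, `method`.
#' @export
category_slope_ci <- function(cluster_summary, level = 0.95) {
  rep_cl <- cluster_summary[cluster_summary$reportable, ]
  out <- rep_cl |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_clusters = dplyr::n(),
      mean_slope = mean(.data$mean_adas_slope),
      sd_slope = sd(.data$mean_adas_slope),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      half = ifelse(.data$n_clusters >= 2,
                    qt(1 - (1 - level) / 2, .data$n_clusters - 1) *
                      .data$sd_slope / sqrt(.data$n_clusters),
                    NA_real_),
      ci_lo = .data$mean_slope - .data$half,
      ci_hi = .data$mean_slope + .data$half,
      method = "t interval, unweighted over reportable cluster mean slopes"
    ) |>
    dplyr::select("category", "n_clusters", "mean_slope", "ci_lo", "ci_hi",
                  "method")
  if (any(is.na(out$ci_lo))) {
    warning("CI omitted for categories with < 2 reportable clusters: ",
            paste(out$category[is.na(out$ci_lo)], collapse = ", "))
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions (1 = identical, ~0 =
#' chance). Used to score recovery of planted subtypes.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  r <- mclust::adjustedRandIndex(a, b)
  if (is.nan(r)) {
    # degenerate case (all singletons or a single cluster in both labelings):
    # the chance-correction denominator vanishes; equal partitions score 1
    same <- identical(as.integer(factor(a, levels = unique(a))),
                      as.integer(factor(b, levels = unique(b))))
    r <- if (same) 1 else 0
  }
  r
}

#' Round a cluster summary for reporting
#'
#' Report-table formatting: 2 decimals for average diagnosis and slopes,
#' 1 decimal for percentages, ages, education and ADAS scores.
#'
#' @param cluster_summary [summarize_clusters()] output.
#' @return The tibble with rounded numeric columns.
#' @export
format_cluster_summary <- function(cluster_summary) {
  cluster_summary |>
    dplyr::mutate(
      dplyr::across(dplyr::any_of(c("average_diagnosis", "mean_adas_slope",
                                    "sd_adas_slope")), ~ round(.x, 2)),
      dplyr::across(dplyr::any_of(c("apoe_prevalence", "declining_status",
                                    "mean_education", "mean_baseline_adas",
                                    "mean_age")), ~ round(.x, 1))
    )
}
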