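# End-to-end orchestration: simulate (or load) -> residualize -> distances ->
# complete linkage -> cut -> characterize -> selected t-maps, with a hashed
# run manifest for reproducibility.

#' Configure a pipeline run
#'
#' @param mode `"synthetic"` (generate a cohort from `cohort`) or `"real"`
#'   (load NIfTI volumes and CSV tables from the given paths).
#' @param output_dir Directory for all artifacts (created if needed).
#' @param cohort A [cohort_config()] (synthetic mode).
#' @param volumes_dir,mask_path,subject_csv,visits_csv Input paths (real
#'   mode). `mask_path` may be `NULL`, in which case a mask is built from
#'   the control subjects with [make_brain_mask()].
#' @param k Cluster count, or `"auto"` for the [suggest_k()] heuristic.
#' @param min_cluster_size Reportability threshold (default 7).
#' @param tmap_pairs List of two-element character vectors naming cluster
#'   groups to contrast; `"+"` unions cluster ids (e.g.
#'   `c("1+2", "3")` compares clusters 1 and 2 pooled against cluster 3).
#' @param var_equal Pooled (default) or Welch t-maps.
#' @param residualize_tmaps Compute t-maps on residuals (default `TRUE`) or
#'   raw densities.
#' @param write_volumes Also write per-subject NIfTI volumes (default
#'   `FALSE`; tables and t-maps are always written).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"), output_dir,
                            cohort = NULL, volumes_dir = NULL,
                            mask_path = NULL, subject_csv = NULL,
                            visits_csv = NULL, k = "auto",
                            min_cluster_size = 7, tmap_pairs = list(),
                            var_equal = TRUE, residualize_tmaps = TRUE,
                            write_volumes = FALSE) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (!inherits(cohort, "cohort_config")) {
      stop("synthetic mode requires a `cohort_config`")
    }
  } else {
    for (p in c(volumes_dir = volumes_dir, subject_csv = subject_csv,
                visits_csv = visits_csv)) {
      if (is.null(p) || !file.exists(p)) {
        stop("real mode input missing or nonexistent: ", p)
      }
    }
    if (!is.null(mask_path) && !file.exists(mask_path)) {
      stop("mask file does not exist: ", mask_path)
    }
  }
  if (!identical(k, "auto")) stopifnot(is.numeric(k), k >= 1)
  structure(list(mode = mode, output_dir = output_dir, cohort = cohort,
                 volumes_dir = volumes_dir, mask_path = mask_path,
                 subject_csv = subject_csv, visits_csv = visits_csv,
                 k = k, min_cluster_size = min_cluster_size,
                 tmap_pairs = tmap_pairs, var_equal = var_equal,
                 residualize_tmaps = residualize_tmaps,
                 write_volumes = write_volumes),
            class = "pipeline_config")
}

parse_group_spec <- function(spec, assignment) {
  cl <- as.integer(strsplit(as.character(spec), "+", fixed = TRUE)[[1]])
  if (anyNA(cl) || !all(cl %in% assignment$cluster)) {
    stop("unknown cluster id in group spec '", spec, "'")
  }
  assignment$id[assignment$cluster %in% cl]
}

#' Run the full structural-phenotyping pipeline
#'
#' Executes simulate/load, confound residualization (fitted on NC),
#' Manhattan distances, complete linkage, tree cut, cluster
#' characterization, category slope CIs and any configured t-map
#' contrasts. All artifacts are written under `output_dir` and listed, with
#' MD5 content hashes, in `manifest.json`; re-running the same config (and
#' seed) reproduces the hashes.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines (default `FALSE`).
#' @return Invisibly, a list with the in-memory results: `subjects`,
#'   `visits`, `tree`, `assignment`, `cluster_summary`,
#'   `category_summary`, `tmaps` and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  }

  if (config$mode == "synthetic") {
    cohort <- simulate_cohort(config$cohort)
    subjects <- cohort$subjects
    visits <- cohort$visits
    volumes <- cohort$volumes
    mask <- cohort$mask
    say("simulate", nrow(subjects), " subjects, ",
        sum(mask), " masked voxels")
  } else {
    volumes <- read_volumes(config$volumes_dir)
    subjects <- readr::read_csv(config$subject_csv, show_col_types = FALSE)
    visits <- readr::read_csv(config$visits_csv, show_col_types = FALSE)
    if (!is.null(config$mask_path)) {
      m <- RNifti::readNifti(config$mask_path)
      mask <- array(as.logical(m), dim = dim(m))
    } else {
      nc_ids <- subjects$id[subjects$baseline_dx == 1]
      mask <- make_brain_mask(volumes[nc_ids])
    }
    say("load", length(volumes), " volumes, ", sum(mask), " masked voxels")
  }

  vm <- extract_voxel_matrix(volumes, mask)
  nc_ids <- subjects$id[subjects$baseline_dx == 1]
  model <- fit_confound_model(vm, subjects, nc_ids)
  resid <- residualize(vm, model, subjects)
  say("residualize", "fitted on ", length(nc_ids), " controls")

  d <- manhattan_distance_matrix(resid, validate = nrow(resid) <= 500)
  tree <- complete_linkage(d)
  k <- if (identical(config$k, "auto")) suggest_k(tree) else
    as.integer(config$k)
  assignment <- cut_clusters(tree, k, config$min_cluster_size)
  say("cluster", "k = ", k, " (", sum(unique(
    assignment[c("cluster", "reportable")])$reportable),
    " reportable clusters)")

  cluster_summary <- summarize_clusters(subjects, visits, assignment)
  category_summary <- suppressWarnings(category_slope_ci(cluster_summary))
  say("characterize", nrow(cluster_summary), " clusters summarized")

  tmaps <- list()
  tmap_input <- if (config$residualize_tmaps) resid else vm
  for (pair in config$tmap_pairs) {
    ga <- parse_group_spec(pair[1], assignment)
    gb <- parse_group_spec(pair[2], assignment)
    tm <- two_sample_tmap(tmap_input, ga, gb, var_equal = config$var_equal)
    nm <- paste0("tmap_", gsub("\\+", "-", pair[1]), "_vs_",
                 gsub("\\+", "-", pair[2]))
    write_tmap(tm, file.path(out, paste0(nm, ".nii")))
    tmaps[[nm]] <- tm
    say("tmap", nm, ": ", sum(abs(tm$t) > 3), " voxels with |t| > 3")
  }

  readr::write_csv(subjects |> dplyr::left_join(assignment, by = "id"),
                   file.path(out, "subjects.csv"))
  readr::write_csv(visits, file.path(out, "visits.csv"))
  readr::write_csv(cluster_summary, file.path(out, "cluster_summary.csv"))
  readr::write_csv(category_summary, file.path(out, "category_summary.csv"))
  readr::write_csv(merge_metric_curve(tree), file.path(out, "merge_curve.csv"))
  write_merge_table(tree, file.path(out, "merge_table.txt"))
  if (config$write_volumes) {
    write_volumes(volumes, mask, file.path(out, "volumes"))
  }

  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(hashes) <- files
  manifest <- list(
    package = "vbmclust",
    version = as.character(utils::packageVersion("vbmclust")),
    mode = config$mode,
    rng_seed = if (config$mode == "synthetic") config$cohort$rng_seed else NA,
    parameters = list(k = k, min_cluster_size = config$min_cluster_size,
                      var_equal = config$var_equal,
                      residualize_tmaps = config$residualize_tmaps,
                      n_subjects = nrow(subjects),
                      n_voxels = sum(mask)),
    files = hashes
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", "manifest with ", length(hashes), " artifacts")

  invisible(list(subjects = subjects, visits = visits, mask = mask,
                 voxel_matrix = vm, residuals = resid, model = model,
                 tree = tree, assignment = assignment,
                 cluster_summary = cluster_summary,
                 category_summary = category_summary,
                 tmaps = tmaps, manifest = manifest))
}
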