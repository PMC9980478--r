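# Pipeline orchestration: one configuration object carrying every stage
# parameter next to its default, a single run_pipeline() entry point, and a
# reproducible run report.

default_params <- function() {
  list(
    blank_cutoff = 1e6,       # solvent-blank raw-area cutoff
    max_cv_percent = 10,      # pooled-QC %CV threshold
    method_blank_stat = "max",
    alpha = 0.05,             # BH FDR cutoff, strict
    noise_cutoff = 3e4,       # raw-area presence floor
    min_fraction = 0.5,       # fraction of a cell's samples for presence
    vessel_k_sd = 3,          # adaptive vessel threshold: mean + k*SD
    vessel_threshold = NA,    # absolute override (NA = adaptive)
    t1_bounds = c(1e-3, 20),  # seconds
    age_weeks = 2
  )
}

#' Pipeline configuration
#'
#' Collects every stage parameter beside its default, the input sources and
#' the seed. Inputs are either synthetic specifications
#' ([feature_table_spec()] / [phantom_spec()]) or paths to on-disk CSV /
#' NIfTI inputs; when both are `NULL` the corresponding branch is skipped.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed used for every stochastic stage.
#' @param feature_spec A [feature_table_spec()], or `NULL`.
#' @param features_csv,manifest_csv Paths to an on-disk feature table
#'   (used when `feature_spec` is `NULL`).
#' @param is_feature_id Internal-standard id for on-disk tables.
#' @param phantom A [phantom_spec()], or `NULL` to skip the MRI branch.
#' @param ... Stage-parameter overrides; anything not overridden keeps its
#'   default (see Details of [run_pipeline()]).
#' @return An object of class `bbb_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, feature_spec = NULL,
                            features_csv = NULL, manifest_csv = NULL,
                            is_feature_id = "IS_cholic_acid",
                            phantom = NULL, ...) {
  defaults <- default_params()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stopf("unknown pipeline parameter(s): %s", paste(unknown, collapse = ", "))
  }
  params <- utils::modifyList(defaults, overrides)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         feature_spec = feature_spec, features_csv = features_csv,
         manifest_csv = manifest_csv, is_feature_id = is_feature_id,
         phantom = phantom, params = params, defaults = defaults),
    class = "bbb_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file with optional keys `out_dir`, `seed`, `params`
#' (stage-parameter overrides), `feature_spec` and `phantom` (argument
#' lists for [feature_table_spec()] / [phantom_spec()]), and
#' `features_csv` / `manifest_csv` / `is_feature_id` for on-disk tables.
#'
#' @param path YAML file.
#' @param out_dir Override for the output directory.
#' @return A `bbb_pipeline_config`.
#' @export
load_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  args <- list(
    out_dir = out_dir %||% y$out_dir %||% ".",
    seed = y$seed %||% 1L,
    features_csv = y$features_csv, manifest_csv = y$manifest_csv,
    is_feature_id = y$is_feature_id %||% "IS_cholic_acid")
  if (!is.null(y$feature_spec)) {
    args$feature_spec <- do.call(feature_table_spec, y$feature_spec)
  }
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  do.call(pipeline_config, c(args, y$params %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bbb_pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> out_dir = %s, seed = %d\n", x$out_dir, x$seed))
  for (nm in names(x$params)) {
    v <- x$params[[nm]]; d <- x$defaults[[nm]]
    cat(sprintf("  %-18s %-12s (default %s)\n", nm,
                paste(format(v), collapse = ","),
                paste(format(d), collapse = ",")))
  }
  invisible(x)
}

log_stage <- function(report_env, stage, message) {
  line <- sprintf("[%s] %s", stage, message)
  report_env$log <- c(report_env$log, line)
  message(line)
}

#' Run the full analysis pipeline
#'
#' Executes, as configured: simulate (or load) a feature table -> curation
#' cascade -> per-compartment differential testing -> serum/brain pool
#' partition -> BBB-crossing classification for the LPS and L. reuteri
#' contrasts; and, when a phantom is configured, simulate -> baseline and
#' post-contrast T1 mapping -> TOF vessel segmentation -> permeability
#' index. All artifacts are written under `out_dir` (CSV/JSON/NIfTI) along
#' with a machine-readable run report; identical config + seed reproduces
#' identical stage outputs.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `bbb_run_report` (also written to
#'   `out_dir/run_report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bbb_pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  env <- new.env(); env$log <- character(0)
  stages <- list()

  ## ---- metabolomics branch -------------------------------------------
  table <- NULL
  if (!is.null(config$feature_spec)) {
    spec <- config$feature_spec
    spec$seed <- config$seed
    sim <- simulate_feature_table(spec)
    table <- sim$table
    write_feature_table(table, file.path(config$out_dir, "features_raw.csv"),
                        file.path(config$out_dir, "manifest.csv"))
    write_truth_json(sim$truth, file.path(config$out_dir, "truth_labels.json"))
    log_stage(env, "simulate", sprintf("feature table %d x %d written",
                                       nrow(table$features), nrow(table$manifest)))
    stages$simulate <- list(n_features = nrow(table$features),
                            n_samples = nrow(table$manifest))
  } else if (!is.null(config$features_csv)) {
    table <- read_feature_table(config$features_csv, config$manifest_csv,
                                config$is_feature_id)
    log_stage(env, "load", sprintf("feature table %d x %d read",
                                   nrow(table$features), nrow(table$manifest)))
    stages$load <- list(n_features = nrow(table$features),
                        n_samples = nrow(table$manifest))
  }

  if (!is.null(table)) {
    cur <- curate(table, blank_cutoff = p$blank_cutoff,
                  max_cv_percent = p$max_cv_percent,
                  method_blank_stat = p$method_blank_stat)
    for (s in cur$report$steps) {
      log_stage(env, "curate", sprintf("%s removed %d feature(s)",
                                       s$step_name, length(s$removed)))
    }
    write_curation_report(cur$report,
                          file.path(config$out_dir, "curation_report.json"))
    stages$curate <- list(n_input = cur$report$n_input,
                          n_retained = cur$report$n_retained)
    curated <- cur$table

    sig <- lapply(c(serum = "serum", brain = "brain"), function(cmp) {
      s <- significant_set(curated, cmp, age_weeks = p$age_weeks,
                           alpha = p$alpha)
      utils::write.csv(s$stats,
                       file.path(config$out_dir,
                                 sprintf("differential_%s.csv", cmp)),
                       row.names = FALSE)
      log_stage(env, "differential",
                sprintf("%s: %d significant of %d at q < %g", cmp,
                        length(s$feature_ids), nrow(s$stats), p$alpha))
      s
    })
    stages$differential <- list(serum = length(sig$serum$feature_ids),
                                brain = length(sig$brain$feature_ids))

    part <- pool_partition(sig$serum, sig$brain)
    jsonlite::write_json(unclass(part),
                         file.path(config$out_dir, "pool_partition.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    log_stage(env, "venn", sprintf("shared %d, serum-only %d, brain-only %d",
                                   length(part$shared), length(part$serum_only),
                                   length(part$brain_only)))
    stages$venn <- lapply(unclass(part), length)

    pres <- presence_calls(curated, noise_cutoff = p$noise_cutoff,
                           min_fraction = p$min_fraction,
                           age_weeks = p$age_weeks)
    crossings <- lapply(c(LPS = "LPS", Reuteri = "Reuteri"), function(tr) {
      cr <- crossing_set(pres, treated_group = tr)
      utils::write.csv(cr$evidence,
                       file.path(config$out_dir,
                                 sprintf("crossing_%s_evidence.csv", tr)),
                       row.names = FALSE)
      log_stage(env, "crossing", sprintf("%s: %d feature(s) crossed the BBB",
                                         tr, length(cr$feature_ids)))
      cr
    })
    jsonlite::write_json(lapply(crossings, `[[`, "feature_ids"),
                         file.path(config$out_dir, "crossing_sets.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    stages$crossing <- lapply(crossings, function(cr) length(cr$feature_ids))
  }

  ## ---- MRI branch -----------------------------------------------------
  if (!is.null(config$phantom)) {
    spec <- config$phantom
    spec$seed <- config$seed
    base <- simulate_relaxometry_series(spec)
    post <- simulate_post_contrast_series(spec, base$truth)
    tof <- simulate_tof_stack(spec)
    log_stage(env, "simulate-mri", sprintf("phantom %s voxels, %d TRs",
                                           paste(spec$geometry$matrix_size,
                                                 collapse = "x"),
                                           length(spec$tr_schedule)))

    base_map <- fit_t1_map(base$series, base$roi, t1_bounds = p$t1_bounds)
    post_maps <- lapply(post$replicates, fit_t1_map, roi = base$roi,
                        t1_bounds = p$t1_bounds)
    write_t1_map_nifti(base_map, file.path(config$out_dir, "t1_baseline"))
    write_t1_map_nifti(post_maps[[1]], file.path(config$out_dir, "t1_post1"))
    write_t1_map_nifti(post_maps[[2]], file.path(config$out_dir, "t1_post2"))
    log_stage(env, "fit-t1", sprintf("baseline map: %d valid voxels",
                                     sum(base_map$valid)))

    thr <- if (is.na(p$vessel_threshold)) NULL else p$vessel_threshold
    vessels <- segment_vessels(tof$stack, tof$roi, threshold = thr,
                               k_sd = p$vessel_k_sd)
    write_mask_nifti(vessels, file.path(config$out_dir, "vessel_mask.nii.gz"))
    mip <- max_intensity_projection(tof$stack, "slice")
    utils::write.csv(mip, file.path(config$out_dir, "tof_mip.csv"),
                     row.names = FALSE)
    log_stage(env, "segment-vessels", sprintf("%d vessel voxel(s)",
                                              sum(vessels$mask)))

    perm <- permeability_index(base_map, post_maps, base$roi, vessels)
    jsonlite::write_json(
      list(baseline_mean_t1 = perm$baseline_mean_t1,
           post_mean_t1 = perm$post_mean_t1, delta_t1 = perm$delta_t1,
           vessel_volume_mm3 = perm$vessel_volume, index = perm$index,
           brain_volume_mm3 = roi_volume(base$roi), n_voxels = perm$n_voxels),
      file.path(config$out_dir, "permeability.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    log_stage(env, "permeability",
              sprintf("dT1 %.4g s over %.4g mm^3 vessels -> index %.4g",
                      perm$delta_t1, perm$vessel_volume, perm$index))
    stages$mri <- list(brain_volume_mm3 = roi_volume(base$roi),
                       vessel_volume_mm3 = perm$vessel_volume,
                       baseline_mean_t1 = perm$baseline_mean_t1,
                       delta_t1 = perm$delta_t1, index = perm$index)
  }

  report <- structure(
    list(stages = stages, parameters = config$params,
         defaults = config$defaults, seed = config$seed,
         version = as.character(utils::packageVersion("bbbaxis")),
         log = env$log,
         wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "bbb_run_report")
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  report
}

#' @export
print.bbb_run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, bbbaxis %s, %.2f s\n", x$seed,
              x$version, x$wall_time_s))
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
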