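# Synthetic LC-MS feature tables with planted ground truth: blank-dominated
# features, contaminants, QC-unstable features, group-differential features
# and compartment-crossing features, over the full manifest structure the
# curation cascade expects (study samples for 4 treatment groups x 2
# compartments, solvent and method blanks, replicate pooled-QC injections
# per treatment group).

.treatments <- c("SPF", "LPS", "Reuteri", "LPS_Reuteri")

#' Feature-table specification
#'
#' Parameters of the synthetic LC-MS experiment. Defaults mirror the study
#' design at 2 weeks of age: n = 3 study samples per treatment group and
#' compartment, three solvent blanks, three method blanks, three pooled-QC
#' injections per treatment group, a cholic-acid internal standard present
#' in every sample, 2 features crossing the BBB under LPS and 14 under
#' L. reuteri. Peak areas are log-normal with a per-sample injection scale
#' factor that the internal standard tracks, so normalization is
#' non-trivial.
#'
#' @param n_features Total feature count (including the internal standard).
#' @param n_samples_per_cell Study samples per (group x compartment) cell.
#' @param n_blank_high Features planted above the solvent-blank cutoff.
#' @param n_contaminant Features flagged as known MS contaminants.
#' @param n_qc_unstable Features with pooled-QC %CV at `qc_cv_high`.
#' @param n_differential Features with a planted LPS group effect of
#'   `lfc` log2 units.
#' @param n_crossing_lps,n_crossing_reuteri Planted BBB-crossing features
#'   for the LPS / L. reuteri contrast.
#' @param is_feature_id Identifier of the internal-standard feature.
#' @param qc_cv_low,qc_cv_high Percent CV planted for stable / unstable
#'   features across pooled-QC injections.
#' @param lfc Planted log2 fold change of differential features (LPS vs
#'   the other groups).
#' @param within_sdlog Log-scale SD of within-group biological noise
#'   (0 gives the noiseless regime).
#' @param scale_sdlog Log-scale SD of the per-sample injection scale factor.
#' @param n_solvent_blank,n_method_blank Blank injection counts.
#' @param n_qc_injections Pooled-QC injections per treatment group.
#' @param age_weeks Age of the simulated study samples (2 or 12).
#' @param seed Integer seed.
#' @return An object of class `bbb_feature_table_spec`.
#' @export
feature_table_spec <- function(n_features = 400L,
                               n_samples_per_cell = 3L,
                               n_blank_high = 5L,
                               n_contaminant = 3L,
                               n_qc_unstable = 6L,
                               n_differential = 10L,
                               n_crossing_lps = 2L,
                               n_crossing_reuteri = 14L,
                               is_feature_id = "IS_cholic_acid",
                               qc_cv_low = 3,
                               qc_cv_high = 25,
                               lfc = 2,
                               within_sdlog = 0.2,
                               scale_sdlog = 0.1,
                               n_solvent_blank = 3L,
                               n_method_blank = 3L,
                               n_qc_injections = 3L,
                               age_weeks = 2,
                               seed = 1L) {
  counts <- c(n_blank_high = n_blank_high, n_contaminant = n_contaminant,
              n_qc_unstable = n_qc_unstable, n_differential = n_differential,
              n_crossing_lps = n_crossing_lps,
              n_crossing_reuteri = n_crossing_reuteri)
  for (nm in names(counts)) {
    if (!is_count(counts[[nm]])) stopf("%s must be a non-negative count", nm)
  }
  if (!is_count(n_features) || n_features < 1) stopf("n_features must be >= 1")
  if (sum(counts) + 1L > n_features) {
    stopf("planted categories (%d) plus the internal standard exceed n_features (%d)",
          sum(counts), n_features)
  }
  if (!is_count(n_samples_per_cell) || n_samples_per_cell < 1) {
    stopf("n_samples_per_cell must be >= 1")
  }
  if (!is_count(n_qc_injections) || n_qc_injections < 2) {
    stopf("n_qc_injections must be >= 2")
  }
  if (!(age_weeks %in% c(2, 12))) stopf("age_weeks must be 2 or 12")
  if (qc_cv_low < 0 || qc_cv_high <= qc_cv_low) {
    stopf("need 0 <= qc_cv_low < qc_cv_high")
  }
  structure(
    list(n_features = as.integer(n_features),
         n_samples_per_cell = as.integer(n_samples_per_cell),
         n_blank_high = as.integer(n_blank_high),
         n_contaminant = as.integer(n_contaminant),
         n_qc_unstable = as.integer(n_qc_unstable),
         n_differential = as.integer(n_differential),
         n_crossing_lps = as.integer(n_crossing_lps),
         n_crossing_reuteri = as.integer(n_crossing_reuteri),
         is_feature_id = is_feature_id,
         qc_cv_low = qc_cv_low, qc_cv_high = qc_cv_high, lfc = lfc,
         within_sdlog = within_sdlog, scale_sdlog = scale_sdlog,
         n_solvent_blank = as.integer(n_solvent_blank),
         n_method_blank = as.integer(n_method_blank),
         n_qc_injections = as.integer(n_qc_injections),
         age_weeks = age_weeks, seed = as.integer(seed)),
    class = "bbb_feature_table_spec"
  )
}

#' @export
print.bbb_feature_table_spec <- function(x, ...) {
  cat(sprintf(
    "<feature_table_spec> %d features, n=%d per cell; planted: %d blank-high, %d contaminant,\n  %d QC-unstable, %d differential, %d LPS-crossing, %d Reuteri-crossing; seed %d\n",
    x$n_features, x$n_samples_per_cell, x$n_blank_high, x$n_contaminant,
    x$n_qc_unstable, x$n_differential, x$n_crossing_lps,
    x$n_crossing_reuteri, x$seed))
  invisible(x)
}

# QC replicate multipliers with exactly the requested sample %CV
# (mean 1, sample SD cv/100 for three injections; for n != 3 the pattern is
# centred and rescaled to keep the sample CV exact).
qc_cv_pattern <- function(n, cv_percent) {
  base <- seq(-1, 1, length.out = n)
  base <- base - mean(base)
  s <- stats::sd(base)
  if (s == 0 || cv_percent == 0) return(rep(1, n))
  1 + base / s * cv_percent / 100
}

build_manifest <- function(spec) {
  rows <- list()
  for (g in .treatments) {
    for (cmp in c("serum", "brain")) {
      for (i in seq_len(spec$n_samples_per_cell)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_%d", g, cmp, i), role = "study",
          compartment = cmp, group = g, age_weeks = spec$age_weeks,
          qc_group = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_len(spec$n_solvent_blank)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("solvent_blank_%d", i), role = "solvent_blank",
      compartment = "none", group = "none", age_weeks = NA_real_,
      qc_group = NA_character_, stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_method_blank)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("method_blank_%d", i), role = "method_blank",
      compartment = "none", group = "none", age_weeks = NA_real_,
      qc_group = NA_character_, stringsAsFactors = FALSE)
  }
  for (g in .treatments) {
    for (i in seq_len(spec$n_qc_injections)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("QC_%s_%d", g, i), role = "pooled_qc",
        compartment = "none", group = "none", age_weeks = NA_real_,
        qc_group = g, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate an LC-MS feature table with planted ground truth
#'
#' Generates the full manifest (study samples, solvent and method blanks,
#' pooled-QC injections per treatment group), log-normal baseline areas, a
#' per-sample injection scale factor carried by the cholic-acid internal
#' standard, and the planted feature categories recorded in the returned
#' truth labels:
#'
#' * `blank_high` - raw area above 1E6 in the solvent blanks;
#' * `contaminant` - `contaminant_flag` set;
#' * `qc_unstable` - pooled-QC percent CV planted at `qc_cv_high`
#'   (others at `qc_cv_low`);
#' * `differential` - LPS study areas multiplied by `2^lfc`;
#' * `crossing_lps` / `crossing_reuteri` - detected in control (SPF) serum
#'   and the treated brain, absent (area 0) from control brain, the treated
#'   serum, and the other treatment's brain.
#'
#' @param spec A [feature_table_spec()].
#' @return List with `table` (a raw [feature_table()]), `truth` (data frame
#'   `feature_id`, `category`) and `spec`.
#' @export
simulate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "bbb_feature_table_spec"))
  manifest <- build_manifest(spec)
  n <- spec$n_features
  ids <- sprintf("F%04d", seq_len(n))
  ids[1] <- spec$is_feature_id

  # planted category assignment: IS first, then the planted blocks
  category <- rep("clean", n)
  category[1] <- "internal_standard"
  cursor <- 2L
  take <- function(k, label) {
    if (k > 0) {
      category[cursor:(cursor + k - 1L)] <<- label
      cursor <<- cursor + k
    }
  }
  take(spec$n_blank_high, "blank_high")
  take(spec$n_contaminant, "contaminant")
  take(spec$n_qc_unstable, "qc_unstable")
  take(spec$n_differential, "differential")
  take(spec$n_crossing_lps, "crossing_lps")
  take(spec$n_crossing_reuteri, "crossing_reuteri")

  out <- with_seed(spec$seed, {
    features <- data.frame(
      feature_id = ids,
      mz = round(stats::runif(n, 100, 1000), 4),
      rt_min = round(stats::runif(n, 0.1, 7), 3),
      putative_id = sprintf("compound_%03d", seq_len(n)),
      contaminant_flag = category == "contaminant",
      stringsAsFactors = FALSE)
    features$putative_id[1] <- "cholic acid (internal standard)"

    base <- stats::rlnorm(n, meanlog = log(5e5), sdlog = 0.5)
    base[1] <- 5e5  # internal standard

    scale <- stats::rlnorm(nrow(manifest), 0, spec$scale_sdlog)
    names(scale) <- manifest$sample_id

    areas <- matrix(0, n, nrow(manifest),
                    dimnames = list(ids, manifest$sample_id))

    study <- manifest$role == "study"
    for (j in which(study)) {
      g <- manifest$group[j]
      cmp <- manifest$compartment[j]
      a <- base
      if (spec$within_sdlog > 0) {
        a <- a * stats::rlnorm(n, 0, spec$within_sdlog)
      }
      if (g == "LPS") {
        a[category == "differential"] <- a[category == "differential"] * 2^spec$lfc
      }
      # compartment presence/absence of planted crossing features
      cl <- category == "crossing_lps"
      cr <- category == "crossing_reuteri"
      if (cmp == "serum") {
        a[cl & rep(g == "LPS", n)] <- 0
        a[cr & rep(g == "Reuteri", n)] <- 0
      } else {  # brain
        a[cl & rep(g != "LPS", n)] <- 0
        a[cr & rep(g != "Reuteri", n)] <- 0
      }
      areas[, j] <- a
    }

    # blanks: background at 1e3 everywhere; blank-high features planted at
    # 2e6 in the solvent blanks; method blanks stay at background so the
    # method-blank step is exercised by dedicated fixtures, not the simulator
    solvent <- manifest$role == "solvent_blank"
    method <- manifest$role == "method_blank"
    areas[, solvent] <- 1e3
    areas[, method] <- 1e2
    areas[category == "blank_high", solvent] <- 2e6

    # pooled QC: base level with an exact planted %CV across the injections
    # of each treatment-group pool
    for (g in .treatments) {
      cols <- manifest$sample_id[manifest$role == "pooled_qc" &
                                   !is.na(manifest$qc_group) &
                                   manifest$qc_group == g]
      lo <- qc_cv_pattern(length(cols), spec$qc_cv_low)
      hi <- qc_cv_pattern(length(cols), spec$qc_cv_high)
      for (k in seq_along(cols)) {
        mult <- ifelse(category == "qc_unstable", hi[k], lo[k])
        areas[, cols[k]] <- base * mult
      }
    }

    # internal standard tracks the per-sample injection scale exactly
    areas[1, ] <- base[1]
    areas <- sweep(areas, 2, scale, `*`)

    list(features = features, areas = areas)
  })

  table <- feature_table(out$features, manifest, out$areas,
                         is_feature_id = spec$is_feature_id)
  truth <- data.frame(feature_id = ids, category = category,
                      stringsAsFactors = FALSE)
  list(table = table, truth = truth, spec = spec)
}

#' Write ground-truth labels as JSON
#'
#' @param truth Truth data frame from [simulate_feature_table()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(split(truth$feature_id, truth$category), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
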