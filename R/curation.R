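# Five-step LC-MS feature-curation cascade with an audit trail:
# solvent-blank filter (raw areas) -> internal-standard normalization ->
# method-blank filter -> pooled-QC %CV filter -> contaminant removal.

drop_features <- function(table, removed_ids) {
  if (!length(removed_ids)) return(table)
  keep <- !(table$features$feature_id %in% removed_ids)
  feature_table(table$features[keep, , drop = FALSE], table$manifest,
                table$areas[keep, , drop = FALSE], table$is_feature_id,
                normalized = table$normalized,
                raw_areas = table$raw_areas[keep, , drop = FALSE])
}

#' Remove features detected in solvent blanks
#'
#' A feature is removed iff its raw peak area strictly exceeds `cutoff`
#' (default 1E6) in at least one solvent-blank sample. Applied before
#' normalization, on raw areas; an area of exactly the cutoff is retained.
#' With no solvent blanks in the manifest the step is a warning no-op.
#'
#' @param table A raw (un-normalized) [feature_table()].
#' @param cutoff Raw-area cutoff (default `1e6`).
#' @return List with `table` (filtered) and `removed` (feature ids).
#' @export
filter_solvent_blank <- function(table, cutoff = 1e6) {
  stopifnot(inherits(table, "bbb_feature_table"))
  if (table$normalized) stopf("solvent-blank filtering uses raw areas; table is already normalized")
  if (!is_scalar_num(cutoff) || cutoff < 0) stopf("cutoff must be >= 0")
  blanks <- sample_ids_where(table$manifest, role = "solvent_blank")
  if (!length(blanks)) {
    warnf("no solvent-blank samples in manifest; solvent-blank filter is a no-op")
    return(list(table = table, removed = character(0)))
  }
  hit <- apply(table$areas[, blanks, drop = FALSE] > cutoff, 1, any)
  removed <- table$features$feature_id[hit]
  list(table = drop_features(table, removed), removed = removed)
}

#' Normalize peak areas by the internal standard
#'
#' Divides every feature's peak area within a sample by the area of the
#' cholic-acid internal standard in that sample, so the internal standard's
#' own normalized area is 1 everywhere. Raw areas are retained in
#' `raw_areas`. Refuses a second normalization and rejects tables where the
#' internal standard is missing or non-positive in any sample, naming the
#' sample.
#'
#' @param table A raw [feature_table()] containing the internal standard.
#' @return The normalized [feature_table()].
#' @export
normalize_internal_standard <- function(table) {
  stopifnot(inherits(table, "bbb_feature_table"))
  if (table$normalized) stopf("table is already internal-standard normalized")
  is_id <- table$is_feature_id
  if (!(is_id %in% table$features$feature_id)) {
    stopf("internal standard '%s' is not present in the table", is_id)
  }
  is_area <- table$areas[is_id, ]
  bad <- is_area <= 0 | !is.finite(is_area)
  if (any(bad)) {
    stopf("internal standard non-positive in sample(s): %s",
          paste(names(is_area)[bad], collapse = ", "))
  }
  norm <- sweep(table$areas, 2, is_area, `/`)
  feature_table(table$features, table$manifest, norm, is_id,
                normalized = TRUE, raw_areas = table$raw_areas)
}

#' Remove features dominated by method blanks
#'
#' A feature is removed iff its summary normalized area over study samples
#' is less than or equal to the same summary over method-blank samples.
#' The summary statistic is the maximum by default (the most conservative
#' retention rule that still removes blank-dominated features); `"mean"`
#' compares means instead. With no method blanks the step is a warning
#' no-op. The internal standard is exempt: it is spiked into blanks and
#' samples alike, so its normalized area is identically 1 on both sides of
#' the comparison and the rule would always discard the normalization
#' anchor.
#'
#' @param table A normalized [feature_table()].
#' @param stat `"max"` (default) or `"mean"`.
#' @return List with `table` and `removed`.
#' @export
filter_method_blank <- function(table, stat = c("max", "mean")) {
  stopifnot(inherits(table, "bbb_feature_table"))
  if (!table$normalized) stopf("method-blank filtering uses normalized areas; normalize first")
  stat <- match.arg(stat)
  blanks <- sample_ids_where(table$manifest, role = "method_blank")
  study <- sample_ids_where(table$manifest, role = "study")
  if (!length(blanks)) {
    warnf("no method-blank samples in manifest; method-blank filter is a no-op")
    return(list(table = table, removed = character(0)))
  }
  if (!length(study)) stopf("no study samples in manifest")
  f <- if (stat == "max") function(m) apply(m, 1, max) else rowMeans
  study_stat <- f(table$areas[, study, drop = FALSE])
  blank_stat <- f(table$areas[, blanks, drop = FALSE])
  removed <- setdiff(table$features$feature_id[study_stat <= blank_stat],
                     table$is_feature_id)
  list(table = drop_features(table, removed), removed = removed)
}

# %CV of one feature across the injections of one QC pool; all-zero is 0
# (not detected anywhere, trivially stable), zero mean with any signal is
# unstable by convention.
qc_percent_cv <- function(x) {
  m <- mean(x)
  if (m == 0) {
    if (any(x != 0)) return(Inf)
    return(0)
  }
  100 * stats::sd(x) / m
}

#' Remove features unstable across pooled-QC injections
#'
#' For every pooled-QC group (one pool per treatment group, injected in
#' replicate through the run) the percent coefficient of variation of the
#' normalized area is computed across that pool's injections using the
#' sample (n-1) standard deviation. A feature is removed iff its %CV
#' strictly exceeds `max_cv_percent` (default 10) in any pool. An all-zero
#' feature has %CV 0; a zero-mean feature with any non-zero injection is
#' treated as unstable.
#'
#' @param table A normalized [feature_table()].
#' @param max_cv_percent Removal threshold in percent (default 10).
#' @return List with `table`, `removed`, and `cv` (features x pools matrix).
#' @export
filter_qc_cv <- function(table, max_cv_percent = 10) {
  stopifnot(inherits(table, "bbb_feature_table"))
  if (!table$normalized) stopf("QC %%CV filtering uses normalized areas; normalize first")
  if (!is_scalar_num(max_cv_percent) || max_cv_percent < 0) {
    stopf("max_cv_percent must be >= 0")
  }
  qc <- table$manifest[table$manifest$role == "pooled_qc", ]
  if (!nrow(qc)) stopf("no pooled-QC samples in manifest")
  pools <- unique(qc$qc_group)
  cv <- matrix(NA_real_, nrow(table$features), length(pools),
               dimnames = list(table$features$feature_id, pools))
  for (p in pools) {
    cols <- qc$sample_id[qc$qc_group == p]
    if (length(cols) < 2L) {
      stopf("qc_group '%s' has %d injection(s); >= 2 required", p, length(cols))
    }
    cv[, p] <- apply(table$areas[, cols, drop = FALSE], 1, qc_percent_cv)
  }
  removed <- table$features$feature_id[apply(cv > max_cv_percent, 1, any)]
  list(table = drop_features(table, removed), removed = removed, cv = cv)
}

#' Remove flagged mass-spectrometry contaminants
#'
#' Removes exactly the features whose `contaminant_flag` is set (known MS
#' contaminants and polyether polymers matched upstream; flag ingestion,
#' not spectral matching, happens here).
#'
#' @param table A [feature_table()].
#' @return List with `table` and `removed`.
#' @export
filter_contaminants <- function(table) {
  stopifnot(inherits(table, "bbb_feature_table"))
  removed <- table$features$feature_id[table$features$contaminant_flag]
  list(table = drop_features(table, removed), removed = removed)
}

#' Run the full feature-curation cascade
#'
#' Applies, in order: solvent-blank filter (raw areas, cutoff
#' `blank_cutoff`), internal-standard normalization, method-blank filter,
#' pooled-QC %CV filter, contaminant removal. Each step's removals are
#' recorded in an audit report; a feature is attributed to the first step
#' that removes it, so the removal sets are disjoint and
#' `retained + sum(removed) = input`. Running `curate()` on an
#' already-curated (normalized) table skips the raw-area steps and removes
#' nothing.
#'
#' @param table A [feature_table()].
#' @param blank_cutoff Solvent-blank raw-area cutoff (default `1e6`).
#' @param max_cv_percent Pooled-QC %CV threshold (default 10).
#' @param method_blank_stat `"max"` or `"mean"`, see [filter_method_blank()].
#' @return List with `table` (curated, normalized) and `report`
#'   (class `bbb_curation_report`).
#' @export
curate <- function(table, blank_cutoff = 1e6, max_cv_percent = 10,
                   method_blank_stat = "max") {
  stopifnot(inherits(table, "bbb_feature_table"))
  n_input <- nrow(table$features)
  steps <- list()
  add_step <- function(name, params, removed, reason) {
    steps[[length(steps) + 1L]] <<- list(
      step_name = name, parameters = params,
      removed = as.character(removed), reason = reason)
  }

  if (!table$normalized) {
    s1 <- filter_solvent_blank(table, cutoff = blank_cutoff)
    add_step("solvent_blank", list(cutoff = blank_cutoff), s1$removed,
             "raw peak area over the cutoff in at least one solvent blank")
    table <- normalize_internal_standard(s1$table)
    add_step("normalize_internal_standard",
             list(is_feature_id = table$is_feature_id), character(0),
             "areas divided by the cholic-acid internal standard per sample")
  } else {
    add_step("solvent_blank", list(cutoff = blank_cutoff), character(0),
             "skipped: table already normalized")
    add_step("normalize_internal_standard",
             list(is_feature_id = table$is_feature_id), character(0),
             "skipped: table already normalized")
  }

  s3 <- filter_method_blank(table, stat = method_blank_stat)
  add_step("method_blank", list(stat = method_blank_stat), s3$removed,
           "study-sample normalized area at or below the method-blank level")
  s4 <- filter_qc_cv(s3$table, max_cv_percent = max_cv_percent)
  add_step("qc_cv", list(max_cv_percent = max_cv_percent), s4$removed,
           "normalized-area %CV above threshold in a pooled-QC group")
  s5 <- filter_contaminants(s4$table)
  add_step("contaminants", list(), s5$removed,
           "matched known MS contaminants / polyether polymers")

  report <- structure(
    list(steps = steps, n_input = n_input,
         n_retained = nrow(s5$table$features)),
    class = "bbb_curation_report")
  validate_curation_report(report)
  list(table = s5$table, report = report)
}

validate_curation_report <- function(report) {
  removed <- lapply(report$steps, `[[`, "removed")
  all_removed <- unlist(removed)
  if (anyDuplicated(all_removed)) {
    stopf("curation report removal sets are not disjoint")
  }
  if (report$n_input != report$n_retained + length(all_removed)) {
    stopf("curation report does not conserve features: %d != %d + %d",
          report$n_input, report$n_retained, length(all_removed))
  }
  invisible(report)
}

#' @export
print.bbb_curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> %d features in, %d retained\n",
              x$n_input, x$n_retained))
  for (s in x$steps) {
    cat(sprintf("  %-28s removed %3d  (%s)\n", s$step_name,
                length(s$removed), s$reason))
  }
  invisible(x)
}

#' Write a curation report as JSON
#'
#' @param report A `bbb_curation_report` from [curate()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_curation_report <- function(report, path) {
  jsonlite::write_json(
    list(n_input = report$n_input, n_retained = report$n_retained,
         steps = lapply(report$steps, function(s) {
           list(step_name = s$step_name, parameters = s$parameters,
                removed = s$removed, reason = s$reason)
         })),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
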