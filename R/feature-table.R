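# LC-MS feature table container: feature metadata, sample manifest and the
# features x samples peak-area matrix, plus the CSV dialect used on disk.

.roles <- c("study", "solvent_blank", "method_blank", "pooled_qc")
.compartments <- c("serum", "brain", "none")
.groups <- c("SPF", "LPS", "Reuteri", "LPS_Reuteri", "none")

#' Validate a sample manifest
#'
#' A manifest has one row per sample: `sample_id`, `role` (study,
#' solvent_blank, method_blank or pooled_qc), `compartment` (serum, brain or
#' none), `group` (SPF, LPS, Reuteri, LPS_Reuteri or none), `age_weeks`
#' (2, 12 or NA) and `qc_group` (label shared by the replicate injections of
#' one pooled QC; NA for non-QC samples). Study samples must carry
#' compartment, group and age; every pooled-QC group needs at least two
#' injections (three is typical).
#'
#' @param manifest A data frame as described.
#' @return The validated manifest (invisibly unchanged).
#' @export
sample_manifest <- function(manifest) {
  req <- c("sample_id", "role", "compartment", "group", "age_weeks", "qc_group")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) stopf("manifest lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$sample_id)) stopf("duplicate sample_id in manifest")
  bad <- setdiff(unique(manifest$role), .roles)
  if (length(bad)) stopf("unknown sample role(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(manifest$compartment), .compartments)
  if (length(bad)) stopf("unknown compartment(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(manifest$group), .groups)
  if (length(bad)) stopf("unknown group(s): %s", paste(bad, collapse = ", "))

  st <- manifest[manifest$role == "study", ]
  if (nrow(st)) {
    incomplete <- st$compartment == "none" | st$group == "none" |
      !(st$age_weeks %in% c(2, 12))
    if (any(incomplete)) {
      stopf("study sample(s) missing compartment/group/age: %s",
            paste(st$sample_id[incomplete], collapse = ", "))
    }
  }
  qc <- manifest[manifest$role == "pooled_qc", ]
  if (nrow(qc)) {
    if (any(is.na(qc$qc_group) | qc$qc_group == "")) {
      stopf("pooled-QC samples must carry a qc_group label")
    }
    counts <- table(qc$qc_group)
    if (any(counts < 2)) {
      stopf("qc_group(s) with < 2 injections: %s",
            paste(names(counts)[counts < 2], collapse = ", "))
    }
  }
  invisible(manifest)
}

#' Construct an LC-MS feature table
#'
#' Bundles feature metadata, the sample manifest and the peak-area matrix.
#' Areas are raw peak areas until [normalize_internal_standard()] divides
#' each sample by its cholic-acid internal-standard area; the raw matrix is
#' retained in `raw_areas` so presence calls can be made on the raw scale
#' after curation.
#'
#' @param features Data frame with `feature_id`, `mz`, `rt_min`,
#'   `putative_id`, `contaminant_flag`.
#' @param manifest Sample manifest, see [sample_manifest()].
#' @param areas Numeric matrix, features x samples, rownames = feature ids,
#'   colnames = sample ids, all values >= 0.
#' @param is_feature_id Feature id of the internal standard.
#' @param normalized Has internal-standard normalization been applied?
#' @param raw_areas Raw-area matrix (defaults to `areas` when not yet
#'   normalized).
#' @return An object of class `bbb_feature_table`.
#' @export
feature_table <- function(features, manifest, areas, is_feature_id,
                          normalized = FALSE, raw_areas = NULL) {
  req <- c("feature_id", "mz", "rt_min", "putative_id", "contaminant_flag")
  miss <- setdiff(req, names(features))
  if (length(miss)) stopf("features lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(features$feature_id)) stopf("duplicate feature_id")
  if (any(features$mz <= 0)) stopf("mz must be > 0")
  if (any(features$rt_min < 0)) stopf("rt_min must be >= 0")
  sample_manifest(manifest)
  if (!is.matrix(areas) || !is.numeric(areas)) stopf("areas must be a numeric matrix")
  if (nrow(areas) != nrow(features) ||
      !identical(rownames(areas), as.character(features$feature_id))) {
    stopf("areas rows must match features$feature_id")
  }
  if (ncol(areas) != nrow(manifest) ||
      !identical(colnames(areas), as.character(manifest$sample_id))) {
    stopf("areas columns must match manifest$sample_id")
  }
  if (any(areas < 0)) stopf("peak areas must be >= 0")
  if (is.null(raw_areas)) {
    if (normalized) stopf("a normalized table must carry raw_areas")
    raw_areas <- areas
  }
  if (!identical(dim(raw_areas), dim(areas))) stopf("raw_areas dim mismatch")
  if (!normalized && !(is_feature_id %in% features$feature_id)) {
    stopf("internal standard '%s' is not in the table", is_feature_id)
  }
  if (!normalized && is_feature_id %in% features$feature_id) {
    z <- areas[is_feature_id, ] <= 0
    if (any(z)) {
      stopf("internal standard has non-positive area in sample(s): %s",
            paste(colnames(areas)[z], collapse = ", "))
    }
  }
  structure(
    list(features = features, manifest = manifest, areas = areas,
         raw_areas = raw_areas, is_feature_id = is_feature_id,
         normalized = normalized),
    class = "bbb_feature_table"
  )
}

#' @export
print.bbb_feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d samples (%s areas), IS = %s\n",
    nrow(x$features), nrow(x$manifest),
    if (x$normalized) "IS-normalized" else "raw", x$is_feature_id))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(table(x$manifest$role)),
                            table(x$manifest$role)), collapse = ", ")))
  invisible(x)
}

# Column indices of samples by role (and optional group/compartment/age).
sample_ids_where <- function(manifest, role = NULL, group = NULL,
                             compartment = NULL, age_weeks = NULL,
                             qc_group = NULL) {
  keep <- rep(TRUE, nrow(manifest))
  if (!is.null(role)) keep <- keep & manifest$role %in% role
  if (!is.null(group)) keep <- keep & manifest$group %in% group
  if (!is.null(compartment)) keep <- keep & manifest$compartment %in% compartment
  if (!is.null(age_weeks)) keep <- keep & manifest$age_weeks %in% age_weeks
  if (!is.null(qc_group)) keep <- keep & !is.na(manifest$qc_group) &
      manifest$qc_group %in% qc_group
  manifest$sample_id[keep]
}

#' Write / read a feature table as CSV
#'
#' The on-disk dialect is two plain CSV files: a feature table whose first
#' five columns are `feature_id`, `mz`, `rt_min`, `putative_id`,
#' `contaminant_flag` followed by one raw-area column per sample, and a
#' manifest with `sample_id`, `role`, `compartment`, `group`, `age_weeks`,
#' `qc_group`.
#'
#' @param table A [feature_table()] (raw, not yet normalized, for writing).
#' @param features_csv,manifest_csv File paths.
#' @param is_feature_id Internal-standard feature id (for reading).
#' @return `read_feature_table()` returns a [feature_table()];
#'   `write_feature_table()` returns the paths invisibly.
#' @export
write_feature_table <- function(table, features_csv, manifest_csv) {
  stopifnot(inherits(table, "bbb_feature_table"))
  out <- cbind(table$features,
               as.data.frame(table$raw_areas, check.names = FALSE))
  utils::write.csv(out, features_csv, row.names = FALSE)
  utils::write.csv(table$manifest, manifest_csv, row.names = FALSE)
  invisible(c(features_csv, manifest_csv))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(features_csv, manifest_csv, is_feature_id) {
  raw <- utils::read.csv(features_csv, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta_cols <- c("feature_id", "mz", "rt_min", "putative_id", "contaminant_flag")
  miss <- setdiff(meta_cols, names(raw))
  if (length(miss)) stopf("feature CSV lacks columns: %s", paste(miss, collapse = ", "))
  features <- raw[meta_cols]
  features$contaminant_flag <- as.logical(features$contaminant_flag)
  features$putative_id <- as.character(features$putative_id)
  features$putative_id[is.na(features$putative_id)] <- ""
  areas <- as.matrix(raw[setdiff(names(raw), meta_cols)])
  rownames(areas) <- as.character(features$feature_id)
  manifest <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  manifest$qc_group <- as.character(manifest$qc_group)
  areas <- areas[, as.character(manifest$sample_id), drop = FALSE]
  feature_table(features, manifest, areas, is_feature_id)
}
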