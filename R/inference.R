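# Differential-feature testing and serum/brain compartment set inference:
# per-feature one-way ANOVA, Benjamini-Hochberg control, Tukey HSD post hoc,
# presence/absence calls, significant-pool partitioning and the
# BBB-crossing classification.

#' Per-feature one-way ANOVA
#'
#' Fixed-effects one-way ANOVA of each feature's (normalized) areas across
#' treatment groups via [stats::aov()]. Degenerate features are handled
#' before fitting: zero variance within and between groups gives p = 1;
#' zero within-group variance with a real group effect gives p = 0.
#'
#' @param values Numeric matrix, features x samples (rownames = feature
#'   ids), or a numeric vector for a single feature.
#' @param groups Factor/character vector of group labels, one per sample;
#'   at least 2 groups with at least 2 samples each.
#' @return Data frame with `feature_id`, `f_stat`, `p_value`.
#' @export
#' @examples
#' anova_per_feature(rbind(f1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9)),
#'                   rep(c("a", "b", "c"), each = 3))
anova_per_feature <- function(values, groups) {
  if (is.vector(values)) values <- matrix(values, nrow = 1,
                                          dimnames = list("feature", NULL))
  groups <- as.factor(as.character(groups))
  if (ncol(values) != length(groups)) {
    stopf("values has %d columns for %d group labels", ncol(values),
          length(groups))
  }
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("at least 2 groups are required")
  if (any(sizes < 2L)) {
    stopf("group(s) with < 2 samples: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("feature_%d", seq_len(nrow(values)))

  f_stat <- numeric(nrow(values))
  p_value <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    y <- values[i, ]
    gm <- tapply(y, groups, mean)
    between <- stats::var(gm[as.character(groups)])  # 0 iff all group means equal
    within <- sum(tapply(y, groups, function(v) sum((v - mean(v))^2)))
    if (within == 0) {
      if (between == 0 || is.na(between)) {
        f_stat[i] <- 0; p_value[i] <- 1
      } else {
        f_stat[i] <- Inf; p_value[i] <- 0
      }
      next
    }
    fit <- summary(stats::aov(y ~ groups))[[1]]
    f_stat[i] <- fit[["F value"]][1]
    p_value[i] <- fit[["Pr(>F)"]][1]
  }
  data.frame(feature_id = ids, f_stat = f_stat, p_value = p_value,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (monotone, capped at 1; tied p-values share
#' the max-rank adjusted value).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Significantly differential features for one compartment and age
#'
#' Runs [anova_per_feature()] across the four treatment groups on the
#' normalized areas of the study samples of one compartment and age,
#' adjusts with [bh_adjust()], and keeps features with q strictly below
#' `alpha` (default 0.05).
#'
#' @param table A curated, normalized [feature_table()].
#' @param compartment `"serum"` or `"brain"`.
#' @param age_weeks 2 or 12.
#' @param alpha FDR cutoff (default 0.05, strict inequality).
#' @param log_transform Test on `log(area + 1)` instead of the normalized
#'   area (off by default).
#' @return An object of class `bbb_significant_set`: `feature_ids`, a
#'   `stats` data frame (`feature_id`, `f_stat`, `p_value`, `q_value`),
#'   `compartment`, `age_weeks`, `alpha`.
#' @export
significant_set <- function(table, compartment, age_weeks, alpha = 0.05,
                            log_transform = FALSE) {
  stopifnot(inherits(table, "bbb_feature_table"))
  if (!table$normalized) stopf("differential testing uses normalized areas; curate first")
  if (!(compartment %in% c("serum", "brain"))) {
    stopf("compartment must be 'serum' or 'brain'")
  }
  if (!is_scalar_num(alpha) || alpha < 0 || alpha > 1) {
    stopf("alpha must be in [0, 1]")
  }
  ids <- sample_ids_where(table$manifest, role = "study",
                          compartment = compartment, age_weeks = age_weeks)
  if (!length(ids)) stopf("no study samples for %s at %g weeks", compartment,
                          age_weeks)
  groups <- table$manifest$group[match(ids, table$manifest$sample_id)]
  vals <- table$areas[, ids, drop = FALSE]
  if (log_transform) vals <- log(vals + 1)
  res <- anova_per_feature(vals, groups)
  res$q_value <- bh_adjust(res$p_value)
  structure(
    list(feature_ids = res$feature_id[res$q_value < alpha],
         stats = res, compartment = compartment, age_weeks = age_weeks,
         alpha = alpha),
    class = "bbb_significant_set")
}

#' @export
print.bbb_significant_set <- function(x, ...) {
  cat(sprintf("<significant_set> %s, %g weeks: %d of %d features at q < %g\n",
              x$compartment, x$age_weeks, length(x$feature_ids),
              nrow(x$stats), x$alpha))
  invisible(x)
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise group comparisons after a one-way ANOVA, via the
#' studentized-range distribution ([stats::TukeyHSD()]). Groups with no
#' residual variance are handled directly: identical groups give adjusted
#' p = 1, a real difference with zero residual variance gives p = 0.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, one per observation; >= 2 groups with >= 2
#'   samples each.
#' @return Data frame with `group_a`, `group_b`, `diff`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("at least 2 groups are required")
  if (any(sizes < 2L)) {
    stopf("group(s) with < 2 samples: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (length(values) != length(groups)) stopf("values/groups length mismatch")

  within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  gm <- tapply(values, groups, mean)
  if (within == 0) {
    diffs <- gm[pairs[2, ]] - gm[pairs[1, ]]
    return(data.frame(group_a = pairs[2, ], group_b = pairs[1, ],
                      diff = unname(diffs),
                      p_adj = ifelse(diffs == 0, 1, 0),
                      stringsAsFactors = FALSE))
  }
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group_a = vapply(nm, `[`, "", 1),
             group_b = vapply(nm, `[`, "", 2),
             diff = unname(tk[, "diff"]),
             p_adj = unname(tk[, "p adj"]),
             stringsAsFactors = FALSE)
}

#' Presence/absence calls per feature, group and compartment
#'
#' A feature is called present (detected) in one (group, compartment) cell
#' iff its raw peak area is at or above `noise_cutoff` in at least
#' `min_fraction` of that cell's study samples. The default cutoff 3.0E4 is
#' the raw-area floor used when the feature list was built; presence is a
#' raw-scale notion, so the raw areas retained through curation are used.
#'
#' @param table A curated [feature_table()].
#' @param noise_cutoff Raw-area detection floor (default `3e4`).
#' @param min_fraction Required fraction of the cell's samples in (0, 1]
#'   (default 0.5).
#' @param age_weeks Age of the study samples to use (default 2).
#' @return An object of class `bbb_presence_matrix`: logical array
#'   features x groups x compartments plus the parameters.
#' @export
presence_calls <- function(table, noise_cutoff = 3e4, min_fraction = 0.5,
                           age_weeks = 2) {
  stopifnot(inherits(table, "bbb_feature_table"))
  if (!is_scalar_num(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stopf("min_fraction must lie in (0, 1]")
  }
  if (!is_scalar_num(noise_cutoff) || noise_cutoff < 0) {
    stopf("noise_cutoff must be >= 0")
  }
  grps <- setdiff(.groups, "none")
  cmps <- c("serum", "brain")
  ids <- table$features$feature_id
  detected <- array(FALSE, c(length(ids), length(grps), length(cmps)),
                    dimnames = list(ids, grps, cmps))
  for (g in grps) {
    for (cmp in cmps) {
      cols <- sample_ids_where(table$manifest, role = "study", group = g,
                               compartment = cmp, age_weeks = age_weeks)
      if (!length(cols)) next
      frac <- rowMeans(table$raw_areas[, cols, drop = FALSE] >= noise_cutoff)
      detected[, g, cmp] <- frac >= min_fraction
    }
  }
  structure(list(detected = detected, noise_cutoff = noise_cutoff,
                 min_fraction = min_fraction, age_weeks = age_weeks),
            class = "bbb_presence_matrix")
}

#' Partition serum and brain significant pools
#'
#' Venn-style split of the significantly differential features of the two
#' compartments into shared, serum-only and brain-only sets. The sets are
#' pairwise disjoint; shared + serum-only recovers the serum pool and
#' shared + brain-only the brain pool.
#'
#' @param serum_sig,brain_sig [significant_set()] objects or plain
#'   character vectors of feature ids.
#' @return An object of class `bbb_pool_partition` with `shared`,
#'   `serum_only`, `brain_only`.
#' @export
#' @examples
#' pool_partition(c("a", "b", "c"), c("b", "c", "d"))
pool_partition <- function(serum_sig, brain_sig) {
  ids <- function(x) {
    if (inherits(x, "bbb_significant_set")) x$feature_ids
    else as.character(x)
  }
  s <- unique(ids(serum_sig))
  b <- unique(ids(brain_sig))
  structure(
    list(shared = intersect(s, b), serum_only = setdiff(s, b),
         brain_only = setdiff(b, s)),
    class = "bbb_pool_partition")
}

#' @export
print.bbb_pool_partition <- function(x, ...) {
  cat(sprintf("<pool_partition> shared %d, serum-only %d, brain-only %d\n",
              length(x$shared), length(x$serum_only), length(x$brain_only)))
  invisible(x)
}

#' Features that newly crossed the blood-brain barrier
#'
#' Classifies a feature as crossing the BBB under `treated_group` iff it is
#' (i) present in the control group's serum, (ii) absent from the control
#' group's brain, (iii) present in the treated group's brain, and
#' (iv) absent from the treated group's serum - i.e. a metabolite seen only
#' on the blood side in controls that appears specifically on the brain
#' side under treatment, excluding anything still detectable in the treated
#' serum. Per-feature evidence flags are recorded.
#'
#' @param presence A [presence_calls()] result.
#' @param treated_group Treatment group, e.g. `"LPS"` or `"Reuteri"`.
#' @param control_group Control group (default `"SPF"`).
#' @return An object of class `bbb_crossing_result` with `treatment`,
#'   `feature_ids` and an `evidence` data frame of the four flags for all
#'   features.
#' @export
crossing_set <- function(presence, treated_group, control_group = "SPF") {
  stopifnot(inherits(presence, "bbb_presence_matrix"))
  grps <- dimnames(presence$detected)[[2]]
  for (g in c(treated_group, control_group)) {
    if (!(g %in% grps)) stopf("unknown group label '%s'", g)
  }
  d <- presence$detected
  evidence <- data.frame(
    feature_id = dimnames(d)[[1]],
    present_control_serum = d[, control_group, "serum"],
    absent_control_brain = !d[, control_group, "brain"],
    present_treated_brain = d[, treated_group, "brain"],
    absent_treated_serum = !d[, treated_group, "serum"],
    stringsAsFactors = FALSE, row.names = NULL)
  hit <- evidence$present_control_serum & evidence$absent_control_brain &
    evidence$present_treated_brain & evidence$absent_treated_serum
  structure(
    list(treatment = treated_group, control = control_group,
         feature_ids = evidence$feature_id[hit], evidence = evidence),
    class = "bbb_crossing_result")
}

#' @export
print.bbb_crossing_result <- function(x, ...) {
  cat(sprintf("<crossing_result> %s vs %s: %d feature(s) crossed the BBB\n",
              x$treatment, x$control, length(x$feature_ids)))
  invisible(x)
}
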