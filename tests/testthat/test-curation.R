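# Curation cascade: per-step rules, the hand-enumerated toy oracle,
# conservation, idempotence and scale equivariance.

test_that("solvent-blank filter removes strictly-above-cutoff features only", {
  toy <- load_toy_table()
  res <- filter_solvent_blank(toy)
  expect_setequal(res$removed, c("F02", "F10"))
  # boundary: exactly 1E6 is retained ("over" is strict)
  expect_true("F03" %in% res$table$features$feature_id)
  expect_error(filter_solvent_blank(toy, cutoff = -1), ">= 0")

  # with no solvent blanks the step is a warning no-op
  keep <- toy$manifest$role != "solvent_blank"
  t2 <- feature_table(toy$features, toy$manifest[keep, ],
                      toy$areas[, keep], toy$is_feature_id)
  expect_warning(res2 <- filter_solvent_blank(t2), "no-op")
  expect_length(res2$removed, 0)
})

test_that("internal-standard normalization divides by the IS per sample", {
  toy <- load_toy_table()
  norm <- normalize_internal_standard(toy)
  expect_true(norm$normalized)
  # sample with IS area 2 and feature area 10 -> 5; S2 has IS area 4
  expect_equal(norm$areas["F07", "S1"], 5)
  expect_equal(norm$areas["F07", "S2"], 3)
  expect_true(all(norm$areas["F01", ] == 1))
  expect_identical(norm$raw_areas, toy$areas)
  expect_error(normalize_internal_standard(norm), "already")

  # zero IS in one sample is rejected naming the sample
  bad_areas <- toy$areas
  bad_areas["F01", "S3"] <- 0
  expect_error(feature_table(toy$features, toy$manifest, bad_areas, "F01"),
               "S3")
})

test_that("method-blank filter compares study vs blank summary on normalized areas", {
  norm <- normalize_internal_standard(load_toy_table())
  res <- filter_method_blank(norm)
  expect_setequal(res$removed, c("F04", "F09"))
  expect_error(filter_method_blank(load_toy_table()), "normalize")

  # mean-vs-mean variant still removes the all-zero and blank-dominated rows
  res_mean <- filter_method_blank(norm, stat = "mean")
  expect_true(all(c("F04", "F09") %in% res_mean$removed))
})

test_that("QC %CV uses the sample SD per pool with strict threshold", {
  norm <- normalize_internal_standard(load_toy_table())
  res <- filter_qc_cv(norm)
  # F05 QC normalized areas (1, 1.2, 0.8): sd 0.2, mean 1 -> 20% > 10
  expect_equal(unname(res$cv["F05", "QC1"]), 20)
  expect_true("F05" %in% res$removed)
  # stable features (CV 0) are retained
  expect_equal(unname(res$cv["F07", "QC1"]), 0)
  expect_false("F07" %in% res$removed)
  # all-zero feature has CV 0, not NaN
  expect_equal(unname(res$cv["F09", "QC1"]), 0)

  # a pool with fewer than 2 injections is rejected already at the manifest
  keep <- norm$manifest$sample_id != "Q2" & norm$manifest$sample_id != "Q3"
  expect_error(
    feature_table(norm$features, norm$manifest[keep, ],
                  norm$areas[, keep], norm$is_feature_id,
                  normalized = TRUE, raw_areas = norm$raw_areas[, keep]),
    "< 2 injections")
})

test_that("contaminant filter removes exactly the flagged features", {
  toy <- load_toy_table()
  res <- filter_contaminants(toy)
  expect_setequal(res$removed, c("F06", "F10"))
  unflagged <- toy
  unflagged$features$contaminant_flag <- FALSE
  res0 <- filter_contaminants(feature_table(unflagged$features, toy$manifest,
                                            toy$areas, toy$is_feature_id))
  expect_length(res0$removed, 0)
})

test_that("cascade on the toy fixture matches the hand enumeration", {
  cur <- curate(load_toy_table())
  steps <- setNames(lapply(cur$report$steps, `[[`, "removed"),
                    vapply(cur$report$steps, `[[`, "", "step_name"))
  expect_setequal(steps$solvent_blank, toy_expected$solvent_blank)
  expect_setequal(steps$method_blank, toy_expected$method_blank)
  expect_setequal(steps$qc_cv, toy_expected$qc_cv)
  # F10 is flagged but already removed at step 1 (first reason wins)
  expect_setequal(steps$contaminants, toy_expected$contaminants)
  expect_setequal(cur$table$features$feature_id, toy_expected$retained)
  expect_equal(cur$report$n_retained, 6)
})

test_that("cascade recovers planted simulator categories exactly", {
  sim <- simulate_feature_table(small_feature_spec(seed = 7L))
  cur <- curate(sim$table)
  steps <- setNames(lapply(cur$report$steps, `[[`, "removed"),
                    vapply(cur$report$steps, `[[`, "", "step_name"))
  truth <- sim$truth
  planted <- function(cat) truth$feature_id[truth$category == cat]
  expect_setequal(steps$solvent_blank, planted("blank_high"))
  expect_length(steps$method_blank, 0)
  expect_setequal(steps$qc_cv, planted("qc_unstable"))
  expect_setequal(steps$contaminants, planted("contaminant"))
})

test_that("null simulator table passes curation untouched", {
  spec <- feature_table_spec(n_features = 30, n_blank_high = 0,
                             n_contaminant = 0, n_qc_unstable = 0,
                             n_differential = 0, n_crossing_lps = 0,
                             n_crossing_reuteri = 0, seed = 3L)
  sim <- simulate_feature_table(spec)
  cur <- curate(sim$table)
  expect_equal(cur$report$n_retained, 30)
  expect_true(all(vapply(cur$report$steps,
                         function(s) length(s$removed) == 0, logical(1))))
})

test_that("conservation holds on random simulator tables", {
  for (seed in 1:25) {
    spec <- feature_table_spec(
      n_features = 40,
      n_blank_high = seed %% 4, n_contaminant = seed %% 3,
      n_qc_unstable = seed %% 5, n_differential = seed %% 6,
      n_crossing_lps = seed %% 2, n_crossing_reuteri = seed %% 3,
      seed = seed)
    cur <- curate(simulate_feature_table(spec)$table)
    removed <- unlist(lapply(cur$report$steps, `[[`, "removed"))
    expect_equal(anyDuplicated(removed), 0)
    expect_equal(cur$report$n_input,
                 cur$report$n_retained + length(removed))
  }
})

test_that("curation is idempotent", {
  cur1 <- curate(load_toy_table())
  cur2 <- curate(cur1$table)
  expect_equal(cur2$report$n_retained, cur1$report$n_retained)
  expect_true(all(vapply(cur2$report$steps,
                         function(s) length(s$removed) == 0, logical(1))))
  expect_equal(cur2$table$areas, cur1$table$areas)
})

test_that("step order changes attribution but not the toy retained set", {
  toy <- load_toy_table()
  # contaminants first, then the standard remainder
  c1 <- filter_contaminants(toy)
  s1 <- filter_solvent_blank(c1$table)
  n1 <- normalize_internal_standard(s1$table)
  m1 <- filter_method_blank(n1)
  q1 <- filter_qc_cv(m1$table)
  expect_setequal(q1$table$features$feature_id, toy_expected$retained)
  # F10 now attributed to the contaminant step instead of the blank step
  expect_true("F10" %in% c1$removed)
  expect_false("F10" %in% s1$removed)

  # QC filter before the method-blank filter
  s2 <- filter_solvent_blank(toy)
  n2 <- normalize_internal_standard(s2$table)
  q2 <- filter_qc_cv(n2)
  m2 <- filter_method_blank(q2$table)
  c2 <- filter_contaminants(m2$table)
  expect_setequal(c2$table$features$feature_id, toy_expected$retained)
})

test_that("rescaling one sample (including its IS) leaves normalized steps unchanged", {
  sim <- simulate_feature_table(small_feature_spec(seed = 12L))
  tab <- sim$table
  scaled_areas <- tab$areas
  scaled_areas[, "LPS_brain_2"] <- scaled_areas[, "LPS_brain_2"] * 7.5
  tab2 <- feature_table(tab$features, tab$manifest, scaled_areas,
                        tab$is_feature_id)
  cur1 <- curate(tab)
  cur2 <- curate(tab2)
  expect_identical(lapply(cur1$report$steps, `[[`, "removed"),
                   lapply(cur2$report$steps, `[[`, "removed"))
  expect_equal(cur1$table$areas, cur2$table$areas)
})
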