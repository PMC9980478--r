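# Differential testing, BH adjustment, Tukey HSD, presence calls, pool
# partitioning and the crossing classification.

test_that("per-feature ANOVA matches the hand-computed sums of squares", {
  # groups (1,2,3), (4,5,6), (7,8,9): SS_between = 54, SS_within = 6,
  # F = (54/2) / (6/6) = 27 on (2, 6) df
  res <- anova_per_feature(rbind(f1 = 1:9), rep(c("a", "b", "c"), each = 3))
  expect_equal(res$f_stat, 27)
  expect_equal(res$p_value, stats::pf(27, 2, 6, lower.tail = FALSE))

  # identical groups: F = 0, p = 1
  res0 <- anova_per_feature(rbind(f1 = rep(2, 6)), rep(c("a", "b"), each = 3))
  expect_equal(res0$f_stat, 0)
  expect_equal(res0$p_value, 1)

  # group effect with zero residual variance: p = 0
  resd <- anova_per_feature(rbind(f1 = rep(c(1, 5), each = 3)),
                            rep(c("a", "b"), each = 3))
  expect_equal(resd$p_value, 0)

  expect_error(anova_per_feature(rbind(f1 = 1:4), c("a", "a", "a", "b")),
               "< 2 samples")
  expect_error(anova_per_feature(rbind(f1 = 1:4), rep("a", 4)), "2 groups")
})

test_that("planted differential features rank smallest in p", {
  sim <- simulate_feature_table(small_feature_spec(seed = 5L))
  cur <- curate(sim$table)
  sig <- significant_set(cur$table, "serum", 2, alpha = 0.05)
  planted <- sim$truth$feature_id[sim$truth$category == "differential"]
  n_p <- length(planted)
  top <- sig$stats$feature_id[order(sig$stats$p_value)][seq_len(n_p + 6)]
  # all planted features sit among the smallest p-values (crossing features
  # are also group-structured, hence the small allowance)
  expect_true(all(planted %in% top))
})

test_that("bh_adjust equals brute-force BH, including the worked example", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    if (i %% 5 == 0) p <- round(p, 1)  # force ties
    q <- bh_adjust(p)
    expect_equal(q, bh_brute_force(p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p order
    expect_true(all(q <= 1 & q >= p))
  }
})

test_that("significant_set respects alpha limits and the strict inequality", {
  sim <- simulate_feature_table(small_feature_spec(seed = 5L))
  cur <- curate(sim$table)
  expect_length(significant_set(cur$table, "serum", 2, alpha = 0)$feature_ids, 0)
  all_sig <- significant_set(cur$table, "brain", 2, alpha = 1)
  defined <- !is.na(all_sig$stats$p_value)
  # alpha = 1 keeps everything with q < 1 (q == 1 features excluded by strictness)
  expect_setequal(all_sig$feature_ids,
                  all_sig$stats$feature_id[all_sig$stats$q_value < 1 & defined])
  expect_error(significant_set(cur$table, "plasma", 2), "serum")
})

test_that("strong planted effects are recovered exactly in the noiseless regime", {
  spec <- feature_table_spec(n_features = 50, n_blank_high = 0,
                             n_contaminant = 0, n_qc_unstable = 0,
                             n_differential = 8, n_crossing_lps = 0,
                             n_crossing_reuteri = 0, within_sdlog = 0,
                             seed = 17L)
  sim <- simulate_feature_table(spec)
  cur <- curate(sim$table)
  planted <- sim$truth$feature_id[sim$truth$category == "differential"]
  for (cmp in c("serum", "brain")) {
    sig <- significant_set(cur$table, cmp, 2)
    expect_setequal(sig$feature_ids, planted)
  }
})

test_that("empirical FDR of the significant set stays near alpha", {
  # moderate noise, strong effects, many null features; fixed seed
  spec <- feature_table_spec(n_features = 200, n_blank_high = 0,
                             n_contaminant = 0, n_qc_unstable = 0,
                             n_differential = 30, n_crossing_lps = 0,
                             n_crossing_reuteri = 0, lfc = 3,
                             within_sdlog = 0.1, n_samples_per_cell = 6,
                             seed = 23L)
  sim <- simulate_feature_table(spec)
  cur <- curate(sim$table)
  planted <- sim$truth$feature_id[sim$truth$category == "differential"]
  sig <- significant_set(cur$table, "serum", 2, alpha = 0.05)
  fdr <- mean(!(sig$feature_ids %in% planted))
  expect_gt(length(sig$feature_ids), 0)
  expect_true(all(planted %in% sig$feature_ids))
  expect_lte(fdr, 0.10)  # alpha plus stochastic slack
})

test_that("Tukey HSD agrees with a direct studentized-range computation", {
  # 4 groups, n = 3 each; oracle computed from first principles:
  # q_ab = |mean_a - mean_b| / sqrt(MSE / n), p = ptukey(q, k, df)
  y <- c(18, 20, 22, 25, 27, 29, 14, 15, 16, 30, 33, 36)
  g <- rep(c("w", "x", "y", "z"), each = 3)
  res <- tukey_hsd(y, g)
  gm <- tapply(y, g, mean)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (12 - 4)
  for (i in seq_len(nrow(res))) {
    qstat <- unname(abs(gm[res$group_a[i]] - gm[res$group_b[i]]) / sqrt(mse / 3))
    expect_equal(res$p_adj[i],
                 stats::ptukey(qstat, nmeans = 4, df = 8, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(res$diff[i],
                 unname(gm[res$group_a[i]] - gm[res$group_b[i]]))
  }
  # symmetric in group order: relabelling reverses signs, keeps p
  res_rev <- tukey_hsd(y, factor(g, levels = c("z", "y", "x", "w")))
  m1 <- res[order(paste(pmin(res$group_a, res$group_b),
                        pmax(res$group_a, res$group_b))), ]
  m2 <- res_rev[order(paste(pmin(res_rev$group_a, res_rev$group_b),
                            pmax(res_rev$group_a, res_rev$group_b))), ]
  expect_equal(m1$p_adj, m2$p_adj)
  expect_equal(abs(m1$diff), abs(m2$diff))

  # identical groups: all pairwise p = 1
  res_id <- tukey_hsd(rep(5, 8), rep(c("a", "b"), each = 4))
  expect_true(all(res_id$p_adj == 1))
})

test_that("presence calls follow the cutoff and fraction rules", {
  sim <- simulate_feature_table(small_feature_spec(seed = 7L))
  cur <- curate(sim$table)
  pres <- presence_calls(cur$table)
  # features planted as always-present are detected in every cell
  clean <- sim$truth$feature_id[sim$truth$category == "clean"]
  clean <- intersect(clean, cur$table$features$feature_id)
  expect_true(all(pres$detected[clean, , ]))
  expect_error(presence_calls(cur$table, min_fraction = 0), "\\(0, 1\\]")
  expect_error(presence_calls(cur$table, min_fraction = 1.5), "\\(0, 1\\]")

  # fraction logic on a hand-built cell: 1 of 3 above cutoff -> absent,
  # 2 of 3 -> present
  tab <- cur$table
  ids <- tab$manifest$sample_id[
    tab$manifest$role == "study" & tab$manifest$group == "SPF" &
      tab$manifest$compartment == "serum"]
  f <- clean[1]
  tab$raw_areas[f, ids] <- c(5e4, 0, 0)
  expect_false(presence_calls(tab)$detected[f, "SPF", "serum"])
  tab$raw_areas[f, ids] <- c(5e4, 5e4, 0)
  expect_true(presence_calls(tab)$detected[f, "SPF", "serum"])

  # all-zero feature is absent everywhere
  tab$raw_areas[f, ] <- 0
  expect_true(all(!presence_calls(tab)$detected[f, , ]))
})

test_that("pool partition satisfies the Venn identities", {
  part <- pool_partition(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_setequal(part$shared, c("b", "c"))
  expect_setequal(part$serum_only, "a")
  expect_setequal(part$brain_only, c("d", "e"))

  # disjoint and equal cases
  expect_length(pool_partition(c("a"), c("b"))$shared, 0)
  same <- pool_partition(c("a", "b"), c("a", "b"))
  expect_length(same$serum_only, 0)
  expect_length(same$brain_only, 0)

  # size identities on random sets
  set.seed(4)
  for (i in 1:20) {
    s <- sample(letters, sample(0:20, 1))
    b <- sample(letters, sample(0:20, 1))
    p <- pool_partition(s, b)
    expect_equal(length(p$shared) + length(p$serum_only), length(unique(s)))
    expect_equal(length(p$shared) + length(p$brain_only), length(unique(b)))
    expect_length(intersect(p$serum_only, p$brain_only), 0)
  }
})

test_that("pool partition reproduces the printed 77/80/20 arithmetic", {
  serum <- sprintf("s%02d", 1:77)
  brain <- c(serum[1:20], sprintf("b%02d", 1:60))
  part <- pool_partition(serum, brain)
  expect_length(part$shared, 20)
  expect_length(part$serum_only, 57)
  expect_length(part$brain_only, 60)
})

test_that("crossing classification applies all four conditions", {
  sim <- simulate_feature_table(small_feature_spec(seed = 7L))
  cur <- curate(sim$table)
  pres <- presence_calls(cur$table)

  reut <- crossing_set(pres, "Reuteri")
  lps <- crossing_set(pres, "LPS")
  expect_setequal(reut$feature_ids,
                  sim$truth$feature_id[sim$truth$category == "crossing_reuteri"])
  expect_setequal(lps$feature_ids,
                  sim$truth$feature_id[sim$truth$category == "crossing_lps"])
  # the two contrasts are disjoint by the planted design
  expect_length(intersect(reut$feature_ids, lps$feature_ids), 0)
  expect_error(crossing_set(pres, "Mystery"), "unknown group")

  # flipping the treated-serum flag removes a feature (the exclusion rule)
  f <- reut$feature_ids[1]
  tab <- cur$table
  serum_ids <- tab$manifest$sample_id[
    tab$manifest$role == "study" & tab$manifest$group == "Reuteri" &
      tab$manifest$compartment == "serum"]
  tab$raw_areas[f, serum_ids] <- 1e6
  reut2 <- crossing_set(presence_calls(tab), "Reuteri")
  expect_false(f %in% reut2$feature_ids)

  # raising the cutoff beyond all areas empties the crossing sets
  pres_hi <- presence_calls(cur$table,
                            noise_cutoff = max(cur$table$raw_areas) * 2)
  expect_length(crossing_set(pres_hi, "Reuteri")$feature_ids, 0)

  # anti-monotonicity in the cutoff via the treated-brain condition
  cuts <- c(3e4, 1e5, 3e5, 1e6)
  sets <- lapply(cuts, function(ct)
    crossing_set(presence_calls(cur$table, noise_cutoff = ct), "Reuteri"))
  for (i in seq_along(cuts)[-1]) {
    gained <- setdiff(sets[[i]]$feature_ids, sets[[i - 1]]$feature_ids)
    ev <- sets[[i - 1]]$evidence
    # any newly-included feature got in through conditions (i)/(ii)/(iv),
    # never by gaining treated-brain presence at a higher cutoff
    if (length(gained)) {
      prev_brain <- ev$present_treated_brain[match(gained, ev$feature_id)]
      now_brain <- sets[[i]]$evidence$present_treated_brain[
        match(gained, sets[[i]]$evidence$feature_id)]
      expect_true(all(prev_brain >= now_brain))
    }
  }
})
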