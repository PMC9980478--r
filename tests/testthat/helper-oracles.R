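# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Brute-force step-up Benjamini-Hochberg: q_(i) = min_{j >= i} p_(j) * m / j.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# 2-D grid search over (P0, T1) minimizing the sum of squared residuals of
# the saturation-recovery model; returns the grid point per voxel.
grid_search_t1 <- function(signal_matrix, trs, p0_grid, t1_grid) {
  grid <- expand.grid(p0 = p0_grid, t1 = t1_grid)
  model <- outer(seq_len(nrow(grid)), seq_along(trs),
                 function(i, j) grid$p0[i] * (1 - exp(-trs[j] / grid$t1[i])))
  # SSE_gv = ||model_g||^2 - 2 model_g . s_v + ||s_v||^2; the last term is
  # constant per voxel
  cross <- model %*% t(signal_matrix)
  sse <- rowSums(model^2) - 2 * cross
  best <- apply(sse, 2, which.min)
  data.frame(p0 = grid$p0[best], t1 = grid$t1[best])
}

# Loads the committed 12-feature toy table.
load_toy_table <- function() {
  read_feature_table(
    system.file("extdata", "toy_features.csv", package = "bbbaxis"),
    system.file("extdata", "toy_manifest.csv", package = "bbbaxis"),
    is_feature_id = "F01")
}

# Hand enumeration of the toy cascade (committed oracle): which feature is
# removed at which step, and why.
toy_expected <- list(
  solvent_blank = c("F02", "F10"),   # 1.5E6 / 1.2E6 in the solvent blank
  method_blank = c("F04", "F09"),    # study max <= method-blank level
  qc_cv = "F05",                     # QC (1, 1.2, 0.8) -> 20% CV
  contaminants = "F06",              # flagged (F10 already gone at step 1)
  retained = c("F01", "F03", "F07", "F08", "F11", "F12")
)

# Small feature-table spec used when a test needs speed over realism.
small_feature_spec <- function(n_features = 60, n_blank_high = 5,
                               n_contaminant = 3, n_qc_unstable = 6,
                               n_differential = 10, n_crossing_lps = 2,
                               n_crossing_reuteri = 4, ...) {
  feature_table_spec(n_features = n_features, n_blank_high = n_blank_high,
                     n_contaminant = n_contaminant,
                     n_qc_unstable = n_qc_unstable,
                     n_differential = n_differential,
                     n_crossing_lps = n_crossing_lps,
                     n_crossing_reuteri = n_crossing_reuteri, ...)
}

# Small phantom used across MRI tests.
small_phantom <- function(matrix_size = c(3, 24, 24), roi_margin = 2,
                          n_vessels = 2, vessel_radius = 1.5, ...) {
  phantom_spec(matrix_size = matrix_size, roi_margin = roi_margin,
               n_vessels = n_vessels, vessel_radius = vessel_radius, ...)
}
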