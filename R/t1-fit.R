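# Voxel-wise T1 estimation by nonlinear least squares on the
# saturation-recovery model S(TR) = P0 * (1 - exp(-TR / T1)).

t1_model <- function(p0, t1, trs) p0 * (1 - exp(-trs / t1))

#' Fit T1 in a single voxel
#'
#' Bounded Levenberg-Marquardt least squares of the two-parameter
#' saturation-recovery model against signal intensities measured at a
#' strictly increasing TR schedule. Initialization is P0 = max signal,
#' T1 = median TR. The fit is flagged invalid when the signal is degenerate
#' (non-positive or constant), the optimizer fails, T1 lands on a bound, or
#' the residual RMSE exceeds `rmse_max`.
#'
#' @param signals Numeric vector of voxel intensities, one per TR.
#' @param trs Repetition times in seconds, strictly increasing, length >= 3.
#' @param t1_bounds Lower/upper T1 bounds in seconds (default 1 ms to 20 s).
#' @param rmse_max Validity ceiling on the fit RMSE (default `Inf`,
#'   disabled).
#' @return A list with `p0`, `t1`, `rmse` and logical `valid`.
#' @export
#' @examples
#' trs <- c(0.281, 0.35, 0.5, 1, 1.5, 2, 3, 5, 10)
#' fit_t1_voxel(1000 * (1 - exp(-trs / 1.5)), trs)
fit_t1_voxel <- function(signals, trs, t1_bounds = c(1e-3, 20),
                         rmse_max = Inf) {
  if (length(signals) != length(trs)) {
    stopf("signals (%d) and trs (%d) differ in length",
          length(signals), length(trs))
  }
  if (length(trs) < 3L) stopf("T1 fitting needs >= 3 TR points")
  check_tr_schedule(trs)
  if (length(t1_bounds) != 2L || t1_bounds[1] <= 0 ||
      t1_bounds[2] <= t1_bounds[1]) {
    stopf("t1_bounds must be increasing positives")
  }

  invalid <- list(p0 = NA_real_, t1 = NA_real_, rmse = NA_real_, valid = FALSE)
  if (anyNA(signals) || !all(is.finite(signals))) return(invalid)
  if (max(signals) <= 0 || stats::sd(signals) == 0) return(invalid)

  # data-driven T1 start: the TR where the recovery reaches ~63% of the
  # plateau, with the median TR as a fallback start against local minima
  p0_start <- max(signals)
  frac <- signals / p0_start
  i63 <- which(frac >= 0.632)
  t1_data <- if (length(i63)) trs[i63[1]] else max(trs)
  t1_starts <- unique(pmin(pmax(c(t1_data, stats::median(trs)),
                                t1_bounds[1] * 2), t1_bounds[2] / 2))
  one_fit <- function(t1_start) {
    tryCatch(
      minpack.lm::nls.lm(
        par = c(p0 = p0_start, t1 = t1_start),
        lower = c(1e-12, t1_bounds[1]),
        upper = c(Inf, t1_bounds[2]),
        fn = function(par) signals - t1_model(par[1], par[2], trs),
        control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                             maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fits <- Filter(Negate(is.null), lapply(t1_starts, one_fit))
  if (!length(fits)) return(invalid)
  sse <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  fit <- fits[[which.min(sse)]]
  p0 <- unname(fit$par[1])
  t1 <- unname(fit$par[2])
  rmse <- sqrt(mean(fit$fvec^2))
  on_bound <- t1 <= t1_bounds[1] * (1 + 1e-9) || t1 >= t1_bounds[2] * (1 - 1e-9)
  valid <- is.finite(p0) && is.finite(t1) && !on_bound && rmse <= rmse_max
  list(p0 = p0, t1 = t1, rmse = rmse, valid = valid)
}

#' Fit a T1 map over a region of interest
#'
#' Applies [fit_t1_voxel()] independently to every voxel inside `roi`;
#' voxels outside the ROI are not fitted and are marked invalid. Per-voxel
#' results are identical to calling [fit_t1_voxel()] directly (locality).
#'
#' @param series A [relaxometry_series()].
#' @param roi A [voxel_mask()] with matching geometry.
#' @inheritParams fit_t1_voxel
#' @return A [t1_map()].
#' @export
fit_t1_map <- function(series, roi, t1_bounds = c(1e-3, 20), rmse_max = Inf) {
  stopifnot(inherits(series, "bbb_relaxometry_series"),
            inherits(roi, "bbb_mask"))
  check_same_geometry(series$geometry, roi$geometry, "series and ROI")
  dims <- series$geometry$matrix_size
  idx <- which(roi$mask)
  sig <- vapply(series$stacks, function(s) s$intensities[idx],
                numeric(length(idx)))
  if (length(idx) == 1L) sig <- matrix(sig, nrow = 1L)

  t1 <- array(NA_real_, dims)
  p0 <- array(NA_real_, dims)
  rmse <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  for (i in seq_along(idx)) {
    f <- fit_t1_voxel(sig[i, ], series$trs, t1_bounds, rmse_max)
    t1[idx[i]] <- f$t1
    p0[idx[i]] <- f$p0
    rmse[idx[i]] <- f$rmse
    valid[idx[i]] <- f$valid
  }
  # invalid voxels keep their estimates in t1/p0 for inspection, but the
  # valid mask gates every downstream summary
  t1_map(t1, p0, rmse, valid, series$geometry)
}
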