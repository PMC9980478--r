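# MRI phantom generator: saturation-recovery relaxometry series, paired
# post-contrast series, and time-of-flight angiography stacks with known
# ground truth (T1 maps, brain ROI, vessel mask).

#' Phantom specification
#'
#' Describes a digital brain phantom: grid geometry, tissue and blood T1,
#' vessel count/calibre, a per-subject contrast-leakage strength
#' (`permeability_param`), noise level and the variable-TR schedule. Defaults
#' follow a 9.4 T neonatal-mouse protocol: 128 x 96 in-plane matrix over a
#' 25.6 x 19.2 mm field of view (0.2 mm pixels), nine 1.5 mm slices, and the
#' nine-point TR schedule 0.281, 0.35, 0.5, 1, 1.5, 2, 3, 5, 10 s.
#'
#' The brain ROI is a centred in-plane ellipse through all slices; vessels
#' are straight cylinders along the slice axis with in-plane radius
#' `vessel_radius` voxels, so each vessel's volume is analytically
#' pi * r^2 * h. Post-contrast leakage raises the relaxation rate uniformly
#' inside the ROI: R1_post = R1_base + contrast_kappa * permeability_param.
#'
#' @param matrix_size (slices, rows, cols) voxels.
#' @param voxel_size In-plane pixel edge, mm.
#' @param slice_thickness Slice thickness, mm.
#' @param tissue_t1 Parenchyma baseline T1, seconds.
#' @param vessel_t1 Blood T1, seconds.
#' @param n_vessels Number of straight tubular vessels.
#' @param vessel_radius In-plane vessel radius, voxels.
#' @param permeability_param Dimensionless leakage strength, >= 0.
#' @param noise_sd Gaussian noise standard deviation, signal units.
#' @param p0 Equilibrium signal amplitude inside the brain ROI.
#' @param tr_schedule Strictly increasing repetition times, seconds.
#' @param contrast_kappa Leakage rate constant, s^-1 per unit
#'   `permeability_param`.
#' @param tof_background TOF intensity of parenchyma.
#' @param tof_contrast_ratio Vessel / parenchyma TOF intensity ratio.
#' @param roi_margin In-plane margin (voxels) between ROI ellipse and the
#'   matrix edge.
#' @param seed Integer seed; all stochastic draws are local to it.
#' @return An object of class `bbb_phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(matrix_size = c(3, 32, 32), noise_sd = 0)
phantom_spec <- function(matrix_size = c(9L, 128L, 96L),
                         voxel_size = 0.2,
                         slice_thickness = 1.5,
                         tissue_t1 = 1.8,
                         vessel_t1 = 2.2,
                         n_vessels = 5L,
                         vessel_radius = 2,
                         permeability_param = 0,
                         noise_sd = 20,
                         p0 = 1000,
                         tr_schedule = c(0.281, 0.35, 0.5, 1, 1.5, 2, 3, 5, 10),
                         contrast_kappa = 0.5,
                         tof_background = 100,
                         tof_contrast_ratio = 4,
                         roi_margin = 4,
                         seed = 1L) {
  check_tr_schedule(tr_schedule)
  if (!is_scalar_num(tissue_t1) || tissue_t1 <= 0) stopf("tissue_t1 must be > 0")
  if (!is_scalar_num(vessel_t1) || vessel_t1 <= 0) stopf("vessel_t1 must be > 0")
  if (!is_scalar_num(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is_scalar_num(permeability_param) || permeability_param < 0) {
    stopf("permeability_param must be >= 0")
  }
  if (!is_count(n_vessels)) stopf("n_vessels must be a non-negative count")
  if (!is_scalar_num(vessel_radius) || vessel_radius <= 0) {
    stopf("vessel_radius must be > 0 voxels")
  }
  if (!is_scalar_num(p0) || p0 <= 0) stopf("p0 must be > 0")
  if (!is_scalar_num(contrast_kappa) || contrast_kappa < 0) {
    stopf("contrast_kappa must be >= 0")
  }
  geom <- geometry(matrix_size, voxel_size, slice_thickness)
  structure(
    list(geometry = geom, tissue_t1 = tissue_t1, vessel_t1 = vessel_t1,
         n_vessels = as.integer(n_vessels), vessel_radius = vessel_radius,
         permeability_param = permeability_param, noise_sd = noise_sd,
         p0 = p0, tr_schedule = as.numeric(tr_schedule),
         contrast_kappa = contrast_kappa, tof_background = tof_background,
         tof_contrast_ratio = tof_contrast_ratio, roi_margin = roi_margin,
         seed = as.integer(seed)),
    class = "bbb_phantom_spec"
  )
}

#' @export
print.bbb_phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s voxels, %d vessels (r=%g vox), T1 tissue/vessel %.3g/%.3g s,\n  permeability %.3g, noise sd %.3g, %d TRs, seed %d\n",
    paste(x$geometry$matrix_size, collapse = "x"), x$n_vessels,
    x$vessel_radius, x$tissue_t1, x$vessel_t1, x$permeability_param,
    x$noise_sd, length(x$tr_schedule), x$seed))
  invisible(x)
}

# In-plane squared-distance field to the ROI ellipse centre, normalized so
# value <= 1 is inside the ellipse. Returns a (rows x cols) matrix.
roi_ellipse_field <- function(spec) {
  nr <- spec$geometry$matrix_size[2]
  nc <- spec$geometry$matrix_size[3]
  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  ar <- nr / 2 - spec$roi_margin
  ac <- nc / 2 - spec$roi_margin
  if (ar <= 1 || ac <= 1) stopf("matrix too small for roi_margin %g", spec$roi_margin)
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - cr) / ar)^2 + ((c - cc) / ac)^2
}

# Deterministic phantom anatomy: brain ROI (all slices) and vessel mask.
# Vessel centres are drawn uniformly inside the ROI ellipse shrunk by
# (radius + 1) voxels so no cylinder clips the ROI boundary.
phantom_anatomy <- function(spec) {
  dims <- spec$geometry$matrix_size
  field <- roi_ellipse_field(spec)
  roi_plane <- field <= 1
  roi <- array(rep(roi_plane, each = dims[1]), dim = dims)

  vessel_plane <- matrix(FALSE, dims[2], dims[3])
  centres <- NULL
  if (spec$n_vessels > 0) {
    nr <- dims[2]; nc <- dims[3]
    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    ar <- nr / 2 - spec$roi_margin - spec$vessel_radius - 1
    ac <- nc / 2 - spec$roi_margin - spec$vessel_radius - 1
    if (ar <= 0 || ac <= 0) {
      stopf("matrix too small to place vessels of radius %g", spec$vessel_radius)
    }
    centres <- with_seed(spec$seed, {
      out <- matrix(NA_real_, spec$n_vessels, 2)
      for (k in seq_len(spec$n_vessels)) {
        repeat {
          u <- stats::runif(2, -1, 1)
          if (sum(u^2) <= 1) break
        }
        out[k, ] <- c(cr + u[1] * ar, cc + u[2] * ac)
      }
      out
    })
    rgrid <- matrix(seq_len(nr), nr, nc)
    cgrid <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (k in seq_len(spec$n_vessels)) {
      d2 <- (rgrid - centres[k, 1])^2 + (cgrid - centres[k, 2])^2
      vessel_plane <- vessel_plane | (d2 <= spec$vessel_radius^2)
    }
  }
  vessels <- array(rep(vessel_plane, each = dims[1]), dim = dims) & roi

  list(roi = voxel_mask(roi, spec$geometry),
       vessels = voxel_mask(vessels, spec$geometry),
       centres = centres)
}

# Ground-truth T1 map implied by a spec's anatomy.
phantom_truth <- function(spec, anatomy) {
  dims <- spec$geometry$matrix_size
  t1 <- array(NA_real_, dims)
  p0 <- array(NA_real_, dims)
  t1[anatomy$roi$mask] <- spec$tissue_t1
  t1[anatomy$vessels$mask] <- spec$vessel_t1
  p0[anatomy$roi$mask] <- spec$p0
  rmse <- array(NA_real_, dims)
  rmse[anatomy$roi$mask] <- 0
  t1_map(t1, p0, rmse, anatomy$roi$mask, spec$geometry)
}

# Noise-free forward model: one stack per TR from a truth map; signal is 0
# outside the ROI (air).
forward_signal_stacks <- function(truth, trs) {
  dims <- dim(truth$t1)
  lapply(trs, function(tr) {
    s <- array(0, dims)
    v <- truth$valid
    s[v] <- truth$p0[v] * (1 - exp(-tr / truth$t1[v]))
    s
  })
}

add_noise_series <- function(signal_arrays, geom, noise_sd, seed) {
  stacks <- with_seed(seed, {
    lapply(signal_arrays, function(s) {
      if (noise_sd > 0) s <- s + array(stats::rnorm(length(s), 0, noise_sd), dim(s))
      image_stack(s, geom)
    })
  })
  stacks
}

#' Simulate a variable-TR relaxometry series
#'
#' Generates one image stack per repetition time from the saturation-recovery
#' model `S(TR) = P0 * (1 - exp(-TR / T1))`, with per-voxel ground truth T1
#' equal to `tissue_t1` in parenchyma and `vessel_t1` in vessel voxels, plus
#' additive Gaussian noise. Outputs are byte-identical for identical
#' spec + seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `series` ([relaxometry_series()]),
#'   `truth` (ground-truth [t1_map()]), `roi` and `vessels`
#'   ([voxel_mask()]s).
#' @export
simulate_relaxometry_series <- function(spec) {
  stopifnot(inherits(spec, "bbb_phantom_spec"))
  anat <- phantom_anatomy(spec)
  truth <- phantom_truth(spec, anat)
  signals <- forward_signal_stacks(truth, spec$tr_schedule)
  stacks <- add_noise_series(signals, spec$geometry, spec$noise_sd,
                             seed = spec$seed + 1L)
  list(series = relaxometry_series(stacks, spec$tr_schedule),
       truth = truth, roi = anat$roi, vessels = anat$vessels)
}

#' Ground-truth post-contrast T1 map
#'
#' Applies the uniform leakage model inside the ROI:
#' `R1_post = R1_base + contrast_kappa * permeability_param`, i.e. contrast
#' agent accumulation shortens T1 by an amount strictly increasing in the
#' permeability parameter (and leaves it unchanged when the parameter is 0).
#'
#' @param spec A [phantom_spec()].
#' @param baseline_truth Ground-truth [t1_map()] from
#'   [simulate_relaxometry_series()].
#' @return A [t1_map()] of the post-contrast truth.
#' @export
post_contrast_truth <- function(spec, baseline_truth) {
  stopifnot(inherits(spec, "bbb_phantom_spec"),
            inherits(baseline_truth, "bbb_t1_map"))
  check_same_geometry(spec$geometry, baseline_truth$geometry,
                      "spec and baseline truth")
  t1 <- baseline_truth$t1
  v <- baseline_truth$valid
  t1[v] <- 1 / (1 / t1[v] + spec$contrast_kappa * spec$permeability_param)
  t1_map(t1, baseline_truth$p0, baseline_truth$rmse, v, baseline_truth$geometry)
}

#' Simulate the post-contrast relaxometry measurement
#'
#' Repeats the variable-TR measurement after (simulated) contrast injection.
#' The measurement is acquired twice, mirroring a repeated post-contrast
#' protocol, so two independent-noise replicate series are returned along
#' with the post-contrast ground truth.
#'
#' @param spec A [phantom_spec()]; `permeability_param` and `contrast_kappa`
#'   set the T1 shortening.
#' @param baseline_truth Ground-truth [t1_map()] from
#'   [simulate_relaxometry_series()] with the same geometry.
#' @return List with `replicates` (list of two [relaxometry_series()]) and
#'   `truth` (post-contrast [t1_map()]).
#' @export
simulate_post_contrast_series <- function(spec, baseline_truth) {
  truth <- post_contrast_truth(spec, baseline_truth)
  signals <- forward_signal_stacks(truth, spec$tr_schedule)
  reps <- lapply(1:2, function(r) {
    stacks <- add_noise_series(signals, spec$geometry, spec$noise_sd,
                               seed = spec$seed + 100L + r)
    relaxometry_series(stacks, spec$tr_schedule)
  })
  list(replicates = reps, truth = truth)
}

#' Simulate a time-of-flight angiography stack
#'
#' Flowing blood is bright without contrast agent: vessel voxels take
#' intensity `tof_background * tof_contrast_ratio`, parenchyma
#' `tof_background`, air 0, plus Gaussian noise.
#'
#' @param spec A [phantom_spec()].
#' @return List with `stack` ([image_stack()]), `roi` and `vessels`
#'   ([voxel_mask()]s).
#' @export
simulate_tof_stack <- function(spec) {
  stopifnot(inherits(spec, "bbb_phantom_spec"))
  anat <- phantom_anatomy(spec)
  dims <- spec$geometry$matrix_size
  s <- array(0, dims)
  s[anat$roi$mask] <- spec$tof_background
  s[anat$vessels$mask] <- spec$tof_background * spec$tof_contrast_ratio
  stack <- add_noise_series(list(s), spec$geometry, spec$noise_sd,
                            seed = spec$seed + 200L)[[1]]
  list(stack = stack, roi = anat$roi, vessels = anat$vessels)
}
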