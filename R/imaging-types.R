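# Core imaging containers. Arrays are indexed (slice, row, col); masks are
# voxel sets (a voxel is in or out, no partial volumes).

#' Image geometry
#'
#' Voxel grid description shared by all stacks, maps and masks of one
#' acquisition: matrix size as (slices, rows, cols), square in-plane pixels
#' and the slice thickness. The voxel volume in mm^3 is
#' `pixel_size^2 * slice_thickness`.
#'
#' @param matrix_size Integer vector (slices, rows, cols), all positive.
#' @param pixel_size In-plane pixel edge in mm.
#' @param slice_thickness Slice thickness in mm.
#' @return An object of class `bbb_geometry`.
#' @export
#' @examples
#' geometry(c(9, 128, 96), pixel_size = 0.2, slice_thickness = 1.5)
geometry <- function(matrix_size, pixel_size, slice_thickness) {
  if (length(matrix_size) != 3L || any(matrix_size < 1) ||
      any(matrix_size != round(matrix_size))) {
    stopf("matrix_size must be three positive integers (slices, rows, cols)")
  }
  if (!is_scalar_num(pixel_size) || pixel_size <= 0) {
    stopf("pixel_size must be a positive scalar (mm)")
  }
  if (!is_scalar_num(slice_thickness) || slice_thickness <= 0) {
    stopf("slice_thickness must be a positive scalar (mm)")
  }
  structure(
    list(matrix_size = as.integer(matrix_size),
         pixel_size = pixel_size,
         slice_thickness = slice_thickness),
    class = "bbb_geometry"
  )
}

#' Voxel volume of a geometry
#'
#' @param geom A [geometry()] object.
#' @return Volume of one voxel in mm^3.
#' @export
voxel_volume <- function(geom) {
  stopifnot(inherits(geom, "bbb_geometry"))
  geom$pixel_size^2 * geom$slice_thickness
}

same_geometry <- function(a, b) {
  identical(a$matrix_size, b$matrix_size) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$slice_thickness, b$slice_thickness))
}

check_same_geometry <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b)) stopf("geometry mismatch between %s", what)
  invisible(TRUE)
}

#' @export
print.bbb_geometry <- function(x, ...) {
  cat(sprintf("<geometry> %d x %d x %d voxels, %.3g mm pixels, %.3g mm slices\n",
              x$matrix_size[1], x$matrix_size[2], x$matrix_size[3],
              x$pixel_size, x$slice_thickness))
  invisible(x)
}

#' Image stack
#'
#' A single 3-D intensity array with its geometry.
#'
#' @param intensities Non-negative numeric 3-D array, dim = matrix_size.
#' @param geom A [geometry()] object.
#' @return An object of class `bbb_image_stack`.
#' @export
image_stack <- function(intensities, geom) {
  stopifnot(inherits(geom, "bbb_geometry"))
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stopf("intensities must be a 3-D array")
  }
  if (!identical(dim(intensities), as.integer(geom$matrix_size))) {
    stopf("intensities dim (%s) does not match geometry matrix_size (%s)",
          paste(dim(intensities), collapse = "x"),
          paste(geom$matrix_size, collapse = "x"))
  }
  structure(list(intensities = intensities, geometry = geom),
            class = "bbb_image_stack")
}

#' @export
print.bbb_image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %s, intensity range [%.4g, %.4g]\n",
              paste(dim(x$intensities), collapse = "x"),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Variable-TR relaxometry series
#'
#' An ordered set of co-registered image stacks, one per repetition time, as
#' acquired by a variable-TR saturation-recovery protocol. TRs are strictly
#' increasing seconds; at least 3 are required for the two-parameter T1 fit.
#'
#' @param stacks List of [image_stack()] objects, one per TR.
#' @param trs Numeric vector of repetition times in seconds, same length.
#' @return An object of class `bbb_relaxometry_series`.
#' @export
relaxometry_series <- function(stacks, trs) {
  check_tr_schedule(trs)
  if (length(trs) < 3L) stopf("a relaxometry series needs >= 3 TRs")
  if (length(stacks) != length(trs)) {
    stopf("got %d stacks for %d TRs", length(stacks), length(trs))
  }
  geom <- stacks[[1L]]$geometry
  for (s in stacks) {
    stopifnot(inherits(s, "bbb_image_stack"))
    check_same_geometry(geom, s$geometry, "stacks of one series")
  }
  structure(list(stacks = stacks, trs = as.numeric(trs), geometry = geom),
            class = "bbb_relaxometry_series")
}

#' @export
print.bbb_relaxometry_series <- function(x, ...) {
  cat(sprintf("<relaxometry_series> %d TRs (%s s), %s voxels\n",
              length(x$trs), paste(format(x$trs), collapse = ", "),
              paste(x$geometry$matrix_size, collapse = "x")))
  invisible(x)
}

#' Voxel mask
#'
#' A logical voxel mask (brain ROI or vessel mask) with its geometry.
#'
#' @param mask Logical 3-D array, dim = matrix_size.
#' @param geom A [geometry()] object.
#' @return An object of class `bbb_mask`.
#' @export
voxel_mask <- function(mask, geom) {
  stopifnot(inherits(geom, "bbb_geometry"))
  if (!is.array(mask) || length(dim(mask)) != 3L) stopf("mask must be 3-D")
  if (!identical(dim(mask), as.integer(geom$matrix_size))) {
    stopf("mask dim does not match geometry matrix_size")
  }
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, geometry = geom), class = "bbb_mask")
}

#' @export
print.bbb_mask <- function(x, ...) {
  cat(sprintf("<mask> %s, %d voxels set\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Per-voxel T1 map
#'
#' Result of voxel-wise saturation-recovery fitting: longitudinal relaxation
#' time `t1` (seconds), equilibrium signal `p0`, root-mean-square fit
#' residual `rmse`, and a `valid` mask marking voxels where the fit
#' converged inside bounds.
#'
#' @param t1,p0,rmse Numeric 3-D arrays (NA where not fitted).
#' @param valid Logical 3-D array.
#' @param geom A [geometry()] object.
#' @return An object of class `bbb_t1_map`.
#' @export
t1_map <- function(t1, p0, rmse, valid, geom) {
  stopifnot(inherits(geom, "bbb_geometry"))
  dims <- as.integer(geom$matrix_size)
  for (a in list(t1, p0, rmse, valid)) {
    if (!identical(dim(a), dims)) stopf("t1 map arrays must match geometry")
  }
  storage.mode(valid) <- "logical"
  if (any(valid & !(is.finite(t1) & t1 > 0))) {
    stopf("t1 must be finite and > 0 wherever valid")
  }
  structure(list(t1 = t1, p0 = p0, rmse = rmse, valid = valid,
                 geometry = geom),
            class = "bbb_t1_map")
}

#' @export
print.bbb_t1_map <- function(x, ...) {
  n <- sum(x$valid)
  cat(sprintf("<t1_map> %s, %d valid voxels", paste(dim(x$t1), collapse = "x"), n))
  if (n > 0) cat(sprintf(", median T1 %.3g s", stats::median(x$t1[x$valid])))
  cat("\n")
  invisible(x)
}
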