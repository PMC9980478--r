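# NIfTI import/export for stacks, series and masks. One NIfTI file per TR
# with a sidecar JSON carrying the TR schedule (seconds) and the geometry.

nifti_from_array <- function(arr, geom) {
  # (slice, row, col) array; record voxel edges in mm via pixdim
  RNifti::asNifti(arr, pixdim = c(geom$slice_thickness, geom$pixel_size,
                                  geom$pixel_size))
}

#' Write / read an image stack as NIfTI
#'
#' @param stack An [image_stack()] (or [voxel_mask()] for the mask
#'   variants, stored as 0/1 voxels).
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @param geom Geometry to attach on read (voxel sizes are also recorded in
#'   the NIfTI header).
#' @return Read variants return the reconstructed object; write variants
#'   the path, invisibly.
#' @export
write_stack_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "bbb_image_stack"))
  RNifti::writeNifti(nifti_from_array(stack$intensities, stack$geometry), path)
  invisible(path)
}

#' @rdname write_stack_nifti
#' @export
read_stack_nifti <- function(path, geom) {
  arr <- array(as.numeric(RNifti::readNifti(path)), dim = geom$matrix_size)
  image_stack(arr, geom)
}

#' @rdname write_stack_nifti
#' @export
write_mask_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "bbb_mask"))
  arr <- array(as.integer(stack$mask), dim = dim(stack$mask))
  RNifti::writeNifti(nifti_from_array(arr, stack$geometry), path)
  invisible(path)
}

#' @rdname write_stack_nifti
#' @export
read_mask_nifti <- function(path, geom) {
  arr <- array(as.numeric(RNifti::readNifti(path)), dim = geom$matrix_size)
  voxel_mask(arr != 0, geom)
}

#' Write / read a relaxometry series as NIfTI files plus sidecar JSON
#'
#' Writes one NIfTI file per repetition time (`<prefix>_tr001.nii.gz`, ...)
#' and `<prefix>.json` recording `tr_seconds`, `matrix_size`,
#' `pixel_size_mm` and `slice_thickness_mm`.
#'
#' @param series A [relaxometry_series()].
#' @param prefix Output path prefix.
#' @return `read_series_nifti()` returns a [relaxometry_series()];
#'   `write_series_nifti()` the sidecar path, invisibly.
#' @export
write_series_nifti <- function(series, prefix) {
  stopifnot(inherits(series, "bbb_relaxometry_series"))
  paths <- sprintf("%s_tr%03d.nii.gz", prefix, seq_along(series$trs))
  for (i in seq_along(series$trs)) {
    write_stack_nifti(series$stacks[[i]], paths[i])
  }
  sidecar <- sprintf("%s.json", prefix)
  g <- series$geometry
  jsonlite::write_json(
    list(tr_seconds = series$trs, files = basename(paths),
         matrix_size = g$matrix_size, pixel_size_mm = g$pixel_size,
         slice_thickness_mm = g$slice_thickness),
    sidecar, auto_unbox = FALSE, pretty = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_series_nifti
#' @export
read_series_nifti <- function(prefix) {
  sidecar <- sprintf("%s.json", prefix)
  if (!file.exists(sidecar)) stopf("sidecar JSON not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  geom <- geometry(meta$matrix_size, meta$pixel_size_mm,
                   meta$slice_thickness_mm)
  stacks <- lapply(file.path(dirname(sidecar), meta$files),
                   read_stack_nifti, geom = geom)
  relaxometry_series(stacks, meta$tr_seconds)
}

#' Write a T1 map as NIfTI (seconds)
#'
#' Stores the T1 values (NA-filled outside the valid mask becomes 0) and a
#' companion `_valid` mask file.
#'
#' @param map A [t1_map()].
#' @param prefix Output path prefix.
#' @return The main path, invisibly.
#' @export
write_t1_map_nifti <- function(map, prefix) {
  stopifnot(inherits(map, "bbb_t1_map"))
  t1 <- map$t1
  t1[!map$valid | is.na(t1)] <- 0
  RNifti::writeNifti(nifti_from_array(t1, map$geometry),
                     sprintf("%s.nii.gz", prefix))
  write_mask_nifti(voxel_mask(map$valid, map$geometry),
                   sprintf("%s_valid.nii.gz", prefix))
  invisible(sprintf("%s.nii.gz", prefix))
}
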