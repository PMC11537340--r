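## NIfTI + JSON sidecar I/O for dynamic series and 3D maps.

#' Write / read a dynamic series as NIfTI with a JSON sidecar
#'
#' The image goes to `<path>.nii.gz`, the acquisition metadata (offset
#' schedule, timing, infusion start, normalisation state, Larmor
#' frequency) to `<path>.json`, and the mask to `<path>_mask.nii.gz`.
#'
#' @param series A [dynamic_series()].
#' @param path Output path prefix (no extension).
#' @return `write_dynamic_series` returns `path` invisibly;
#'   `read_dynamic_series` returns the [dynamic_series()].
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  RNifti::writeNifti(RNifti::asNifti(series$data), paste0(path, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(series$mask),
                                           dim(series$mask))),
                     paste0(path, "_mask.nii.gz"))
  meta <- list(offset_schedule_ppm = series$offset_schedule,
               n_dynamics = series$n_dynamics,
               dynamic_duration_s = series$dynamic_duration_s,
               infusion_start_dynamic = series$infusion_start_dynamic,
               larmor_mhz = series$larmor_mhz,
               normalized = series$normalized,
               motion_corrected = series$motion_corrected)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dynamic_series
#' @export
read_dynamic_series <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mask_file <- paste0(path, "_mask.nii.gz")
  mask <- if (file.exists(mask_file)) {
    array(as.logical(RNifti::readNifti(mask_file) > 0.5), dim(img)[1:3])
  } else NULL
  dynamic_series(array(as.numeric(img), dim(img)),
                 offset_schedule = meta$offset_schedule_ppm,
                 dynamic_duration_s = meta$dynamic_duration_s,
                 infusion_start_dynamic = meta$infusion_start_dynamic,
                 mask = mask,
                 larmor_mhz = meta$larmor_mhz,
                 normalized = isTRUE(meta$normalized),
                 motion_corrected = isTRUE(meta$motion_corrected))
}

#' Write a 3D map as NIfTI
#'
#' @param map 3D numeric array.
#' @param path Output file (`.nii.gz` appended if absent).
#' @return The path, invisibly.
#' @export
write_map <- function(map, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(map), path)
  invisible(path)
}
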