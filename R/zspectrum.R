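## Z-spectrum container: normalised saturation intensities S/S0 versus
## offset, with free-form provenance metadata, plus CSV + JSON
## serialisation.

#' Z-spectrum object
#'
#' @param offsets_ppm Saturation offsets (ppm), any order; stored ascending.
#' @param intensities Normalised intensities S/S0, same length.
#' @param metadata Free-form provenance list.
#' @return Object of class `"zspectrum"`.
#' @export
zspectrum <- function(offsets_ppm, intensities, metadata = list()) {
  if (length(offsets_ppm) != length(intensities))
    stop("offsets and intensities must have equal length")
  ord <- order(offsets_ppm)
  structure(list(offsets_ppm = as.numeric(offsets_ppm[ord]),
                 intensities = as.numeric(intensities[ord]),
                 metadata = metadata),
            class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum> %d offsets [%.2f, %.2f] ppm, Z in [%.3f, %.3f]\n",
              length(x$offsets_ppm), min(x$offsets_ppm), max(x$offsets_ppm),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
as.data.frame.zspectrum <- function(x, ...) {
  data.frame(offset_ppm = x$offsets_ppm, z = x$intensities)
}

#' @export
plot.zspectrum <- function(x, ..., xlab = "offset (ppm)", ylab = "S/S0",
                           type = "b") {
  graphics::plot(x$offsets_ppm, x$intensities, xlab = xlab, ylab = ylab,
                 type = type, xlim = rev(range(x$offsets_ppm)), ...)
  invisible(x)
}

#' Write / read a Z-spectrum as CSV plus JSON metadata sidecar
#'
#' The CSV holds two columns (`offset_ppm`, `z`); metadata goes to
#' `<path>.json`.
#'
#' @param spec A [zspectrum] object.
#' @param path CSV file path.
#' @return `write_zspectrum` returns `path` invisibly; `read_zspectrum`
#'   returns the [zspectrum].
#' @export
write_zspectrum <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
  jsonlite::write_json(spec$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_zspectrum
#' @export
read_zspectrum <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  zspectrum(df$offset_ppm, df$z, metadata = meta)
}

#' Resample a Z-spectrum onto new offsets
#'
#' Cubic-spline interpolation of intensities onto a target offset grid,
#' e.g. from the 41-offset simulation schedule onto the 28-offset
#' experimental schedule. Extrapolation outside the simulated range is
#' refused.
#'
#' @param spec A [zspectrum] object.
#' @param target_offsets_ppm Target offsets; default [offsets_experimental()].
#' @return A [zspectrum] on the target grid.
#' @export
resample_offsets <- function(spec, target_offsets_ppm = offsets_experimental()) {
  rng <- range(spec$offsets_ppm)
  if (any(target_offsets_ppm < rng[1] - 1e-9 | target_offsets_ppm > rng[2] + 1e-9))
    stop("target offsets outside the source range (no extrapolation)")
  sp <- stats::spline(spec$offsets_ppm, spec$intensities,
                      xout = target_offsets_ppm, method = "natural")
  zspectrum(sp$x, sp$y, metadata = c(spec$metadata,
                                     list(resampled_from = length(spec$offsets_ppm))))
}

#' Add Rician noise to a Z-spectrum
#'
#' Each intensity S is replaced by \eqn{\sqrt{(S+n_1)^2+n_2^2}} with
#' \eqn{n_1, n_2 \sim N(0, \sigma)}, \eqn{\sigma} = `sigma_fraction` of
#' the unsaturated reference (S0 = 1 for a normalised spectrum): the
#' magnitude-image noise model.
#'
#' @param spec A [zspectrum] object.
#' @param sigma_fraction Noise standard deviation as a fraction of S0.
#' @param seed Optional integer for reproducible draws (the calling
#'   environment's RNG state is preserved).
#' @param s0 Unsaturated reference level (1 for normalised spectra).
#' @return A [zspectrum] with noisy intensities.
#' @export
add_rician_noise <- function(spec, sigma_fraction = 0.02, seed = NULL, s0 = 1) {
  if (sigma_fraction < 0) stop("sigma_fraction must be >= 0")
  if (sigma_fraction == 0) return(spec)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(spec$intensities)
  sg <- sigma_fraction * s0
  noisy <- sqrt((spec$intensities + stats::rnorm(n, 0, sg))^2 +
                  stats::rnorm(n, 0, sg)^2)
  zspectrum(spec$offsets_ppm, noisy,
            metadata = c(spec$metadata, list(rician_sigma_fraction = sigma_fraction)))
}
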