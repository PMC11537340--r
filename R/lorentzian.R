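## Single-Lorentzian fitting of the direct water saturation line, the
## linewidth (FWHM) extraction in Hz, and the low-B1 continuous-wave
## closed-form linewidth.

#' Lorentzian direct-saturation line model
#'
#' \deqn{Z(\Delta\omega) = b - a \frac{(w/2)^2}{(\Delta\omega - c)^2 + (w/2)^2}}
#' with amplitude (depth) `a`, center `c`, full width at half maximum `w`
#' (all offsets in ppm) and baseline `b`. At the center the value is
#' `b - a`; at `c +- w/2` it is `b - a/2`.
#'
#' @param offset_ppm Offsets at which to evaluate (ppm).
#' @param amplitude Depth of the dip (dimensionless).
#' @param center Center position (ppm).
#' @param fwhm_ppm Full width at half maximum (ppm, > 0).
#' @param baseline Baseline level (dimensionless).
#' @return Intensities at `offset_ppm`.
#' @export
lorentzian <- function(offset_ppm, amplitude, center, fwhm_ppm, baseline = 1) {
  if (any(fwhm_ppm <= 0)) stop("fwhm_ppm must be positive")
  h <- (fwhm_ppm / 2)^2
  baseline - amplitude * h / ((offset_ppm - center)^2 + h)
}

#' Fit a single Lorentzian to a direct-saturation Z-spectrum
#'
#' Deterministic bounded nonlinear least squares (Levenberg-Marquardt)
#' for the water direct-saturation line, reporting the linewidth (FWHM)
#' in ppm and Hz. Initialisation: amplitude from the spectrum minimum,
#' center at the minimising offset, width from the half-depth crossing
#' distance, baseline from the outer (|offset| >= 4 ppm) points. Bounds:
#' width 1--1000 Hz, center within +-1 ppm, baseline 0.8--1.1. Points
#' outside `fit_window_ppm` are excluded.
#'
#' @param spec A [zspectrum], or anything coercible via
#'   `data.frame(offset_ppm, z)`.
#' @param larmor_mhz Larmor frequency in MHz for the ppm-to-Hz conversion;
#'   taken from the spectrum metadata when present.
#' @param fit_window_ppm Half-width of the fit window (default 5 ppm; the
#'   +-10 ppm normalisation points never enter the fit).
#' @return Object of class `"ds_lorentzian"` with methods [print],
#'   [summary], [coef], [predict], [fitted], [residuals] and [plot].
#'   Coefficients: `amplitude`, `center_ppm`, `fwhm_ppm`, `fwhm_hz`,
#'   `baseline`; plus `residual_rms` and `converged`. A failed fit is
#'   returned with `converged = FALSE` rather than an error, so that map
#'   consumers can mask the voxel.
#' @examples
#' x <- offsets_experimental()
#' z <- lorentzian(x, 0.8, 0.05, 60 / 127.731, 1)
#' fit <- fit_lorentzian(zspectrum(x, z), larmor_mhz = 127.731)
#' coef(fit)[["fwhm_hz"]]   # 60
#' @export
fit_lorentzian <- function(spec, larmor_mhz = NULL, fit_window_ppm = 5) {
  if (inherits(spec, "zspectrum")) {
    if (is.null(larmor_mhz)) larmor_mhz <- spec$metadata$larmor_mhz
    x <- spec$offsets_ppm; y <- spec$intensities
  } else {
    df <- as.data.frame(spec)
    x <- df$offset_ppm; y <- df$z
  }
  if (is.null(larmor_mhz)) larmor_mhz <- larmor_mhz(3)
  keep <- is.finite(x) & is.finite(y) & abs(x) <= fit_window_ppm
  x <- x[keep]; y <- y[keep]
  out <- structure(
    list(coefficients = c(amplitude = NA_real_, center_ppm = NA_real_,
                          fwhm_ppm = NA_real_, fwhm_hz = NA_real_,
                          baseline = NA_real_),
         residual_rms = NA_real_, converged = FALSE,
         larmor_mhz = larmor_mhz, data = data.frame(offset_ppm = x, z = y)),
    class = "ds_lorentzian")
  if (length(x) < 6) return(out)

  a0 <- max(1 - min(y), 0.05)
  c0 <- x[which.min(y)]
  outer <- abs(x) >= 4
  b0 <- if (any(outer)) mean(y[outer]) else max(y)
  b0 <- min(max(b0, 0.8), 1.1)
  below <- x[y < b0 - a0 / 2]
  f0 <- if (length(below) > 1) diff(range(below)) else 30 / larmor_mhz
  f0 <- min(max(f0, 2 / larmor_mhz), 900 / larmor_mhz)
  c0 <- min(max(c0, -0.9), 0.9)

  resid_fn <- function(p) {
    h <- (p[3] / 2)^2
    y - (p[4] - p[1] * h / ((x - p[2])^2 + h))
  }
  ## d(residual)/dp with residual = y - model, model = b - a h / ((x-c)^2 + h)
  jac_fn <- function(p) {
    h <- (p[3] / 2)^2
    den <- (x - p[2])^2 + h
    cbind(a = h / den,
          cc = p[1] * h * 2 * (x - p[2]) / den^2,
          w = p[1] * (p[3] / 2) * (x - p[2])^2 / den^2,
          b = rep(-1, length(x)))
  }
  lower <- c(0, -1, 1 / larmor_mhz, 0.8)
  upper <- c(1.5, 1, 1000 / larmor_mhz, 1.1)
  try_fit <- function(p0) {
    r <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lower), upper), fn = resid_fn,
                         jac = jac_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(r) && r$info %in% 1:4) r else NULL
  }
  ## deterministic multi-start; keep the lowest-RSS solution (non-Lorentzian
  ## shapes can have several near-equal local minima)
  fits <- list(try_fit(c(a0, c0, f0, b0)),
               try_fit(c(a0, c0, f0 * 2, b0)),
               try_fit(c(a0, c0, max(f0 * 0.5, 2 / larmor_mhz), b0)))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) return(out)
  rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  fit <- fits[[which.min(rss)]]
  p <- fit$par
  out$coefficients <- c(amplitude = p[1], center_ppm = p[2],
                        fwhm_ppm = p[3], fwhm_hz = p[3] * larmor_mhz,
                        baseline = p[4])
  out$residual_rms <- sqrt(mean(fit$fvec^2))
  out$converged <- TRUE
  out
}

#' @export
print.ds_lorentzian <- function(x, ...) {
  if (!x$converged) {
    cat("<ds_lorentzian> fit did not converge\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf("<ds_lorentzian> FWHM %.2f Hz (%.4f ppm), center %+.3f ppm, depth %.3f, baseline %.3f\n",
              cf[["fwhm_hz"]], cf[["fwhm_ppm"]], cf[["center_ppm"]],
              cf[["amplitude"]], cf[["baseline"]]))
  invisible(x)
}

#' @export
summary.ds_lorentzian <- function(object, ...) {
  cat("Single-Lorentzian direct-saturation fit\n")
  cat(sprintf("  points: %d, larmor %.3f MHz, converged: %s\n",
              nrow(object$data), object$larmor_mhz, object$converged))
  if (object$converged) {
    print(round(object$coefficients, 5))
    cat(sprintf("  residual RMS: %.3g\n", object$residual_rms))
  }
  invisible(object)
}

#' @export
coef.ds_lorentzian <- function(object, ...) object$coefficients

#' @export
predict.ds_lorentzian <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$offset_ppm else {
    if (is.list(newdata)) newdata$offset_ppm else newdata
  }
  cf <- object$coefficients
  lorentzian(x, cf[["amplitude"]], cf[["center_ppm"]], cf[["fwhm_ppm"]],
             cf[["baseline"]])
}

#' @export
fitted.ds_lorentzian <- function(object, ...) predict(object)

#' @export
residuals.ds_lorentzian <- function(object, ...) {
  object$data$z - fitted(object)
}

#' @export
plot.ds_lorentzian <- function(x, ...) {
  graphics::plot(x$data$offset_ppm, x$data$z, xlab = "offset (ppm)",
                 ylab = "S/S0", xlim = rev(range(x$data$offset_ppm)), ...)
  if (x$converged) {
    xx <- seq(min(x$data$offset_ppm), max(x$data$offset_ppm), length.out = 400)
    graphics::lines(xx, predict(x, xx), col = "red3")
  }
  invisible(x)
}

#' Closed-form direct-saturation linewidth under continuous-wave saturation
#'
#' Low-B1 steady-state linewidth of the water line:
#' \deqn{LW = \frac{1}{\pi}\sqrt{\frac{R_1 R_2^2 + \omega_1^2 R_2}{R_1}}}
#' with \eqn{\omega_1 = \gamma B_1} in rad/s. The approximate form drops
#' the \eqn{R_1 R_2^2} term (valid when \eqn{\omega_1^2 \gg R_1 R_2}).
#'
#' @param R1,R2 Longitudinal / transverse relaxation rates (1/s, > 0).
#' @param b1_uT Saturation amplitude in microtesla (>= 0).
#' @param approximate Use the high-saturation approximation.
#' @return Linewidth (FWHM) in Hz. At `b1 = 0` the full form collapses to
#'   `R2 / pi`.
#' @export
analytic_lw <- function(R1, R2, b1_uT, approximate = FALSE) {
  if (R1 <= 0 || R2 <= 0) stop("R1 and R2 must be positive")
  if (b1_uT < 0) stop("b1_uT must be >= 0")
  w1 <- gyromagnetic_ratio() * b1_uT
  if (approximate) {
    sqrt(w1^2 * R2 / R1) / pi
  } else {
    sqrt((R1 * R2^2 + w1^2 * R2) / R1) / pi
  }
}
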