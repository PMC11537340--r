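## Pool systems: a data frame with one row per proton pool.  The first
## pool is always water (shift 0 ppm, proton fraction 1); exchanging
## solute pools carry an exchange rate towards water and a proton
## fraction relative to water protons.

#' Define a proton pool
#'
#' A pool is one exchanging proton species: water itself, or a solute
#' pool such as a glucose hydroxyl resonance, characterised by its
#' chemical shift relative to water, longitudinal and transverse
#' relaxation times, exchange rate towards water and proton fraction.
#'
#' @param label Pool name. The water pool must be labelled `"water"`.
#' @param shift_ppm Chemical shift relative to water (ppm).
#' @param T1_s,T2_s Relaxation times in seconds. Both must be positive;
#'   `T2 <= T1` is deliberately not enforced because apparent blood values
#'   can violate the naive bound.
#' @param k_hz Exchange rate towards water in Hz (0 for water itself).
#' @param fraction Proton fraction relative to water protons (1 for water).
#' @return One-row data frame with class `"bm_pool"` usable in
#'   [pool_system()].
#' @examples
#' pool("water", 0, 3.48, 2.78)
#' pool("OH-2,3,4", 1.28, 1.2, 0.1, k_hz = 6500, fraction = 1.5e-4)
#' @export
pool <- function(label, shift_ppm, T1_s, T2_s, k_hz = 0, fraction = 1) {
  stopifnot(is.character(label), length(label) == 1)
  if (!is.finite(shift_ppm)) stop("shift_ppm must be finite")
  if (!is.finite(T1_s) || T1_s <= 0) stop("T1_s must be positive")
  if (!is.finite(T2_s) || T2_s <= 0) stop("T2_s must be positive")
  if (!is.finite(k_hz) || k_hz < 0) stop("k_hz must be >= 0")
  if (identical(label, "water")) {
    fraction <- 1
  } else if (!is.finite(fraction) || fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1)")
  }
  p <- data.frame(label = label, shift_ppm = shift_ppm, T1_s = T1_s,
                  T2_s = T2_s, k_hz = k_hz, fraction = fraction,
                  stringsAsFactors = FALSE)
  class(p) <- c("bm_pool", class(p))
  p
}

#' Assemble a validated pool system
#'
#' Combines a water pool and any number of solute pools into the pool
#' table consumed by the Bloch-McConnell generator. Exactly one pool must
#' be water (label `"water"`, shift 0, fraction 1) and it is moved to the
#' first row.
#'
#' @param ... Pools created with [pool()], or data frames of pools.
#' @return Data frame of pools, water first, class `"bm_pool_system"`.
#' @export
pool_system <- function(...) {
  pools <- do.call(rbind, lapply(list(...), as.data.frame))
  iw <- which(pools$label == "water")
  if (length(iw) == 0) stop("pool system needs a pool labelled 'water'")
  if (length(iw) > 1) stop("two pools labelled water")
  if (abs(pools$shift_ppm[iw]) > 1e-12) stop("water pool must sit at 0 ppm")
  if (pools$fraction[iw] != 1) stop("water pool must have fraction 1")
  pools <- rbind(pools[iw, , drop = FALSE], pools[-iw, , drop = FALSE])
  rownames(pools) <- NULL
  class(pools) <- c("bm_pool_system", "data.frame")
  pools
}

#' Pulsed saturation train
#'
#' Describes the RF saturation preparation: a train of identical shaped
#' pulses. The default reproduces a train of 10 consecutive 50-ms
#' sinc-Gaussian pulses with 0.5 uT peak amplitude (total saturation
#' time 0.5 s).
#'
#' @param shape `"sinc_gauss"` (a single-main-lobe sinc apodised by a
#'   Gaussian window) or `"block"` (constant amplitude; the continuous-wave
#'   limit when `n_pulses = 1`).
#' @param n_pulses Number of pulses (>= 1).
#' @param pulse_duration_s Duration of one pulse in seconds.
#' @param b1_peak_uT Peak B1 amplitude in microtesla.
#' @param interpulse_delay_s Gap between consecutive pulses in seconds
#'   (0: pulses are contiguous).
#' @param samples_per_pulse Number of piecewise-constant samples used to
#'   discretise the envelope (>= 8). 64 leaves fitted linewidths stable
#'   to well under 1 percent on doubling.
#' @param sinc_lobes Zero crossings of the sinc term per half-window; 1
#'   gives a single dominant lobe filling the pulse.
#' @param gauss_sigma_frac Gaussian window standard deviation as a
#'   fraction of the pulse duration.
#' @return Object of class `"pulse_train"`.
#' @examples
#' pulse_train()                      # the default DS-DGE train
#' pulse_train(shape = "block", n_pulses = 1, pulse_duration_s = 2)
#' @export
pulse_train <- function(shape = c("sinc_gauss", "block"),
                        n_pulses = 10,
                        pulse_duration_s = 0.05,
                        b1_peak_uT = 0.5,
                        interpulse_delay_s = 0,
                        samples_per_pulse = 64,
                        sinc_lobes = 1,
                        gauss_sigma_frac = 0.25) {
  shape <- match.arg(shape)
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  if (!is.finite(pulse_duration_s) || pulse_duration_s <= 0)
    stop("pulse_duration_s must be positive")
  if (b1_peak_uT < 0) stop("b1_peak_uT must be >= 0")
  if (interpulse_delay_s < 0) stop("interpulse_delay_s must be >= 0")
  if (samples_per_pulse < 8) stop("samples_per_pulse must be >= 8")
  structure(
    list(shape = shape, n_pulses = as.integer(n_pulses),
         pulse_duration_s = pulse_duration_s, b1_peak_uT = b1_peak_uT,
         interpulse_delay_s = interpulse_delay_s,
         samples_per_pulse = as.integer(samples_per_pulse),
         sinc_lobes = sinc_lobes, gauss_sigma_frac = gauss_sigma_frac),
    class = "pulse_train")
}

#' Total saturation time of a pulse train
#'
#' @param train A [pulse_train()].
#' @return Seconds: `n_pulses * pulse_duration + (n_pulses - 1) * delay`.
#' @export
saturation_time <- function(train) {
  train$n_pulses * train$pulse_duration_s +
    (train$n_pulses - 1) * train$interpulse_delay_s
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %s, %d x %.0f ms, B1peak %.2f uT, tsat %.3f s\n",
              x$shape, x$n_pulses, 1000 * x$pulse_duration_s,
              x$b1_peak_uT, saturation_time(x)))
  invisible(x)
}

#' Simulation / acquisition protocol
#'
#' Offset schedule, static field and repetition timing for Z-spectrum
#' simulation. Spectra are indexed from negative to positive ppm with
#' positive offsets downfield of water.
#'
#' @param offsets_ppm Saturation offsets in ppm. Default: the 41-offset
#'   simulation schedule from -10 to +10 ppm ([offsets_simulation()]).
#' @param field_strength_t Static field in tesla.
#' @param tr_s Repetition time (one saturation block plus recovery) in
#'   seconds; must be at least the total saturation time.
#' @param initial_state `"cycled_steady_state"` repeats
#'   saturation/readout/recovery cycles, spoiling transverse magnetization
#'   at each readout, until the readout water Mz converges -- the dynamic
#'   acquisition regime; `"thermal"` starts each offset from equilibrium
#'   and applies a single train.
#' @param spoil_transverse Spoil transverse magnetization at the end of
#'   every TR cycle (the crushed EPI readout). Only meaningful for cycled
#'   steady state.
#' @return Object of class `"sim_protocol"`; `larmor_mhz` is derived from
#'   the field strength.
#' @export
sim_protocol <- function(offsets_ppm = offsets_simulation(),
                         field_strength_t = 3,
                         tr_s = 1.2,
                         initial_state = c("cycled_steady_state", "thermal"),
                         spoil_transverse = TRUE) {
  initial_state <- match.arg(initial_state)
  if (length(offsets_ppm) == 0) stop("offsets_ppm must be non-empty")
  if (any(!is.finite(offsets_ppm))) stop("offsets_ppm must be finite")
  if (tr_s <= 0) stop("tr_s must be positive")
  structure(
    list(offsets_ppm = offsets_ppm,
         field_strength_t = field_strength_t,
         larmor_mhz = larmor_mhz(field_strength_t),
         tr_s = tr_s,
         initial_state = initial_state,
         spoil_transverse = spoil_transverse),
    class = "sim_protocol")
}

#' @export
print.sim_protocol <- function(x, ...) {
  cat(sprintf("<sim_protocol> %d offsets [%.2f, %.2f] ppm, %.1f T (%.3f MHz), TR %.2f s, %s\n",
              length(x$offsets_ppm), min(x$offsets_ppm), max(x$offsets_ppm),
              x$field_strength_t, x$larmor_mhz, x$tr_s, x$initial_state))
  invisible(x)
}

#' Standard offset schedules
#'
#' `offsets_simulation()` is the 41-offset schedule used for compartment
#' simulations (0 and +-\[0.036 ... 10\] ppm). `offsets_experimental()` is
#' the 28-offset schedule measured in vivo (+-\[0.1 ... 5\] ppm), onto
#' which simulated spectra are resampled before fitting.
#'
#' @return Numeric vector of offsets in ppm, ascending.
#' @export
offsets_simulation <- function() {
  half <- c(10, 5.0, 4.0, 3.0, 2.5, 2.0, 1.75, 1.5, 1.25, 1.0, 0.80, 0.65,
            0.55, 0.48, 0.40, 0.33, 0.26, 0.18, 0.11, 0.036)
  sort(c(-half, 0, half))
}

#' @rdname offsets_simulation
#' @export
offsets_experimental <- function() {
  half <- c(5.0, 2.5, 2.0, 1.5, 1.2, 1.0, 0.80, 0.70, 0.60, 0.50, 0.40,
            0.30, 0.20, 0.10)
  sort(c(-half, half))
}
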