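## Field constants used throughout: proton gyromagnetic ratio and the
## ppm <-> Hz conversion.  All offsets and chemical shifts are in ppm
## relative to water; all B1 amplitudes in microtesla.

#' Gyromagnetic ratio of the proton
#'
#' @param units `"rad_s_uT"` (default) returns \eqn{\gamma} in rad/s per
#'   microtesla, the unit used for \eqn{\omega_1 = \gamma B_1}; `"mhz_t"`
#'   returns \eqn{\gamma/2\pi} in MHz per tesla.
#' @return Numeric scalar.
#' @export
gyromagnetic_ratio <- function(units = c("rad_s_uT", "mhz_t")) {
  units <- match.arg(units)
  switch(units,
    rad_s_uT = 2 * pi * 42.577 * 1e6 * 1e-6, # = 267.52 rad/s/uT
    mhz_t = 42.577
  )
}

#' Proton Larmor frequency for a given static field
#'
#' @param field_strength_t Static field in tesla (3 by default).
#' @return Larmor frequency in MHz (127.731 MHz at 3 T); 1 ppm corresponds
#'   to this many Hz.
#' @export
larmor_mhz <- function(field_strength_t = 3) {
  42.577 * field_strength_t
}

## Water proton reference concentration: 2 x 55,500 mM protons.
WATER_PROTON_MM <- 111000
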