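## Independent oracles and shared fixtures.

## ---- RK4 oracle ----------------------------------------------------------
## Fixed-step RK4 integration of the coupled Bloch-McConnell equations with
## the derivative written out directly from the pool parameters (independent
## of the package's generator-matrix construction).

bm_derivative <- function(M, pools, offset_ppm, b1_uT, larmor) {
  n <- nrow(pools)
  gamma <- 2 * pi * 42.577
  w1 <- gamma * b1_uT
  dM <- numeric(3 * n)
  for (i in seq_len(n)) {
    dw <- 2 * pi * larmor * (pools$shift_ppm[i] - offset_ppm)
    R1 <- 1 / pools$T1_s[i]; R2 <- 1 / pools$T2_s[i]
    mx <- M[3 * i - 2]; my <- M[3 * i - 1]; mz <- M[3 * i]
    dM[3 * i - 2] <- -R2 * mx + dw * my
    dM[3 * i - 1] <- -dw * mx - R2 * my + w1 * mz
    dM[3 * i]     <- -w1 * my - R1 * (mz - pools$fraction[i])
  }
  for (i in seq_len(n)[-1]) {
    kiw <- pools$k_hz[i]; kwi <- pools$fraction[i] * kiw
    for (c in 1:3) {
      j <- 3 * (i - 1) + c
      dM[j] <- dM[j] - kiw * M[j] + kwi * M[c]
      dM[c] <- dM[c] + kiw * M[j] - kwi * M[c]
    }
  }
  dM
}

rk4_step <- function(M, h, pools, offset_ppm, b1, larmor) {
  k1 <- bm_derivative(M, pools, offset_ppm, b1, larmor)
  k2 <- bm_derivative(M + h / 2 * k1, pools, offset_ppm, b1, larmor)
  k3 <- bm_derivative(M + h / 2 * k2, pools, offset_ppm, b1, larmor)
  k4 <- bm_derivative(M + h * k3, pools, offset_ppm, b1, larmor)
  M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

## propagate a thermal start through a full train, substeps per envelope
## sample, returning the water Mz.  The explicit RK4 step must resolve the
## fastest rate in the system (exchange, relaxation, precession), so the
## substep count adapts to the stiffness; `substeps` is a floor.
rk4_propagate <- function(pools, train, offset_ppm, larmor, substeps = 10) {
  env <- sample_pulse_envelope(train)
  M <- numeric(3 * nrow(pools))
  M[seq(3, length(M), by = 3)] <- pools$fraction
  rate_max <- max(pools$k_hz + 1 / pools$T2_s) +
    max(abs(2 * pi * larmor * (pools$shift_ppm - offset_ppm)))
  substeps <- max(substeps, ceiling(env$dt_s * rate_max / 0.3))
  h <- env$dt_s / substeps
  for (p in seq_len(train$n_pulses)) {
    for (a in env$amplitude_uT) {
      for (s in seq_len(substeps)) M <- rk4_step(M, h, pools, offset_ppm, a, larmor)
    }
    if (train$interpulse_delay_s > 0 && p < train$n_pulses) {
      hd <- train$interpulse_delay_s / (4 * substeps)
      for (s in seq_len(4 * substeps)) M <- rk4_step(M, hd, pools, offset_ppm, 0, larmor)
    }
  }
  M[3]
}

## ---- shared expensive fixtures ------------------------------------------
## Computed lazily once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

sim_table_fixture <- function() {
  if (is.null(.fixtures$tab)) .fixtures$tab <- simulation_table()
  .fixtures$tab
}

tissue_spectrum_fixture <- function(name, state = "normoglycemia") {
  key <- paste(name, state, sep = "|")
  if (is.null(.fixtures$comp_cache))
    .fixtures$comp_cache <- new.env(parent = emptyenv())
  if (is.null(.fixtures$zs)) .fixtures$zs <- list()
  if (is.null(.fixtures$zs[[key]])) {
    .fixtures$zs[[key]] <- tissue_zspectrum(name, state,
                                            cache = .fixtures$comp_cache)
  }
  .fixtures$zs[[key]]
}

## small water-only system used in several tests
water_system <- function(T1 = 1.5, T2 = 0.1) {
  pool_system(pool("water", 0, T1, T2))
}

## water + one hydroxyl-like pool
two_pool_system <- function(k = 5000, fraction = 2e-4, shift = 1.28,
                            T1w = 1.5, T2w = 0.1) {
  pool_system(pool("water", 0, T1w, T2w),
              pool("OH", shift, 1.2, 0.1, k_hz = k, fraction = fraction))
}
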