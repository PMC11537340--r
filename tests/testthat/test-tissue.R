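test_that("glucose pool fractions follow the proton-assignment arithmetic", {
  p0 <- glucose_pools(0)
  expect_equal(p0$fraction, rep(0, 4))
  p <- glucose_pools(5.55)
  ## 1.28 ppm pool: 3 protons x 5.55 mM / 111,000 mM = 1.5e-4
  expect_equal(p$fraction[p$shift_ppm == 1.28], 1.5e-4)
  expect_equal(p$fraction[p$shift_ppm == 0.66], 5e-5)
  expect_equal(sum(p$fraction), 5 * 5.55 / 111000)
  expect_error(glucose_pools(-1), ">= 0")
})

test_that("acidic tumor EES lowers every hydroxyl exchange rate", {
  pn <- glucose_pools(5, "normal")
  pa <- glucose_pools(5, "tumor_acidic")
  expect_true(all(pa$k_hz < pn$k_hz))
  expect_equal(pn$k_hz, c(2900, 6500, 5200, 14300))
  expect_equal(pa$k_hz, c(1500, 3100, 2500, 6000))
})

test_that("shipped tissue table satisfies the fraction and density constraints", {
  tab <- tissue_table()
  for (nm in names(tab$tissues)) {
    tis <- tab$tissues[[nm]]
    expect_equal(tis$blood_fraction + tis$EES_fraction + tis$cell_fraction, 1,
                 tolerance = 1e-9, label = nm)
    expect_equal(tis$arterial_subfraction + tis$venous_subfraction, 1,
                 tolerance = 1e-9, label = nm)
    ## water-density consistency: sum(f_i rho_i) reproduces rho_tis
    rho <- tis$blood_fraction * tis$blood_water_density +
      tis$EES_fraction * tis$EES_water_density +
      tis$cell_fraction * tis$cell_water_density
    expect_lt(abs(rho - tis$tissue_water_density), 0.01)
  }
})

test_that("tissue table overrides merge by key", {
  tab <- tissue_table(overrides = list(
    compartments = list(venous = list(T2_s = 0.06))))
  expect_equal(tab$compartments$venous$T2_s, 0.06)
  expect_equal(tab$compartments$venous$T1_s, 1.73)  # untouched
  expect_equal(tab$compartments$arterial$T2_s, 0.152)
})

test_that("compartment spectra need complete parameters", {
  expect_error(compartment_zspectrum(list(T1_s = 1, glucose_mM = list()),
                                     "normoglycemia"), "T2_s")
})

test_that("zero glucose makes glycemic states indistinguishable", {
  comp <- list(T1_s = 1.2, T2_s = 0.08,
               glucose_mM = list(normoglycemia = 0, hyperglycemia = 0),
               pH_regime = "normal")
  prot <- sim_protocol(offsets_ppm = c(-1, -0.3, 0.3, 1))
  tr <- pulse_train(samples_per_pulse = 16)
  z1 <- compartment_zspectrum(comp, "normoglycemia", tr, prot)
  z2 <- compartment_zspectrum(comp, "hyperglycemia", tr, prot)
  expect_equal(z1$intensities, z2$intensities)
})

test_that("hyperglycemia attenuates the compartment spectrum near water", {
  comp <- tissue_table()$compartments$CSF_EES
  prot <- sim_protocol(offsets_ppm = c(-2.5, -1, -0.5, -0.2, 0.2, 0.5, 1, 2.5))
  tr <- pulse_train(samples_per_pulse = 32)
  zn <- compartment_zspectrum(comp, "normoglycemia", tr, prot)$intensities
  zh <- compartment_zspectrum(comp, "hyperglycemia", tr, prot)$intensities
  expect_true(all(zh <= zn + 1e-9))
})

test_that("mixing returns the EES spectrum for a pure-EES tissue", {
  tab <- tissue_table()
  grid <- c(-2, -1, 0, 1, 2)
  ees <- zspectrum(grid, c(0.9, 0.7, 0.2, 0.7, 0.9))
  out <- mix_tissue_zspectrum(tab$tissues$CSF, list(EES = ees))
  expect_equal(out$intensities, ees$intensities)
})

test_that("mixing identical compartment spectra returns that spectrum", {
  grid <- seq(-3, 3)
  z <- zspectrum(grid, rep(0.6, length(grid)))
  tis <- list(blood_fraction = 0.05, EES_fraction = 0.4, cell_fraction = 0.55,
              arterial_subfraction = 0.3, venous_subfraction = 0.7,
              blood_water_density = 0.856, EES_water_density = 0.938,
              cell_water_density = 0.7,
              tissue_water_density = 0.05 * 0.856 + 0.4 * 0.938 + 0.55 * 0.7)
  out <- mix_tissue_zspectrum(tis, list(arterial = z, venous = z, EES = z,
                                        cell = z))
  expect_equal(out$intensities, z$intensities)
})

test_that("gray-matter mixing weights reproduce the hand-computed sum", {
  tab <- tissue_table()
  gm <- tab$tissues$GM
  grid <- 0
  mk <- function(v) zspectrum(grid, v)
  out <- mix_tissue_zspectrum(gm, list(arterial = mk(0.9), venous = mk(0.8),
                                       EES = mk(0.4), cell = mk(0.6)))
  hand <- (0.038 * 0.856 * (0.3 * 0.9 + 0.7 * 0.8) +
             0.22 * 0.938 * 0.4 + 0.742 * 0.809 * 0.6) / 0.839
  expect_equal(out$intensities, hand)
})

test_that("mixing preserves the intensity range of its components", {
  grid <- seq(-2, 2, by = 0.5)
  set.seed(7)
  comp <- replicate(4, runif(length(grid), 0.2, 1), simplify = FALSE)
  tis <- list(blood_fraction = 0.1, EES_fraction = 0.5, cell_fraction = 0.4,
              arterial_subfraction = 0.3, venous_subfraction = 0.7,
              blood_water_density = 0.9, EES_water_density = 0.9,
              cell_water_density = 0.9, tissue_water_density = 0.9)
  out <- mix_tissue_zspectrum(tis, list(arterial = zspectrum(grid, comp[[1]]),
                                        venous = zspectrum(grid, comp[[2]]),
                                        EES = zspectrum(grid, comp[[3]]),
                                        cell = zspectrum(grid, comp[[4]])))
  lo <- pmin(comp[[1]], comp[[2]], comp[[3]], comp[[4]])
  hi <- pmax(comp[[1]], comp[[2]], comp[[3]], comp[[4]])
  expect_true(all(out$intensities >= lo - 1e-12))
  expect_true(all(out$intensities <= hi + 1e-12))
})

test_that("mixing refuses mismatched offset grids", {
  tab <- tissue_table()
  expect_error(
    mix_tissue_zspectrum(tab$tissues$CSF,
                         list(EES = zspectrum(c(-1, 1), c(0.5, 0.5)))),
    NA)
  tis <- tab$tissues$GM
  z1 <- zspectrum(c(-1, 0, 1), c(0.5, 0.2, 0.5))
  z2 <- zspectrum(c(-1, 0.1, 1), c(0.5, 0.2, 0.5))
  expect_error(mix_tissue_zspectrum(tis, list(arterial = z1, venous = z1,
                                              EES = z2, cell = z1)),
               "offset grids differ")
})

test_that("Rician noise: identity at zero, seeded determinism, positive bias", {
  z <- zspectrum(seq(-5, 5), rep(1, 11))
  expect_identical(add_rician_noise(z, 0)$intensities, z$intensities)
  n1 <- add_rician_noise(z, 0.02, seed = 42)$intensities
  n2 <- add_rician_noise(z, 0.02, seed = 42)$intensities
  expect_identical(n1, n2)
  n3 <- add_rician_noise(z, 0.02, seed = 43)$intensities
  expect_false(identical(n1, n3))
  ## Monte-Carlo oracle for the Rician positive bias at S = 1
  big <- zspectrum(seq_len(1e5), rep(1, 1e5))
  m <- mean(add_rician_noise(big, 0.02, seed = 1)$intensities)
  set.seed(1)
  oracle <- mean(sqrt((1 + rnorm(1e5, 0, 0.02))^2 + rnorm(1e5, 0, 0.02)^2))
  expect_gt(m, 1)
  expect_equal(m, oracle, tolerance = 1e-3)
})

test_that("resampling: identity on the same grid, closed form on a Lorentzian", {
  x41 <- offsets_simulation()
  z <- zspectrum(x41, lorentzian(x41, 0.8, 0, 0.6, 1))
  same <- resample_offsets(z, x41)
  expect_equal(same$intensities, z$intensities, tolerance = 1e-12)
  x28 <- offsets_experimental()
  expect_length(x28, 28)
  res <- resample_offsets(z, x28)
  expect_equal(res$intensities, lorentzian(x28, 0.8, 0, 0.6, 1),
               tolerance = 1e-3)
  expect_error(resample_offsets(z, c(-12, 0)), "extrapolation")
})

test_that("Z-spectrum CSV round trip preserves data and metadata", {
  z <- zspectrum(c(-1, 0, 1), c(0.9, 0.1, 0.9), metadata = list(b1 = 0.5))
  f <- tempfile(fileext = ".csv")
  write_zspectrum(z, f)
  back <- read_zspectrum(f)
  expect_equal(back$intensities, z$intensities)
  expect_equal(back$metadata$b1, 0.5)
  unlink(c(f, paste0(f, ".json")))
})
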