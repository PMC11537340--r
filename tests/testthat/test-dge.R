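F0 <- larmor_mhz(3)

## build a synthetic raw series: every voxel carries a Lorentzian Z-spectrum
## of the given width (Hz) per dynamic, scaled by an S0 gain field
make_series <- function(lw_hz, gain, schedule = dge_schedule(),
                        infusion_start = 3, amplitude = 0.85) {
  dims <- dim(gain)
  n_dyn <- ncol(lw_hz)             # lw_hz: voxel x dynamic matrix
  raw <- array(0, c(dims, length(schedule) * n_dyn))
  for (d in seq_len(n_dyn)) {
    for (j in seq_along(schedule)) {
      zv <- lorentzian(schedule[j], amplitude, 0, lw_hz[, d] / F0, 1)
      raw[, , , (d - 1) * length(schedule) + j] <- array(zv * c(gain), dims)
    }
  }
  dynamic_series(raw, offset_schedule = schedule,
                 infusion_start_dynamic = infusion_start, larmor_mhz = F0)
}

test_that("normalisation recovers Z exactly under a known S0 gain field", {
  dims <- c(3, 3, 2)
  gain <- array(100 + 10 * seq_len(prod(dims)), dims)
  lw <- matrix(60, prod(dims), 4)
  raw <- make_series(lw, gain)
  norm <- normalize_dynamic(raw)
  sched <- dge_schedule()
  ## Z at +-10 ppm is not exactly 1 for a Lorentzian with baseline 1, so the
  ## recovered Z equals the constructed Z divided by the +-10 ppm average
  zgen <- lorentzian(sched, 0.85, 0, 60 / F0, 1)
  s0 <- mean(zgen[c(2, 4)])
  expect_equal(norm$data[1, 1, 1, seq_along(sched)], zgen / s0,
               tolerance = 1e-9)
  ## scale invariance: doubling the raw data changes nothing
  raw2 <- raw; raw2$data <- raw2$data * 2
  norm2 <- normalize_dynamic(raw2)
  expect_equal(norm2$data, norm$data, tolerance = 1e-12)
})

test_that("uniform raw intensities normalise to Z = 1", {
  sched <- dge_schedule()
  raw <- dynamic_series(array(500, c(2, 2, 1, length(sched) * 3)),
                        infusion_start_dynamic = 2)
  norm <- normalize_dynamic(raw)
  expect_true(all(norm$data == 1))
})

test_that("a schedule without duplicate +-10 ppm references is refused", {
  sched <- c(10, -10, offsets_experimental())
  raw <- array(1, c(2, 2, 1, length(sched) * 3))
  expect_error(normalize_dynamic(dynamic_series(raw, offset_schedule = sched,
                                                infusion_start_dynamic = 2)),
               "twice")
})

test_that("linewidth maps recover a two-region phantom bimodally", {
  dims <- c(4, 4, 1)
  gain <- array(1000, dims)
  lw_true <- c(rep(40, 8), rep(80, 8))
  lw <- matrix(lw_true, prod(dims), 2)
  series <- normalize_dynamic(make_series(lw, gain, infusion_start = 1))
  maps <- compute_lw_maps(series)
  expect_equal(dim(maps), c(dims, 2))
  expect_equal(c(maps[, , , 1]), lw_true, tolerance = 1e-4)
  expect_lt(attr(maps, "failed_fraction"), 0.01)
})

test_that("masked voxels are excluded from fitting", {
  dims <- c(3, 3, 1)
  gain <- array(1, dims)
  lw <- matrix(60, prod(dims), 2)
  raw <- make_series(lw, gain, infusion_start = 1)
  ## voxel (1,1,1) is pure noise and outside the mask
  set.seed(1)
  raw$data[1, 1, 1, ] <- abs(rnorm(dim(raw$data)[4], 0, 1))
  raw$mask[1, 1, 1] <- FALSE
  maps <- compute_lw_maps(normalize_dynamic(raw))
  expect_true(is.na(maps[1, 1, 1, 1]))
  expect_false(anyNA(maps[2, , , ]))
})

test_that("baseline outlier rejection follows the +-2 SD rule", {
  ## 8 identical baseline values: kept, zero rejected
  lw <- array(60, c(1, 1, 1, 8))
  bl <- baseline_lw(lw, 8)
  expect_equal(bl$lw_base[1, 1, 1], 60)
  expect_equal(bl$rejected[1, 1, 1], 0L)
  ## {60 x7, 100}: mean 65, sd sqrt(200) = 14.14, mean + 2sd = 93.3 < 100,
  ## so the 100 is rejected and the baseline is 60
  vals <- c(rep(60, 7), 100)
  lw2 <- array(vals, c(1, 1, 1, 8))
  bl2 <- baseline_lw(lw2, 8)
  expect_equal(bl2$rejected[1, 1, 1], 1L)
  expect_equal(bl2$lw_base[1, 1, 1], 60)
  ## with a tight baseline plus one gross outlier (the motivating motion
  ## artifact case), rejection pulls the baseline towards the median
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(7, 50, 2)
    v <- c(v, 50 + sample(c(-30, 30), 1))[sample(8)]
    b <- baseline_lw(array(v, c(1, 1, 1, 8)), 8)
    expect_equal(b$rejected[1, 1, 1], 1L)
    expect_lt(abs(b$lw_base[1, 1, 1] - median(v)),
              abs(mean(v) - median(v)))
  }
  expect_error(baseline_lw(lw, 2), "at least 3")
})

test_that("exactly the pre-infusion dynamics form the baseline", {
  lw <- array(rep(c(rep(50, 8), rep(70, 4)), each = 1), c(1, 1, 1, 12))
  bl <- baseline_lw(lw, 8)
  expect_equal(bl$lw_base[1, 1, 1], 50)
})

test_that("delta-LW arithmetic and the baseline floor", {
  lw <- array(c(45.15, 18.08), c(1, 2, 1, 1))
  base <- array(c(42, 16), c(1, 2, 1))
  dl <- delta_lw(lw, base)
  expect_equal(dl[1, 1, 1, 1], 7.5)
  expect_equal(dl[1, 2, 1, 1], 13)
  ## identical maps give exactly zero
  dl0 <- delta_lw(array(42, c(1, 1, 1, 3)), array(42, c(1, 1, 1)))
  expect_true(all(dl0 == 0))
  ## sub-floor baseline is masked
  dlf <- delta_lw(array(10, c(1, 1, 1, 1)), array(2, c(1, 1, 1)), lw_floor = 5)
  expect_true(is.na(dlf[1, 1, 1, 1]))
})

test_that("AUC equals the mean delta-LW and the algebraic identity holds", {
  n_dyn <- 12; start <- 4
  set.seed(11)
  lw_t <- c(rep(40, start), 40 * (1 + 0.1 * runif(n_dyn - start)))
  lw <- array(rep(lw_t, each = 1), c(1, 1, 1, n_dyn))
  bl <- baseline_lw(lw, start)
  dl <- delta_lw(lw, bl$lw_base)
  auc <- auc_map(dl, start, "full_post_start")
  ## identity: the windowed mean of the per-dynamic relative change equals
  ## the relative change of the window-averaged linewidth
  lw_avg <- mean(lw_t[(start + 1):n_dyn])
  eq3 <- 100 * (lw_avg - 40) / 40
  expect_equal(auc[1, 1, 1], eq3, tolerance = 1e-12)
  ## constant response c -> AUC = c
  dl_c <- array(rep(c(rep(0, start), rep(5.5, n_dyn - start)), each = 1),
                c(1, 1, 1, n_dyn))
  expect_equal(auc_map(dl_c, start, "full_post_start")[1, 1, 1], 5.5)
})

test_that("the infusion-block window is derived from dose and rate", {
  n_dyn <- 40; start <- 8
  ## 35 g at 6.25 g/min over 38.4-s dynamics -> ceil(8.75) = 9 dynamics
  step <- c(rep(0, start), rep(10, 9), rep(2, n_dyn - start - 9))
  dl <- array(rep(step, each = 1), c(1, 1, 1, n_dyn))
  auc_block <- auc_map(dl, start, "infusion_block_only")
  expect_equal(auc_block[1, 1, 1], 10)
  auc_full <- auc_map(dl, start, "full_post_start")
  expect_equal(auc_full[1, 1, 1], mean(step[(start + 1):n_dyn]))
})

test_that("ROI time curves average and smooth as specified", {
  dl <- array(0, c(2, 2, 1, 5))
  dl[1, 1, 1, ] <- c(0, 0, 3, 0, 0)
  dl[2, 1, 1, ] <- c(0, 0, 3, 0, 0)
  roi <- array(FALSE, c(2, 2, 1)); roi[1:2, 1, 1] <- TRUE
  cur <- roi_timecurve(dl, roi, dynamic_duration_s = 38.4)
  expect_equal(cur$raw, c(0, 0, 3, 0, 0))
  expect_equal(cur$smoothed[3], 1)            # centered 3-point average
  expect_equal(cur$smoothed[1], 0)            # edge replication
  expect_equal(cur$time_s[1], 0.5 * 38.4)
  ## constant curve: smoothing is the identity
  dlc <- array(2, c(1, 1, 1, 6))
  cc <- roi_timecurve(dlc, array(TRUE, c(1, 1, 1)))
  expect_equal(cc$smoothed, cc$raw)
  ## single-voxel ROI reproduces that voxel's series
  one <- array(FALSE, c(2, 2, 1)); one[1, 1, 1] <- TRUE
  c1 <- roi_timecurve(dl, one)
  expect_equal(c1$raw, dl[1, 1, 1, ])
  expect_error(roi_timecurve(dl, array(FALSE, c(2, 2, 1))), "empty ROI")
})

test_that("the pipeline is invariant to a global intensity rescaling", {
  dims <- c(3, 3, 1)
  gain <- array(800, dims)
  n_dyn <- 6
  lw <- matrix(rep(c(50, 50, 50, 60, 60, 60), each = prod(dims)),
               prod(dims), n_dyn)
  raw <- make_series(lw, gain)
  res1 <- dge_pipeline(raw)
  raw2 <- raw; raw2$data <- raw2$data * 3.7
  res2 <- dge_pipeline(raw2)
  expect_equal(res1$lw_base, res2$lw_base, tolerance = 1e-6)
  expect_equal(res1$auc_full, res2$auc_full, tolerance = 1e-6)
})

test_that("dynamic series round-trips through NIfTI + sidecar", {
  sched <- dge_schedule()
  raw <- dynamic_series(array(runif(2 * 2 * 2 * length(sched) * 3),
                              c(2, 2, 2, length(sched) * 3)),
                        infusion_start_dynamic = 2,
                        dynamic_duration_s = 38.4)
  pre <- file.path(tempdir(), "series_rt")
  write_dynamic_series(raw, pre)
  back <- read_dynamic_series(pre)
  expect_equal(back$data, raw$data, tolerance = 1e-6)
  expect_equal(back$offset_schedule, raw$offset_schedule)
  expect_equal(back$infusion_start_dynamic, raw$infusion_start_dynamic)
  unlink(paste0(pre, c(".nii.gz", ".json", "_mask.nii.gz")))
})
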