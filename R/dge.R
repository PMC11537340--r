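## DS-DGE post-processing: normalisation of dynamic Z-spectral series,
## per-voxel per-dynamic Lorentzian linewidth maps, baseline with
## +-2 SD outlier rejection, relative linewidth change, AUC maps and ROI
## time curves.

#' Default dynamic acquisition offset schedule
#'
#' The 32-offset schedule of one dynamic: two acquisitions each at +10
#' and -10 ppm (the second of each pair provides the S0 normalisation),
#' followed by 28 offsets alternating around water from +-5 down to
#' +-0.1 ppm.
#'
#' @return Numeric vector of 32 offsets (ppm) in acquisition order.
#' @export
dge_schedule <- function() {
  half <- c(5.0, 2.5, 2.0, 1.5, 1.2, 1.0, 0.80, 0.70, 0.60, 0.50, 0.40,
            0.30, 0.20, 0.10)
  c(10, 10, -10, -10, as.vector(rbind(half, -half)))
}

#' Dynamic Z-spectral image series
#'
#' Container for a 4D dynamic saturation-image series: spatial dimensions
#' x, y, z and a fourth dimension running over offset (fastest) then
#' dynamic.
#'
#' @param data 4D numeric array `(x, y, z, n_offsets * n_dynamics)`.
#' @param offset_schedule Offsets (ppm) of one dynamic, in acquisition
#'   order; identical across dynamics.
#' @param dynamic_duration_s Duration of one dynamic in seconds.
#' @param infusion_start_dynamic Number of pre-infusion (baseline)
#'   dynamics; infusion starts after this dynamic.
#' @param mask Logical/0-1 3D array of voxels to process; default all.
#' @param larmor_mhz Larmor frequency (MHz) for linewidth conversion.
#' @param normalized Whether `data` already holds Z values.
#' @param motion_corrected Provenance flag: whether an external rigid
#'   motion-correction hook was applied upstream.
#' @return Object of class `"dynamic_series"`.
#' @export
dynamic_series <- function(data, offset_schedule = dge_schedule(),
                           dynamic_duration_s = 38.4,
                           infusion_start_dynamic = 8,
                           mask = NULL,
                           larmor_mhz = 3 * 42.577,
                           normalized = FALSE,
                           motion_corrected = FALSE) {
  d <- dim(data)
  if (length(d) != 4) stop("data must be a 4D array")
  n_off <- length(offset_schedule)
  if (d[4] %% n_off != 0)
    stop("4th dimension must be a multiple of the offset schedule length")
  n_dyn <- d[4] %/% n_off
  if (infusion_start_dynamic >= n_dyn)
    stop("infusion_start_dynamic must be smaller than the number of dynamics")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  structure(
    list(data = data, offset_schedule = offset_schedule,
         n_dynamics = n_dyn, dynamic_duration_s = dynamic_duration_s,
         infusion_start_dynamic = infusion_start_dynamic,
         mask = array(as.logical(mask), d[1:3]),
         larmor_mhz = larmor_mhz, normalized = normalized,
         motion_corrected = motion_corrected),
    class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %dx%dx%d voxels, %d offsets x %d dynamics (%s), infusion after dynamic %d\n",
              d[1], d[2], d[3], length(x$offset_schedule), x$n_dynamics,
              if (x$normalized) "normalized" else "raw",
              x$infusion_start_dynamic))
  invisible(x)
}

## volume indices of dynamic d
dyn_index <- function(series, d) {
  n_off <- length(series$offset_schedule)
  (d - 1L) * n_off + seq_len(n_off)
}

## indices of the S0 reference acquisitions: second occurrence of +10
## and of -10 ppm in the schedule
s0_indices <- function(schedule) {
  ip <- which(schedule == 10)
  im <- which(schedule == -10)
  if (length(ip) < 2 || length(im) < 2)
    stop("offset schedule must contain +10 and -10 ppm each twice (S0 references)")
  c(ip[2], im[2])
}

#' Normalise a dynamic series to Z values
#'
#' Per voxel and per dynamic, S0 is the average of the second of the two
#' acquisitions at +10 and at -10 ppm; every intensity in that dynamic is
#' divided by S0. Voxels with non-positive S0 in any dynamic are removed
#' from the mask.
#'
#' @param raw A raw [dynamic_series()].
#' @return A normalised `dynamic_series` (Z values).
#' @export
normalize_dynamic <- function(raw) {
  stopifnot(inherits(raw, "dynamic_series"))
  if (raw$normalized) return(raw)
  ref <- s0_indices(raw$offset_schedule)
  out <- raw$data
  mask <- raw$mask
  for (d in seq_len(raw$n_dynamics)) {
    idx <- dyn_index(raw, d)
    s0 <- (raw$data[, , , idx[ref[1]], drop = FALSE] +
             raw$data[, , , idx[ref[2]], drop = FALSE]) / 2
    dm <- dim(raw$data)[1:3]
    s0 <- array(s0, dm)
    bad <- !(s0 > 0)
    mask <- mask & !bad
    s0[bad] <- 1  # placeholder; masked out
    for (j in idx)
      out[, , , j] <- array(raw$data[, , , j, drop = FALSE], dm) / s0
  }
  res <- raw
  res$data <- out
  res$mask <- mask
  res$normalized <- TRUE
  res
}

#' Per-dynamic linewidth maps
#'
#' Fits a single Lorentzian ([fit_lorentzian()]) to every masked voxel's
#' Z-spectrum in every dynamic (excluding the +-10 ppm normalisation
#' points) and returns the FWHM in Hz. Non-converged fits are set to
#' `NA`; a warning is emitted if more than half the fits inside the mask
#' fail.
#'
#' @param series A normalised [dynamic_series()].
#' @param fit_window_ppm Fit window half-width (ppm).
#' @return 4D array `(x, y, z, n_dynamics)` of linewidths in Hz, with
#'   attribute `failed_fraction`.
#' @export
compute_lw_maps <- function(series, fit_window_ppm = 5) {
  stopifnot(inherits(series, "dynamic_series"))
  if (!series$normalized) series <- normalize_dynamic(series)
  sched <- series$offset_schedule
  use <- abs(sched) <= fit_window_ppm
  x <- sched[use]
  dm <- dim(series$data)[1:3]
  lw <- array(NA_real_, c(dm, series$n_dynamics))
  vox <- which(series$mask, arr.ind = TRUE)
  n_fail <- 0L; n_tot <- 0L
  for (d in seq_len(series$n_dynamics)) {
    idx <- dyn_index(series, d)[use]
    for (r in seq_len(nrow(vox))) {
      y <- series$data[vox[r, 1], vox[r, 2], vox[r, 3], idx]
      fit <- fit_lorentzian(data.frame(offset_ppm = x, z = y),
                            larmor_mhz = series$larmor_mhz,
                            fit_window_ppm = fit_window_ppm)
      n_tot <- n_tot + 1L
      if (fit$converged) {
        lw[vox[r, 1], vox[r, 2], vox[r, 3], d] <- fit$coefficients[["fwhm_hz"]]
      } else {
        n_fail <- n_fail + 1L
      }
    }
  }
  if (n_tot > 0 && n_fail / n_tot > 0.5)
    warning(sprintf("%.0f%% of linewidth fits failed inside the mask",
                    100 * n_fail / n_tot))
  attr(lw, "failed_fraction") <- if (n_tot > 0) n_fail / n_tot else NA_real_
  lw
}

#' Baseline linewidth with outlier rejection
#'
#' Per voxel: mean and SD of the pre-infusion linewidths; baseline values
#' outside mean +- 2 SD are discarded (single pass) and the baseline
#' linewidth is the mean of the survivors.
#'
#' @param lw_maps 4D linewidth array from [compute_lw_maps()].
#' @param infusion_start Number of baseline dynamics (>= 3).
#' @return List with `lw_base` (3D, Hz; `NA` where all baseline values
#'   were missing) and `rejected` (3D rejection counts).
#' @export
baseline_lw <- function(lw_maps, infusion_start) {
  if (infusion_start < 3) stop("need at least 3 pre-infusion dynamics")
  base <- lw_maps[, , , seq_len(infusion_start), drop = FALSE]
  dm <- dim(base)[1:3]
  lw_base <- array(NA_real_, dm)
  rejected <- array(0L, dm)
  nb <- dim(base)[4]
  bmat <- matrix(base, prod(dm), nb)
  for (v in seq_len(nrow(bmat))) {
    vals <- bmat[v, ]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) next
    m <- mean(vals); s <- stats::sd(vals)
    if (!is.finite(s)) s <- 0
    keep <- vals >= m - 2 * s & vals <= m + 2 * s
    rejected[v] <- sum(!keep)
    if (any(keep)) lw_base[v] <- mean(vals[keep])
  }
  list(lw_base = lw_base, rejected = rejected)
}

#' Relative linewidth change maps
#'
#' \eqn{\Delta LW(t) = 100 (LW(t) - LW_{base}) / LW_{base}} per voxel and
#' dynamic. Voxels with baseline below `lw_floor` (or missing) are set to
#' `NA` to avoid blow-up.
#'
#' @param lw_maps 4D linewidth array (Hz).
#' @param lw_base 3D baseline linewidth (Hz).
#' @param lw_floor Minimum acceptable baseline linewidth (Hz).
#' @return 4D array of percent changes.
#' @export
delta_lw <- function(lw_maps, lw_base, lw_floor = 5) {
  ok <- is.finite(lw_base) & lw_base >= lw_floor
  n_dyn <- dim(lw_maps)[4]
  out <- array(NA_real_, dim(lw_maps))
  for (d in seq_len(n_dyn)) {
    sl <- array(lw_maps[, , , d, drop = FALSE], dim(lw_base))
    sl <- 100 * (sl - lw_base) / lw_base
    sl[!ok] <- NA_real_
    out[, , , d] <- sl
  }
  out
}

#' AUC map of the linewidth change
#'
#' Mean of \eqn{\Delta LW(t)} over the post-infusion window, per voxel --
#' algebraically identical to normalising the window-averaged linewidth
#' by the baseline. `"full_post_start"` covers every dynamic after
#' infusion start; `"infusion_block_only"` covers the infusion itself,
#' whose length in dynamics is derived from dose and infusion rate
#' (35 g at 6.25 g/min by default, rounded up to whole dynamics).
#'
#' @param delta_lw_maps 4D percent-change array from [delta_lw()].
#' @param infusion_start Number of baseline dynamics.
#' @param window `"full_post_start"` or `"infusion_block_only"`.
#' @param dynamic_duration_s Duration of one dynamic (s).
#' @param dose_g,rate_g_min Infused dose and rate defining the infusion
#'   block duration.
#' @return 3D AUC map (%).
#' @export
auc_map <- function(delta_lw_maps, infusion_start,
                    window = c("full_post_start", "infusion_block_only"),
                    dynamic_duration_s = 38.4,
                    dose_g = 35, rate_g_min = 6.25) {
  window <- match.arg(window)
  n_dyn <- dim(delta_lw_maps)[4]
  first <- infusion_start + 1L
  last <- if (window == "full_post_start") n_dyn else {
    block <- ceiling(dose_g / rate_g_min * 60 / dynamic_duration_s)
    min(infusion_start + block, n_dyn)
  }
  if (first > last) stop("empty AUC window")
  sel <- delta_lw_maps[, , , first:last, drop = FALSE]
  apply(sel, 1:3, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
}

#' ROI linewidth-change time curve
#'
#' Mean \eqn{\Delta LW} over a region of interest per dynamic, with a
#' centred moving-average smoothed version (edge replication).
#'
#' @param delta_lw_maps 4D percent-change array.
#' @param roi_mask 3D logical ROI.
#' @param smoothing_window Moving-average length (odd; default 3).
#' @param dynamic_duration_s Seconds per dynamic (for the time axis).
#' @return Data frame with `dynamic`, `time_s`, `raw`, `smoothed`.
#' @export
roi_timecurve <- function(delta_lw_maps, roi_mask, smoothing_window = 3,
                          dynamic_duration_s = 38.4) {
  roi_mask <- array(as.logical(roi_mask), dim(delta_lw_maps)[1:3])
  if (!any(roi_mask)) stop("empty ROI")
  n_dyn <- dim(delta_lw_maps)[4]
  raw <- vapply(seq_len(n_dyn), function(d) {
    v <- delta_lw_maps[, , , d][roi_mask]
    mean(v[is.finite(v)])
  }, numeric(1))
  k <- smoothing_window %/% 2
  padded <- c(rep(raw[1], k), raw, rep(raw[n_dyn], k))
  smoothed <- vapply(seq_len(n_dyn), function(d) mean(padded[d:(d + 2 * k)]),
                     numeric(1))
  data.frame(dynamic = seq_len(n_dyn),
             time_s = (seq_len(n_dyn) - 0.5) * dynamic_duration_s,
             raw = raw, smoothed = smoothed)
}

#' Run the full DS-DGE pipeline
#'
#' Normalisation, per-dynamic linewidth maps, baseline with outlier
#' rejection, \eqn{\Delta LW(t)} maps and both AUC maps.
#'
#' @param series A [dynamic_series()] (raw or normalised).
#' @param lw_floor Baseline linewidth floor (Hz) for [delta_lw()].
#' @param fit_window_ppm Fit window half-width.
#' @param dose_g,rate_g_min Infusion dose/rate (see [auc_map()]).
#' @return Object of class `"dge_result"`: `lw_maps`, `lw_base`,
#'   `rejected_baseline_count`, `delta_lw_maps`, `auc_full`,
#'   `auc_infusion_block`, `mask`, `series` metadata.
#' @export
dge_pipeline <- function(series, lw_floor = 5, fit_window_ppm = 5,
                         dose_g = 35, rate_g_min = 6.25) {
  series <- normalize_dynamic(series)
  lw <- compute_lw_maps(series, fit_window_ppm)
  bl <- baseline_lw(lw, series$infusion_start_dynamic)
  dl <- delta_lw(lw, bl$lw_base, lw_floor)
  structure(
    list(lw_maps = lw, lw_base = bl$lw_base,
         rejected_baseline_count = bl$rejected,
         delta_lw_maps = dl,
         auc_full = auc_map(dl, series$infusion_start_dynamic,
                            "full_post_start", series$dynamic_duration_s,
                            dose_g, rate_g_min),
         auc_infusion_block = auc_map(dl, series$infusion_start_dynamic,
                                      "infusion_block_only",
                                      series$dynamic_duration_s,
                                      dose_g, rate_g_min),
         mask = series$mask,
         infusion_start_dynamic = series$infusion_start_dynamic,
         dynamic_duration_s = series$dynamic_duration_s),
    class = "dge_result")
}

#' @export
print.dge_result <- function(x, ...) {
  cat(sprintf("<dge_result> %s voxels, %d dynamics, infusion after %d\n",
              paste(dim(x$lw_base), collapse = "x"), dim(x$lw_maps)[4],
              x$infusion_start_dynamic))
  v <- x$auc_full[x$mask & is.finite(x$auc_full)]
  if (length(v))
    cat(sprintf("  AUC (full): median %.2f%%, IQR [%.2f, %.2f]\n",
                stats::median(v), stats::quantile(v, 0.25), stats::quantile(v, 0.75)))
  invisible(x)
}

#' @export
plot.dge_result <- function(x, z = NULL, ...) {
  if (is.null(z)) z <- ceiling(dim(x$auc_full)[3] / 2)
  graphics::image(x$auc_full[, , z], main = sprintf("AUC %% (slice %d)", z),
                  useRaster = TRUE, ...)
  invisible(x)
}
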