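## Digital head phantom: deterministic geometric label map (WM core, GM
## rim, CSF ventricles, spherical tumor, cylindrical vessel), exponential
## glucose uptake curves anchored to the tissue table's glycemic states,
## simulator-backed dynamic Z-spectral series and per-voxel Rician noise.

#' Phantom specification
#'
#' @param grid Integer vector of 3 voxel dimensions (>= 4096 voxels total).
#' @param n_dynamics Number of dynamics (Z-spectra) to generate.
#' @param infusion_start_dynamic Baseline dynamics before infusion.
#' @param onset_dynamic First dynamic at which uptake begins (>= infusion
#'   start).
#' @param tau_dynamics Exponential rise time constant of the uptake, in
#'   dynamics.
#' @param uptake_scale Fraction of the normo-to-hyperglycemia
#'   concentration step reached at plateau (per region, recycled).
#' @param tumor_radius_frac Tumor sphere radius as a fraction of the
#'   smallest grid half-dimension (0 removes the tumor).
#' @param vessel_radius_frac Vessel cylinder radius, same units.
#' @param noise_sigma_fraction Rician noise level as a fraction of S0.
#' @param s0 Unsaturated signal level in arbitrary units.
#' @param partial_volume Blend spectra linearly (50/50) at region
#'   boundaries to emulate partial-volume mixing.
#' @param seed Integer seed for the noise draws.
#' @param regions Named character vector mapping region labels to tissue
#'   names of [tissue_table()].
#' @return Object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid = c(32, 32, 12),
                         n_dynamics = 40,
                         infusion_start_dynamic = 8,
                         onset_dynamic = 9,
                         tau_dynamics = 4,
                         uptake_scale = 1,
                         tumor_radius_frac = 0.22,
                         vessel_radius_frac = 0.06,
                         noise_sigma_fraction = 0.02,
                         s0 = 1000,
                         partial_volume = FALSE,
                         seed = 1,
                         regions = c(WM = "WM", GM = "GM", CSF = "CSF",
                                     TUMOR = "TUMOR", vessel = "blood")) {
  grid <- as.integer(grid)
  if (length(grid) != 3 || prod(grid) < 4096)
    stop("grid must be 3 dimensions with at least 16^3 voxels in total")
  if (onset_dynamic < infusion_start_dynamic)
    stop("onset_dynamic must be >= infusion_start_dynamic")
  if (tau_dynamics <= 0) stop("tau_dynamics must be positive")
  if (tumor_radius_frac < 0 || tumor_radius_frac > 0.5)
    stop("tumor_radius_frac must be in [0, 0.5] (tumor must fit the grid)")
  if (any(uptake_scale < 0)) stop("uptake_scale must be >= 0")
  structure(
    list(grid = grid, n_dynamics = as.integer(n_dynamics),
         infusion_start_dynamic = as.integer(infusion_start_dynamic),
         onset_dynamic = onset_dynamic, tau_dynamics = tau_dynamics,
         uptake_scale = uptake_scale,
         tumor_radius_frac = tumor_radius_frac,
         vessel_radius_frac = vessel_radius_frac,
         noise_sigma_fraction = noise_sigma_fraction, s0 = s0,
         partial_volume = partial_volume,
         seed = as.integer(seed), regions = regions),
    class = "phantom_spec")
}

#' Region label codes of the phantom
#' @return Named integer vector.
#' @export
phantom_labels <- function() {
  c(background = 0L, WM = 1L, GM = 2L, CSF = 3L, TUMOR = 4L, vessel = 5L)
}

#' Build the phantom label map
#'
#' Deterministic concentric geometry: a head ellipsoid whose rim is GM
#' and core is WM, two ellipsoidal CSF ventricles, a spherical tumor in
#' one hemisphere and a vertical cylindrical vessel in the other. Later
#' structures override earlier ones.
#'
#' @param spec A [phantom_spec()].
#' @return 3D integer array of [phantom_labels()] codes, with attribute
#'   `expected_counts` (analytic voxel counts of the ideal shapes).
#' @export
build_label_map <- function(spec) {
  g <- spec$grid
  cx <- (g[1] + 1) / 2; cy <- (g[2] + 1) / 2; cz <- (g[3] + 1) / 2
  x <- (seq_len(g[1]) - cx); y <- (seq_len(g[2]) - cy); z <- (seq_len(g[3]) - cz)
  X <- array(rep(x, times = g[2] * g[3]), g)
  Y <- array(rep(rep(y, each = g[1]), times = g[3]), g)
  Z <- array(rep(z, each = g[1] * g[2]), g)
  ax <- 0.45 * g[1]; ay <- 0.45 * g[2]; az <- 0.45 * g[3]
  head <- (X / ax)^2 + (Y / ay)^2 + (Z / az)^2 <= 1
  core <- (X / (0.62 * ax))^2 + (Y / (0.62 * ay))^2 + (Z / (0.62 * az))^2 <= 1
  lab <- array(0L, g)
  lab[head] <- phantom_labels()[["GM"]]
  lab[core] <- phantom_labels()[["WM"]]
  ## ventricles: two small ellipsoids either side of the midline
  va <- 0.10 * g[1]; vb <- 0.18 * g[2]; vc <- 0.30 * g[3]
  for (sgn in c(-1, 1)) {
    vent <- ((X - sgn * 0.14 * g[1]) / va)^2 + (Y / vb)^2 + (Z / vc)^2 <= 1
    lab[vent] <- phantom_labels()[["CSF"]]
  }
  rmin <- min(g) / 2
  rt <- spec$tumor_radius_frac * rmin
  tumor_n <- 0
  if (rt > 0) {
    tum <- (X - 0.22 * g[1])^2 + (Y - 0.18 * g[2])^2 + Z^2 <= rt^2
    lab[tum] <- phantom_labels()[["TUMOR"]]
    tumor_n <- 4 / 3 * pi * rt^3
  }
  rv <- spec$vessel_radius_frac * rmin
  if (rv > 0) {
    ves <- (X + 0.25 * g[1])^2 + (Y + 0.2 * g[2])^2 <= rv^2
    lab[ves] <- phantom_labels()[["vessel"]]
  }
  attr(lab, "expected_counts") <- c(
    head = 4 / 3 * pi * ax * ay * az,
    core = 4 / 3 * pi * (0.62)^3 * ax * ay * az,
    ventricles = 2 * 4 / 3 * pi * va * vb * vc,
    tumor = tumor_n,
    vessel = pi * rv^2 * g[3])
  lab
}

#' Glucose uptake curve
#'
#' Concentration per dynamic: constant `baseline_mM` before
#' `onset_dynamic`, then an exponential approach
#' \eqn{C(t) = baseline + increment\,(1 - e^{-(t - onset)/\tau})}.
#'
#' @param baseline_mM Baseline concentration (mM).
#' @param increment_mM Plateau increment above baseline (mM, >= 0).
#' @param onset_dynamic Dynamic index at which uptake starts.
#' @param tau_dynamics Rise time constant (dynamics, > 0).
#' @param n_dynamics Curve length.
#' @return Numeric vector of length `n_dynamics`.
#' @export
uptake_curve <- function(baseline_mM, increment_mM, onset_dynamic,
                         tau_dynamics, n_dynamics) {
  if (tau_dynamics <= 0) stop("tau_dynamics must be positive")
  if (increment_mM < 0) stop("increment_mM must be >= 0")
  t <- seq_len(n_dynamics)
  ifelse(t < onset_dynamic, baseline_mM,
         baseline_mM + increment_mM * (1 - exp(-(t - onset_dynamic) / tau_dynamics)))
}

## fractional uptake progress (0 before onset, -> 1 at plateau)
uptake_fraction <- function(spec) {
  uptake_curve(0, 1, spec$onset_dynamic, spec$tau_dynamics, spec$n_dynamics)
}

#' Generate a dynamic Z-spectral phantom series
#'
#' For every region and dynamic, interpolates each compartment's glucose
#' concentration along its normo-to-hyperglycemic trajectory according to
#' the uptake curve, simulates the tissue Z-spectrum via the
#' Bloch-McConnell model, resamples it onto the acquisition offset
#' schedule, broadcasts it over the region's voxels, scales by S0 and
#' adds per-voxel Rician noise (seeded).
#'
#' @param spec A [phantom_spec()].
#' @param train A [pulse_train()].
#' @param protocol A [sim_protocol()]; its offsets must span the
#'   acquisition schedule (+-10 ppm).
#' @param schedule Acquisition offset schedule (default [dge_schedule()]).
#' @param table Tissue table (see [tissue_table()]).
#' @return List of class `"dsdge_phantom"`: `series` (a raw
#'   [dynamic_series()]), `label_map`, and `truth` -- a data frame per
#'   region and dynamic with the uptake progress and the noiseless fitted
#'   linewidth (Hz).
#' @export
generate_phantom_series <- function(spec, train = pulse_train(),
                                    protocol = sim_protocol(),
                                    schedule = dge_schedule(),
                                    table = tissue_table()) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- build_label_map(spec)
  labs <- phantom_labels()
  present <- names(spec$regions)[labs[names(spec$regions)] %in% unique(as.vector(lab))]
  u <- uptake_fraction(spec)
  scl <- rep(spec$uptake_scale, length.out = length(present))
  names(scl) <- present

  comp_cache <- new.env(parent = emptyenv())
  sim_comp_at <- function(comp_name, conc) {
    key <- sprintf("%s|%.6f", comp_name, conc)
    if (!is.null(comp_cache[[key]])) return(comp_cache[[key]])
    comp <- table$compartments[[comp_name]]
    comp$glucose_mM <- list(normoglycemia = conc)
    zs <- tryCatch(
      compartment_zspectrum(comp, "normoglycemia", train, protocol,
                            table$hydroxyl),
      error = function(e) stop(sprintf("compartment %s at %.3f mM: %s",
                                       comp_name, conc, conditionMessage(e)),
                               call. = FALSE))
    comp_cache[[key]] <- zs
    zs
  }
  conc_at <- function(comp_name, frac) {
    gl <- table$compartments[[comp_name]]$glucose_mM
    gl$normoglycemia + frac * (gl$hyperglycemia - gl$normoglycemia)
  }
  region_spectrum <- function(region, d) {
    tis_name <- spec$regions[[region]]
    tis <- table$tissues[[tis_name]]
    frac <- u[d] * scl[[region]]
    spectra <- list()
    if (tis$blood_fraction > 0) {
      spectra$arterial <- sim_comp_at("arterial", conc_at("arterial", frac))
      spectra$venous <- sim_comp_at("venous", conc_at("venous", frac))
    }
    if (tis$EES_fraction > 0)
      spectra$EES <- sim_comp_at(tis$EES, conc_at(tis$EES, frac))
    if (tis$cell_fraction > 0)
      spectra$cell <- sim_comp_at(tis$cell, conc_at(tis$cell, frac))
    mixed <- tryCatch(mix_tissue_zspectrum(tis, spectra),
                      error = function(e) stop(sprintf("region %s dynamic %d: %s",
                                                       region, d,
                                                       conditionMessage(e)),
                                               call. = FALSE))
    res <- resample_offsets(mixed, sort(unique(schedule)))
    ## acquisition order (zspectrum stores offsets sorted)
    list(spectrum = res,
         scheduled = res$intensities[match(schedule, res$offsets_ppm)])
  }

  n_off <- length(schedule)
  g <- spec$grid
  raw <- array(0, c(g, n_off * spec$n_dynamics))
  truth <- NULL
  reg_z <- vector("list", length(present)); names(reg_z) <- present
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  for (d in seq_len(spec$n_dynamics)) {
    for (region in present) {
      reg_z[[region]] <- region_spectrum(region, d)
      rs <- reg_z[[region]]$spectrum
      true_fit <- fit_lorentzian(
        zspectrum(rs$offsets_ppm[abs(rs$offsets_ppm) <= 5],
                  rs$intensities[abs(rs$offsets_ppm) <= 5]),
        larmor_mhz = protocol$larmor_mhz)
      truth <- rbind(truth, data.frame(
        region = region, dynamic = d, uptake = u[d] * scl[[region]],
        lw_hz = unname(true_fit$coefficients[["fwhm_hz"]])))
    }
    idx0 <- (d - 1L) * n_off
    vol <- array(0, c(g, n_off))
    for (region in present) {
      sel <- lab == labs[[region]]
      zv <- reg_z[[region]]$scheduled
      for (j in seq_len(n_off)) {
        sl <- vol[, , , j]
        sl[sel] <- zv[j]
        vol[, , , j] <- sl
      }
    }
    if (spec$partial_volume) vol <- blend_boundaries(vol, lab)
    vol <- vol * spec$s0
    if (spec$noise_sigma_fraction > 0) {
      sg <- spec$noise_sigma_fraction * spec$s0
      n1 <- array(stats::rnorm(length(vol), 0, sg), dim(vol))
      n2 <- array(stats::rnorm(length(vol), 0, sg), dim(vol))
      vol <- sqrt((vol + n1)^2 + n2^2)
    }
    raw[, , , idx0 + seq_len(n_off)] <- vol
  }
  series <- dynamic_series(raw, offset_schedule = schedule,
                           dynamic_duration_s = n_off * protocol$tr_s,
                           infusion_start_dynamic = spec$infusion_start_dynamic,
                           mask = array(lab %in% labs[present], dim(lab)),
                           larmor_mhz = protocol$larmor_mhz)
  structure(list(series = series, label_map = lab, truth = truth, spec = spec),
            class = "dsdge_phantom")
}

## 50/50 blend of face-neighbour voxels that straddle a region boundary
blend_boundaries <- function(vol, lab) {
  g <- dim(lab)
  out <- vol
  shift <- function(a, dx, dy, dz) {
    b <- array(NA, dim(a))
    xs <- seq_len(g[1]); ys <- seq_len(g[2]); zs <- seq_len(g[3])
    b[pmax(pmin(xs + dx, g[1]), 1), pmax(pmin(ys + dy, g[2]), 1),
      pmax(pmin(zs + dz, g[3]), 1)] <- a
    b
  }
  nb <- shift(lab, 1, 0, 0)
  boundary <- !is.na(nb) & nb != lab & lab > 0 & nb > 0
  if (any(boundary)) {
    for (j in seq_len(dim(vol)[4])) {
      sl <- vol[, , , j]
      nsl <- shift(sl, 1, 0, 0)
      sl[boundary] <- 0.5 * sl[boundary] + 0.5 * nsl[boundary]
      out[, , , j] <- sl
    }
  }
  out
}

#' @export
print.dsdge_phantom <- function(x, ...) {
  cat(sprintf("<dsdge_phantom> %s grid, %d dynamics, regions: %s\n",
              paste(x$spec$grid, collapse = "x"), x$spec$n_dynamics,
              paste(unique(x$truth$region), collapse = ", ")))
  invisible(x)
}

#' Write a phantom to disk (NIfTI series + sidecar + ground truth CSV)
#'
#' @param phantom Result of [generate_phantom_series()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dynamic_series(phantom$series, file.path(dir, "phantom"))
  write_map(array(as.numeric(phantom$label_map), dim(phantom$label_map)),
            file.path(dir, "phantom_labels"))
  utils::write.csv(phantom$truth, file.path(dir, "phantom_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
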