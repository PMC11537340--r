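## Compartmental glucose tissue model: glucose hydroxyl pool
## construction from concentration, per-compartment Z-spectra, and
## signal-level mixing of compartments into tissue Z-spectra with
## water-density weights.

#' Load the tissue and compartment parameter table
#'
#' Reads the versioned JSON resource shipped with the package: relaxation
#' times, fractional volumes, D-glucose concentrations per glycemic state
#' and water contents for blood (arterial/venous), gray matter, white
#' matter, malignant tumor and CSF compartments, plus the hydroxyl pool
#' constants. User overrides merge by key over the shipped values.
#'
#' @param path Optional path to an alternative JSON resource.
#' @param overrides Optional nested list merged (by name, recursively)
#'   over the loaded table.
#' @return Nested list with elements `hydroxyl`, `compartments`, `tissues`.
#' @export
tissue_table <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tissue_params.json", package = "dsdge")
  }
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(overrides)) tab <- merge_lists(tab, overrides)
  tab
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Glucose hydroxyl proton pools for a given concentration
#'
#' Builds the four hydroxyl pools (0.66, 1.28, 2.08 and 2.88 ppm) for a
#' D-glucose concentration. Proton fractions follow the standard
#' D-glucose assignment -- 1 proton at 0.66 ppm (OH-6), 3 at 1.28 ppm
#' (OH-2,3,4), and the anomeric OH-1 split 0.36/0.64 between 2.08 and
#' 2.88 ppm (alpha/beta equilibrium) -- relative to 111,000 mM water
#' protons. Exchange rates are 2900/6500/5200/14300 Hz at normal pH and
#' 1500/3100/2500/6000 Hz in acidic tumor EES.
#'
#' @param concentration_mM D-glucose concentration (mM, >= 0).
#' @param ph_regime `"normal"` (pH 7.2) or `"tumor_acidic"` (pH 6.8).
#' @param hydroxyl Hydroxyl constants sublist, as in
#'   `tissue_table()$hydroxyl`; exposed so shifts, multiplicities, rates
#'   and relaxation times can be overridden.
#' @return Data frame of four pools for use in [pool_system()].
#' @examples
#' glucose_pools(5.55)         # 1.28 ppm pool fraction = 1.5e-4
#' @export
glucose_pools <- function(concentration_mM,
                          ph_regime = c("normal", "tumor_acidic"),
                          hydroxyl = tissue_table()$hydroxyl) {
  ph_regime <- match.arg(ph_regime)
  if (!is.finite(concentration_mM) || concentration_mM < 0)
    stop("concentration_mM must be >= 0")
  k <- hydroxyl$exchange_rates_hz[[ph_regime]]
  frac <- hydroxyl$protons * concentration_mM / WATER_PROTON_MM
  do.call(rbind, lapply(seq_along(hydroxyl$shifts_ppm), function(i) {
    pool(hydroxyl$labels[i], hydroxyl$shifts_ppm[i],
         hydroxyl$T1_s, hydroxyl$T2_s, k_hz = k[i], fraction = frac[i])
  }))
}

#' Simulate the Z-spectrum of one tissue compartment
#'
#' Builds the pool system for a water environment (compartment): the
#' water pool uses the compartment's relaxation times, the hydroxyl pools
#' are derived from its glucose concentration at the requested glycemic
#' state and its pH regime; then runs the Bloch-McConnell simulation.
#'
#' @param comp Compartment parameter list (one entry of
#'   `tissue_table()$compartments`, or a list with `T1_s`, `T2_s`,
#'   `glucose_mM`, `pH_regime`).
#' @param state `"normoglycemia"` or `"hyperglycemia"`.
#' @param train A [pulse_train()].
#' @param protocol A [sim_protocol()].
#' @param hydroxyl Hydroxyl constants (see [glucose_pools()]).
#' @return A [zspectrum] object.
#' @export
compartment_zspectrum <- function(comp,
                                  state = c("normoglycemia", "hyperglycemia"),
                                  train = pulse_train(),
                                  protocol = sim_protocol(),
                                  hydroxyl = tissue_table()$hydroxyl) {
  state <- match.arg(state)
  for (fld in c("T1_s", "T2_s", "glucose_mM")) {
    if (is.null(comp[[fld]])) stop(sprintf("compartment is missing field '%s'", fld))
  }
  conc <- comp$glucose_mM[[state]]
  if (is.null(conc)) stop(sprintf("compartment has no glucose_mM entry for '%s'", state))
  regime <- if (is.null(comp$pH_regime)) "normal" else comp$pH_regime
  pools <- pool_system(
    pool("water", 0, comp$T1_s, comp$T2_s),
    glucose_pools(conc, regime, hydroxyl))
  zs <- simulate_zspectrum(pools, train, protocol)
  zs$metadata$glycemic_state <- state
  zs$metadata$glucose_mM <- conc
  zs
}

#' Mix compartment Z-spectra into a tissue Z-spectrum
#'
#' Signal-level mixing of normalised compartment spectra with volume
#' fractions and water-density corrections:
#' \deqn{Z_{tis} = [f_b \rho_b (f_a Z_a + f_v Z_v) + f_e \rho_e Z_e +
#'   f_c \rho_c Z_c] / \rho_{tis}.}
#' All spectra must share an identical offset grid; no silent
#' interpolation is performed.
#'
#' @param tissue Tissue definition (one entry of `tissue_table()$tissues`):
#'   fractions `blood_fraction`, `EES_fraction`, `cell_fraction` (summing
#'   to 1), arterial/venous subfractions (summing to 1) and the four water
#'   densities.
#' @param spectra Named list of [zspectrum] objects: `arterial`, `venous`
#'   (needed when `blood_fraction > 0`), `EES`, `cell` (when their
#'   fractions are positive).
#' @return A [zspectrum] object for the mixed tissue.
#' @export
mix_tissue_zspectrum <- function(tissue, spectra) {
  fb <- tissue$blood_fraction; fe <- tissue$EES_fraction; fc <- tissue$cell_fraction
  if (abs(fb + fe + fc - 1) > 1e-9)
    stop("compartment fractions must sum to 1")
  fa <- tissue$arterial_subfraction; fv <- tissue$venous_subfraction
  if (fb > 0 && abs(fa + fv - 1) > 1e-9)
    stop("arterial + venous subfractions must sum to 1")
  need <- c(if (fb > 0) c("arterial", "venous"), if (fe > 0) "EES", if (fc > 0) "cell")
  miss <- setdiff(need, names(spectra))
  if (length(miss)) stop("missing compartment spectra: ", paste(miss, collapse = ", "))
  grid <- spectra[[need[1]]]$offsets_ppm
  for (nm in need) {
    if (length(spectra[[nm]]$offsets_ppm) != length(grid) ||
        any(abs(spectra[[nm]]$offsets_ppm - grid) > 1e-9))
      stop("offset grids differ between compartment spectra (no silent interpolation)")
  }
  num <- numeric(length(grid))
  if (fb > 0) {
    num <- num + fb * tissue$blood_water_density *
      (fa * spectra$arterial$intensities + fv * spectra$venous$intensities)
  }
  if (fe > 0) num <- num + fe * tissue$EES_water_density * spectra$EES$intensities
  if (fc > 0) num <- num + fc * tissue$cell_water_density * spectra$cell$intensities
  zspectrum(grid, num / tissue$tissue_water_density,
            metadata = list(mixture = TRUE,
                            fractions = c(blood = fb, EES = fe, cell = fc)))
}

#' Simulate a full tissue Z-spectrum
#'
#' Convenience wrapper: simulates every compartment the tissue needs at
#' the requested glycemic state and mixes them. A `cache` environment may
#' be supplied to share compartment simulations (e.g. arterial/venous
#' blood) across tissues.
#'
#' @param tissue_name One of `names(tissue_table()$tissues)` -- `"blood"`,
#'   `"arterial"`, `"venous"`, `"GM"`, `"WM"`, `"TUMOR"`, `"CSF"`.
#' @param state `"normoglycemia"` or `"hyperglycemia"`.
#' @param train,protocol Simulation configuration.
#' @param table Tissue table (see [tissue_table()]).
#' @param cache Optional environment used to memoise compartment spectra.
#' @return A [zspectrum] object.
#' @export
tissue_zspectrum <- function(tissue_name,
                             state = c("normoglycemia", "hyperglycemia"),
                             train = pulse_train(),
                             protocol = sim_protocol(),
                             table = tissue_table(),
                             cache = NULL) {
  state <- match.arg(state)
  tis <- table$tissues[[tissue_name]]
  if (is.null(tis)) stop("unknown tissue: ", tissue_name)
  sim_comp <- function(comp_name) {
    key <- paste(comp_name, state, sep = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    zs <- compartment_zspectrum(table$compartments[[comp_name]], state,
                                train, protocol, table$hydroxyl)
    if (!is.null(cache)) cache[[key]] <- zs
    zs
  }
  spectra <- list()
  if (tis$blood_fraction > 0) {
    spectra$arterial <- sim_comp("arterial")
    spectra$venous <- sim_comp("venous")
  }
  if (tis$EES_fraction > 0) spectra$EES <- sim_comp(tis$EES)
  if (tis$cell_fraction > 0) spectra$cell <- sim_comp(tis$cell)
  zs <- mix_tissue_zspectrum(tis, spectra)
  zs$metadata$tissue <- tissue_name
  zs$metadata$glycemic_state <- state
  zs
}
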