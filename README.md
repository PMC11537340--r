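# dsdge

Simulation and analysis of **DS-DGE MRI** — dynamic glucose enhanced
imaging read out through exchange broadening of the **direct water
saturation (DS)** line of the Z-spectrum.

D-glucose carries hydroxyl protons (0.66, 1.28, 2.08 and 2.88 ppm from
water) that exchange with water at kHz rates. Under low-B1, short
saturation — the WASSR-like regime in which the Z-spectrum's central dip
is nearly a pure Lorentzian — this exchange raises the apparent
transverse relaxation rate R2 of water and *broadens* the DS line. For a
single water pool under continuous-wave saturation the full width at
half maximum is

    LW = (1/π) √( (R1 R2² + ω1² R2) / R1 ),   ω1 = γ B1,

so relative broadening is largest where T2 is long (CSF, extravascular
extracellular space) and glucose delivery is high (tumor with disrupted
blood–brain barrier). Tracking the fitted linewidth LW(t) through a
glucose infusion gives ΔLW(t) = 100·(LW(t) − LWbase)/LWbase and its time
average AUC — a glucose-uptake contrast that needs no gadolinium and is
insensitive to B0 shifts between dynamics.

The package is aimed at CEST/DGE methods researchers: it simulates the
full experiment from printed tissue parameters and processes dynamic
Z-spectral series (simulated or acquired) into linewidth, ΔLW and AUC
maps.

## What is inside

* **Bloch–McConnell simulator** (`pool`, `pulse_train`, `sim_protocol`,
  `simulate_zspectrum`): water plus four glucose hydroxyl pools with
  detailed-balance exchange, propagated sample-by-sample through a train
  of shaped saturation pulses by matrix exponentials, cycled to the
  acquisition steady state (transverse spoiling at each readout).
* **Compartmental tissue model** (`tissue_table`, `glucose_pools`,
  `compartment_zspectrum`, `mix_tissue_zspectrum`): arterial/venous
  blood, EES and cell compartments for gray matter, white matter,
  malignant tumor and CSF, mixed at the signal level with volume
  fractions and water-density weights; per-state glucose concentrations;
  acidic-tumor exchange rates; Rician noise.
* **Lorentzian linewidth fitting** (`fit_lorentzian`, `analytic_lw`):
  deterministic bounded Levenberg–Marquardt fit of the DS line returning
  a classed model object with `coef`, `predict`, `plot`, `residuals`
  methods; FWHM in Hz and ppm.
* **DS-DGE pipeline** (`normalize_dynamic`, `compute_lw_maps`,
  `baseline_lw`, `delta_lw`, `auc_map`, `roi_timecurve`,
  `dge_pipeline`): per-voxel per-dynamic fits, ±2 SD baseline outlier
  rejection, ΔLW and AUC maps (full post-infusion window and infusion
  block), smoothed ROI time curves; NIfTI + JSON sidecar I/O.
* **Digital head phantom** (`phantom_spec`, `build_label_map`,
  `uptake_curve`, `generate_phantom_series`): seeded synthetic dynamic
  series with WM/GM/CSF/tumor/vessel regions and exponential glucose
  uptake, for end-to-end testing without patient data.
* A thin command-line wrapper in `inst/cli/dsdge`
  (`simulate`, `phantom`, `fit-dynamics`, `auc`, `roi-curve`,
  `reproduce-table`).

## Worked example

Simulate normoglycemic malignant tumor tissue (5% blood, 50% acidic
EES, 45% cell), resample onto the 28 experimental offsets and fit the
DS line:

```r
library(dsdge)

pulse_train()
#> <pulse_train> sinc_gauss, 10 x 50 ms, B1peak 0.50 uT, tsat 0.500 s
sim_protocol()
#> <sim_protocol> 41 offsets [-10.00, 10.00] ppm, 3.0 T (127.731 MHz), TR 1.20 s, cycled_steady_state

fit <- tissue_linewidth("TUMOR", "normoglycemia")
fit
#> <ds_lorentzian> FWHM 42.70 Hz (0.3343 ppm), center +0.000 ppm, depth 1.443, baseline 1.012
```

The fitted FWHM of 42.7 Hz is the baseline DS linewidth of the tumor
mixture. Repeating at hyperglycemia and applying ΔLW =
100·(LW_hgl − LW_ngl)/LW_ngl for all seven shipped tissue entries:

```r
simulation_table(reference = NULL)
#>     tissue lw_ngl_hz lw_hgl_hz dlw_pct
#> 1    blood     88.01     88.43  0.4752
#> 2 arterial     60.56     61.17  1.0060
#> 3   venous    101.67    101.97  0.2980
#> 4       GM     59.10     59.29  0.3170
#> 5       WM     54.94     55.11  0.3044
#> 6    TUMOR     42.70     44.59  4.4069
#> 7      CSF     35.59     35.78  0.5487
```

Short-T2 venous blood has the broadest line; the glucose-induced change
is an order of magnitude larger in tumor than in normal gray/white
matter, because the disrupted blood–brain barrier floods the long-T2
EES with glucose and the acidic tumor pH slows hydroxyl exchange into
the regime of maximal broadening per millimolar. With
`reference = <published values>` (the default) the same call appends the
published simulation values and pass/fail flags at the configured
tolerances.

End-to-end on synthetic image data:

```r
ph  <- generate_phantom_series(phantom_spec(seed = 1))
res <- dge_pipeline(ph$series)          # LW, ΔLW, AUC maps
curve <- roi_timecurve(res$delta_lw_maps,
                       ph$label_map == phantom_labels()[["TUMOR"]])
```

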