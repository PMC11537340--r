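---
title: "DS-DGE MRI: model, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DS-DGE MRI: model, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement this package models

Dynamic glucose enhanced (DGE) MRI follows a D-glucose infusion through
its effect on tissue water. The variant implemented here reads the
effect off the *direct water saturation* (DS) line of the Z-spectrum:
glucose hydroxyl protons (0.66, 1.28, 2.08, 2.88 ppm from water)
exchange with water protons at kHz rates, which adds an exchange term to
the apparent transverse relaxation rate of water and broadens the DS
line. Acquisition uses low-B1, short saturation (10 consecutive 50-ms
sinc-Gaussian pulses, B1peak 0.5 µT, 0.5 s total, TR 1.2 s), the regime
in which semisolid magnetization transfer, CEST and rNOE contributions
are minimal and the DS line is close to a single Lorentzian. One
Z-spectrum (32 offsets, ±10 ppm twice for normalisation plus 28 offsets
within ±5 ppm) is acquired per dynamic; 40 dynamics cover baseline,
infusion and uptake.

The processing chain is: per-voxel normalisation by the second ±10 ppm
acquisitions → single-Lorentzian fit per dynamic → linewidth maps LW(t)
in Hz → baseline LWbase as the mean of pre-infusion linewidths after
±2 SD outlier rejection → ΔLW(t) = 100·(LW(t) − LWbase)/LWbase → AUC
maps as the time-mean of ΔLW over the post-infusion window (and over the
infusion block alone) → 3-point moving-average ROI curves.

# Bloch–McConnell core

The simulator propagates the full coupled magnetization of water plus
four hydroxyl pools. Pool i contributes (Mx, My, Mz) with relaxation
R1 = 1/T1, R2 = 1/T2, off-resonance precession Δω_i = 2π·f0·(δ_i − δ_rf)
and saturation coupling ω1 = γB1 (B1 along x). Exchange obeys detailed
balance: pool→water at rate k, water→pool at rate f·k with f the proton
fraction. The affine system is embedded as a (3n+1)-dimensional linear
generator and integrated exactly over each piecewise-constant envelope
sample by `Matrix::expm` (the exchange rates — up to 14 300 Hz — make the
generator stiff; the Ward–Padé implementation is robust there, and the
test suite pins the propagation against an independent fine-step RK4
integration to below 1e-4).

**Pulse envelope.** Only peak amplitude (0.5 µT) and duration (50 ms)
of the sinc-Gaussian pulses are published. The shipped default is a
single-main-lobe sinc windowed by a Gaussian of σ = τ/4, peak-normalised
— the simplest shape consistent with "sinc-Gaussian" — discretised into
64 piecewise-constant samples (fitted linewidths change by well under 1%
on doubling the sampling). Lobe count and window width are exposed
(`sinc_lobes`, `gauss_sigma_frac`) because the true parameterization is
scanner-specific; multi-lobe variants were examined and broaden every
line through their larger excitation bandwidth without improving overall
agreement with the published simulated linewidths.

**Steady state.** The spectra are acquired *during* a dynamic steady
state: every TR holds saturation (0.5 s), an EPI readout, and recovery.
Plain cycling of {saturation + recovery} lets transverse magnetization
of long-T2 compartments (CSF, EES; T2 = 2.78 s) survive from cycle to
cycle and build nonphysical coherence — Z-spectra turn oscillatory with
deep spurious sidebands. The readout in the actual sequence is crushed,
so the default cycle spoils transverse magnetization at each readout
("spoiled steady-state cycling"); convergence is declared when the
readout water Mz changes by < 1e-6 between cycles (error after 200
cycles). A thermal single-shot mode exists for unit testing; it produces
qualitatively wrong linewidths for this protocol (saturation-time- rather
than relaxation-limited lines) and is not used in the reproduction
workflow.

**Signed magnetization.** Reported intensities are signed water Mz
normalised by the unsaturated reference. With the default envelope the
per-pulse flip angle is large (≈200° on resonance), so exactly on
resonance long-T2 spins can over-rotate and leave slightly negative Mz.
The experimental offset schedule never samples 0 ppm and the fit window
is |Δω| ≤ 5 ppm with the reference points excluded, so this never enters
a fit. A magnitude-detection variant (|Mz|) was evaluated and degraded
agreement with the published simulated linewidths throughout, so the
signed convention — evidently what the reference simulations used — is
kept.

# Tissue model

Compartments (arterial and venous blood; EES; cell) are simulated
separately — each as water with its own T1/T2 plus hydroxyl pools at the
compartment's glucose concentration — and mixed at the *signal* level:

Z_tis = [ f_b ρ_b (f_a Z_a + f_v Z_v) + f_e ρ_e Z_e + f_c ρ_c Z_c ] / ρ_tis,

with volume fractions f and water densities ρ per mL. Inter-compartment
water exchange is deliberately not modelled (the compartments are mixed
as signals, not as exchanging pools). Blood is an arterial/venous
mixture with f_a = 0.3, f_v = 0.7; tumor EES uses acidic-pH exchange
rates (1500/3100/2500/6000 Hz vs 2900/6500/5200/14300 Hz at normal pH).
The parameter table ships as a versioned JSON resource
(`inst/extdata/tissue_params.json`); user overrides merge by key. Two of
the printed cell volume fractions (GM 0.74, WM 0.76) are rounded such
that the stated constraint f_b + f_e + f_c = 1 fails by 0.002; the
shipped table uses f_c = 1 − f_b − f_e (0.742, 0.762), which also
reproduces the tabulated tissue water densities to four decimals.

**Hydroxyl proton multiplicities.** The per-resonance proton counts are
cited but not printed. The shipped assignment is the standard D-glucose
one: 1 proton at 0.66 ppm (OH-6), 3 at 1.28 ppm (OH-2,3,4), and OH-1
split 0.36/0.64 between 2.08 and 2.88 ppm by the α/β anomeric
equilibrium; proton fractions are protons × C(mM) / 111 000 mM water
protons. The assignment is configurable through the hydroxyl block of
the tissue table.

**Noise.** 2% Rician noise is applied after mixing and before
resampling/fitting, per intensity: √((S+n₁)² + n₂²), n ~ N(0, 0.02·S0),
seeded.

# Lorentzian fitting

The fit is deterministic bounded Levenberg–Marquardt
(`minpack.lm::nls.lm` with an analytic Jacobian) of
Z(Δω) = b − a·(w/2)²/((Δω−c)² + (w/2)²). Initialisation: a from the
spectrum minimum, c at the minimising offset, w from the half-depth
crossing distance, b from the |Δω| ≥ 4 ppm points; bounds
w ∈ [1, 1000] Hz, c ∈ [−1, 1] ppm, b ∈ [0.8, 1.1], a ∈ [0, 1.5]. Three
deterministic starts (w, 2w, w/2) are always evaluated and the
lowest-RSS solution kept — compound lineshapes (narrow EES dip on a
broad cell line) have near-degenerate local minima and single-start
fitting makes the fitted width an unstable function of the data. A fit
that fails all starts, or has fewer than 6 points, is returned with
`converged = FALSE` and masked downstream rather than raising. This
deterministic least-squares stage replaces the trained deep-learning
Lorentzian network used in the original processing: the target quantity
(single-Lorentzian FWHM) is identical, no trained weights are needed,
and results are exactly reproducible.

The closed-form CW linewidth `analytic_lw` implements the full
expression LW = (1/π)√((R1R2² + ω1²R2)/R1) (the approximation dropping
R1R2² is available by flag) and anchors the simulator: a single-pool
continuous-wave simulation fits to the closed form within 5% across the
shipped relaxation regimes.

# DS-DGE pipeline numerics

* Normalisation uses the *second* acquisition at +10 and at −10 ppm;
  voxels with S0 ≤ 0 are masked.
* Baseline outlier rejection is a single pass (mean ± 2 SD of the
  pre-infusion values, per voxel); the baseline SD is per voxel, not
  pooled. Degenerate voxels (all baseline fits missing) are masked.
  Note the rejection rule is not guaranteed to move the trimmed mean
  toward the median for arbitrary baselines; it does in the motivating
  regime (a consistent baseline plus an isolated motion-like outlier),
  which is what the property test covers.
* Voxels with LWbase < 5 Hz are masked before ΔLW to avoid division
  blow-up (the source protocol states no floor; 5 Hz is far below any
  tissue linewidth at this field and B1).
* The infusion-block AUC window is derived from dose and rate (35 g at
  6.25 g/min → 5.6 min → 9 dynamics of 38.4 s, rounded up).
* AUC is the mean of ΔLW over the window — algebraically identical to
  normalising the window-averaged LW by LWbase; missing (failed-fit)
  dynamics are excluded from means, not interpolated.
* Motion correction is an upstream concern: the series container records
  a `motion_corrected` provenance flag; no registration is implemented.

# The digital phantom

`generate_phantom_series` builds a deterministic geometric head (WM
core, GM rim, two CSF ventricles, spherical tumor, cylindrical vessel),
assigns each region a tissue entry, and drives every compartment's
glucose concentration along its normo→hyperglycemic trajectory with an
exponential uptake C(t) = C_ngl + (C_hgl − C_ngl)·u(t),
u(t) = s·(1 − e^{−(t−onset)/τ}) — baseline before onset, monotone
approach after. Defaults mirror the acquisition: 32-offset schedule with
±10 ppm duplicated, 40 dynamics, infusion after dynamic 8; the dynamic
duration is 38.4 s (32 × 1.2 s; the scanner's printed 38.2 s reflects
sequence overhead not modelled here). Noise is per-voxel Rician, seeded;
regions are internally homogeneous (one spectrum per region per dynamic)
with an optional 50/50 linear blend at region boundaries emulating
partial-volume mixing. The exponential uptake form is a stand-in — real
uptake curves are not parameterized in the source — so phantom tests
validate *pipeline recovery of known truth*, not physiological realism;
likewise homogeneous regions mean spatial fit quality, B0/B1
inhomogeneity, EPI distortion and motion are all outside what a passing
phantom test demonstrates about real data.

Problem sizes in the shipped tests are chosen for a desk-scale run:
16³–48³ voxel grids, 4–8 dynamics in pipeline tests, 500 noise
replicates for fit robustness, 20 seeds for the noisy-variant check.

# Reproduction status and known limitations

`scripts/acceptance.R` (and `simulation_table()`) rerun the published
simulation: seven baseline linewidths and seven ΔLW values. With the
shipped defaults the blood, arterial, venous, GM, WM and TUMOR baseline
linewidths land within the ±10% comparison tolerance, as do the blood,
venous, GM and WM linewidth changes. Three quantities do not, and are
reported as computed rather than adjusted:

* **CSF baseline linewidth.** The published 16 Hz implies an effective
  per-pulse rotation far below what any 50-ms single pulse with 0.5 µT
  peak can deliver; every envelope consistent with the other six tissues
  leaves the simulated CSF line 2× broader, dominated by coherent
  pulse-train effects (the sidebands the offset schedule is designed to
  dodge). The unprinted scanner envelope and the trained fit's response
  to non-Lorentzian CSF lines are the suspected sources; CSF ΔLW
  inherits the problem.
* **Arterial ΔLW** misses its ±20% band marginally (computed ≈1.0% vs
  published 1.3%) — sensitive to the hydroxyl multiplicity assignment,
  which is cited but not printed.
* **TUMOR ΔLW** is recovered directionally (an order of magnitude above
  GM/WM) but at ≈4.4% vs published 7.5%: the least-squares fit absorbs
  part of the narrow acidic-EES broadening into amplitude rather than
  width on the compound tissue lineshape, where the trained fit
  evidently apportions it to width.
* Under 2% Rician noise the least-squares width acquires a systematic
  bias on compound and long-T2 lineshapes (tumor high, CSF low) that
  exceeds the Monte-Carlo scatter over 20 seeds; the noiseless variant
  is therefore the reference output of the reproduction workflow.

Within-package invariants — propagation vs independent RK4, detailed
balance, closed-form CW linewidth, Lorentzian round-trips, the ΔLW/AUC
algebraic identity, normalisation scale invariance, known-truth phantom
recovery within 1% — are all enforced by the test suite.
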