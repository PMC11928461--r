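---
title: "Models and numerical methods in guvphase"
author: "guvphase authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in guvphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvphase)
```

guvphase quantifies in vitro membrane phase-coupling assays: protein
recruitment to giant unilamellar vesicles (GUVs), the lipid-order response of
the membrane, condensate formation on and off membranes, the infrared
signatures of the lipid phase transition, the mechanical stiffening it
causes, and the hydrodynamic size of protein–vesicle complexes. This
vignette records the models behind each stage, the parameters that matter,
and the numerical conventions, so that results are interpretable and
reproducible.

## Imaging stages

### Segmentation and recruitment

`segment_guv()` reproduces the standard confocal mask workflow: the membrane
channel is Gaussian-blurred with sigma 1.5 px to suppress detector noise,
then thresholded. The default threshold is Otsu's method on a 256-bin
histogram anchored to the intensity range, which makes the mask invariant to
adding a constant offset to every pixel; ties in the between-class variance
are broken toward the lower threshold so the choice is deterministic. A
`fixed` threshold is available when a comparison series must share one
cutoff. An image with no intensity variation, or a threshold that selects
nothing, raises a `guvphase_no_foreground` error rather than returning an
empty mask.

`quantify_recruitment()` integrates the protein channel over the mask and
normalises to the mask area; `intensity_per_area` is algebraically the mean
masked intensity, which is the quantity that scales linearly with the amount
of protein on the membrane (the synthetic renderer is used to verify exact
2-fold scaling between coat amplitudes of 100 and 200).

Pixel coordinates throughout the package are 1-based `(row, col)`, matching
R's indexing; areas are always converted to µm² through `pixel_size_um^2`.

### Relative lipid order

The solvatochromic membrane dye shifts its emission toward shorter
wavelengths as lipids become more ordered, so the ratio of a blue/green
(449–550 nm) window to a red (550–650 nm) window reports relative lipid
order φ. Two estimators are possible — the ratio of masked sums and the mean
of per-pixel ratios — and the literature rarely states which is used.
`compute_phi()` uses the **ratio of masked sums**: per-pixel division
amplifies noise in dim pixels, whereas the sum ratio is the
maximum-likelihood estimate under additive noise of constant variance. The
per-pixel ratio map is still exposed (out-of-mask pixels zeroed) for display
parity with published ratio images. φ is invariant to rescaling both windows
by a common factor, and with the default synthetic signal-to-noise (membrane
amplitude 200, noise sd 10) it recovers a configured φ of 1.4 within 5%.

`compute_phi_live()` is the live-cell variant: a scalar per-channel
background (the mean over a user-drawn background region) is subtracted from
both windows before the per-region ratio; negative pixels clip to zero. A
region whose background-subtracted red sum is non-positive is returned
flagged invalid rather than dropped, so region bookkeeping survives.

### Condensate detection and the phase diagram

`detect_condensates()` reimplements particle analysis as threshold +
connected components with **8-connectivity** (diagonally touching pixels
merge). The 4-connected labeller in EBImage does not match this convention,
so the package carries its own two-pass union-find labeller.

`classify_phase_state()` applies the condensed-state rule: condensed iff the
mean condensate area exceeds 0.4 µm² *and* the condensate count normalised
to a 90 µm² reference region exceeds 20. Both statistics are densities or
means, so the call is invariant to subdividing the field. The mean area of
an empty detection table is reported as 0, keeping the classifier total.

`fit_phase_boundary()` delegates the decision surface to a support-vector
machine (`e1071::svm`) with either a linear or an inhomogeneous
2nd-degree polynomial kernel (`coef0 = 1`, so linear and cross terms are
available — a homogeneous quadratic kernel cannot represent additive
boundaries). The cost parameter defaults to 1 and is recorded in the output
together with the training accuracy; which kernel fits a given dataset is a
modelling choice left to the user, as both appear in practice.

### Granulosity

The granulosity index G quantifies condensate texture: the
background-subtracted image is Fourier transformed, all components with
radial frequency below the cutoff (in cycles per image dimension) are
zeroed, and G = sd/mean of the inverse transform. A literal circular
high-pass would also remove the DC component, making the mean approximately
zero and the index ill-defined; the package therefore **retains DC**, the
only reading under which a constant image gives G = 0 and the index is
finite and scale-invariant. The cutoff is a required parameter and must be
held constant across any comparison series; it is not defaulted because its
appropriate value depends on the condensate length scale relative to the
field of view. The FFT route is verified against a direct DFT-matrix oracle
to 10⁻⁶ relative on 64×64 images.

## FRAP and binding kinetics

`normalize_trace()` maps a raw trace to
F(t) = (I(t) − I_bleach)/(I_pre − I_bleach), with I_pre the mean of the
pre-bleach frames and I_bleach the **first post-bleach frame** (no
back-extrapolation, matching common plugin behaviour). `fit_recovery()`
fits the single-exponential F(t) = M·(1 − e^(−t/τ)) on the post-bleach
frames with t re-zeroed at the bleach. A single exponential is used because
the assays report % recovery at fixed times (5 s, 15 s), which the fitted
curve summarises through `percent_recovery_at()`; diffusion-coupled FRAP
models are out of scope. Flat post-bleach traces at zero are returned as
M = 0 with a `degenerate` flag instead of failing, since "no recovery" is a
meaningful biological outcome.

`fit_dose_response()` fits the 4-parameter logistic in log₁₀(concentration).
The saturation call is a package definition (published statements like
"saturates at ~10 µM" are qualitative): *saturated* iff the fitted response
at the highest tested dose is within 5% of the plateau `top` **and** the
95% confidence half-width of `top` is below 20% of its value. The second
condition prevents declaring saturation when the plateau is extrapolated far
beyond the tested range, which is exactly the failure mode of collective
binding that keeps rising at the top dose.

## Infrared spectra

Preprocessing follows the instrument: AFM-IR spectra get a 3-point adjacent
average, a Savitzky–Golay smooth (order 2, 13 points), and max-normalisation;
FTIR spectra get SG(2, 9) and the same normalisation. Second derivatives use
SG(2, 13) for AFM-IR and SG(2, 11) for FTIR, divided by the squared grid
step. Order-2 SG filters are exact on quadratics, which the tests exploit.

`locate_co_peak()` defines the lipid carbonyl position as the deepest
second-derivative **minimum** in 1700–1760 cm⁻¹ (derivative minima, not
absorbance maxima, resolve overlapping bands), refined by 3-point parabolic
interpolation; on noise-free Lorentzians swept over 1710–1750 cm⁻¹ the
refined position is within half a grid step of the true centre. The band
width is estimated from the separation of the zero crossings flanking the
minimum. For a bare Lorentzian of FWHM w those crossings sit at
±(w/2)/√3, giving the analytic factor √3; the SG smoothing widens the
negative lobe, so the package calibrates the factor by pushing an analytic
Lorentzian of the reference 20 cm⁻¹ band width through the exact
mode-specific pipeline and storing FWHM/separation (memoized per instrument
mode and grid step). With that calibration the liquid-phase preset reads
20.0 cm⁻¹.

`amide_fractions()` integrates the amide-I band over fixed sub-band windows
(intermolecular β-sheet 1610–1630, β-sheet 1630–1645, random coil 1645–1652,
α-helix 1652–1662, turns 1662–1690 cm⁻¹ — standard FTIR assignments,
config-overridable) after subtracting a linear baseline anchored at the
1600/1700 cm⁻¹ endpoints, the simplest reproducible baseline. Fractions are
sub-band areas over the summed sub-band area, so they sum to 1 exactly;
window integrals interpolate linearly at fractional-grid edges. Because
neighbouring Gaussian bands leak into each other's windows, a true 3-point
difference in intermolecular β-sheet content reads out slightly compressed
(about 2.7 points with the default presets) — comfortably resolvable, and
consistent with treating differences below ~5 points as minor.

## Mechanics

A vesicle pushed into a tapered channel elongates in proportion to the
applied pressure drop in the 100–1000 Pa working range, so
`fit_stress_strain()` is ordinary least squares of strain on pressure. The
**relative elastic modulus** is defined as
E_rel = slope(reference)/slope(sample): the minimal definition under which a
stiffer membrane (less strain per Pa) has a larger modulus, the quantity is
dimensionless and unit-invariant, and reciprocal comparisons multiply to 1.
Naked GUVs are the unit reference. `forth_back_consistency()` exposes the
slope/intercept differences of the two push directions with standard errors
from the pressure-by-direction interaction model and a pooled fit; the
formal ANCOVA is a standard test left to the caller.

The generator's linear-elastic law is strain = P/(k_ref · E_rel) with
k_ref = 4000 Pa, chosen so a naked vesicle reaches 25% elongation at
1000 Pa — a realistic deformation for a fluid-phase GUV in this pressure
range. The stiffness presets (naked 1.0, coated 2.5, coated+ALG2 3.5,
coated+CALC 1.3) are invented magnitudes constrained only by the measured
fold-change bounds (coated > 2-fold, with ALG2 > 3-fold, with CALC back near
naked); they are labelled as such in every ground-truth record.

## Diffusional sizing

The forward model treats the sizing chip as 1-D diffusion across the channel
width with no-flux walls, starting from a top-hat sample stream occupying a
fraction s of the width. The solution is the cosine eigenfunction expansion

c(x, t) = s + Σₙ (2/nπ) sin(nπs) cos(nπx/W) exp(−D(nπ/W)²t),

truncated at 800 terms (the slowest observation time already damps term 800
by far more than machine precision; t = 0 returns the exact top-hat).
Residence times use the **plug-flow approximation**
t_i = L_i·W·H/Q — mean-velocity transport without Poiseuille dispersion.
This is a documented simplification: the fitted R_H is self-consistent with
the forward model, and relative comparisons across conditions are
unaffected, but absolute radii from real chip images would inherit the
approximation. Diffusion along the height is averaged out.

Defaults: width 300 µm, height 25 µm, sample stream fraction 0.25,
observation path lengths 1, 5.6, 21, 58.5 mm, flow 60 µL/h, T = 298.15 K,
η = 8.9·10⁻⁴ Pa·s — a typical four-position sizing device; the exact chip
dimensions are required configuration for real data. `fit_rh()` minimises
the summed squared profile mismatch over a 200-point log grid in
0.1–50 nm, each profile carrying a free linear amplitude (solved in closed
form, absorbing gain and concentration nuisances), then refines between the
best grid neighbours by golden-section search to 0.01 nm. The objective is
unimodal in R_H on noise-free input (asserted by grid scan), every profile
conserves mass to 10⁻³ relative, and the series solution matches an
independent Crank–Nicolson solver to 10⁻⁴ max-norm.

## The synthetic-data generator

Every generator takes a `synth_config` and is bit-identical under a fixed
seed. The noise model is additive Gaussian with standard deviation
`noise_sd`, clipped at zero — not Poisson: all downstream stages are
intensity-ratio or fit based and insensitive to the noise family at the
tested signal-to-noise ratios, and a single `noise_sd` knob keeps SNR
explicit. Defaults emulate Nyquist-sampled high-NA confocal imaging
(0.05 µm/px, 384×384 fields); GUV rings are hard annuli with a half-pixel
edge roll-off; condensate disks are rasterized **area-exactly** by
thresholding sorted pixel-centre distances, so detection tests can assert
exact area recovery; the gel-phase carbonyl preset is the liquid position
plus the 8 cm⁻¹ shift (the shift, not the absolute gel position, is the
observed quantity); dye images encode φ exactly per pixel when the
background is zero (the default).

What the generators do **not** emulate: optical point-spread functions,
camera gain/offset statistics, out-of-focus light, membrane fluctuations,
photobleaching during acquisition, lipid spectral libraries, or Taylor–Aris
dispersion. Passing recovery tests therefore demonstrate correctness of the
analysis algebra and numerics under controlled conditions, not robustness to
every instrumental artefact of real data.

## Problem sizes and runtime

The shipped test suite runs entirely on generated data: 384×384 imaging
fields, 198-point spectra, 200-frame FRAP traces, 100-point SVM grids,
20-replicate sizing-noise studies and 100-replicate EC50 recovery studies —
sizes chosen so the full suite completes in well under a minute on a single
core while still exercising every code path and tolerance stated above.

## Known limitations

- Strain extraction from raw deformation movies (vesicle tracking) is out of
  scope; the mechanics module consumes (pressure, strain) tables.
- The amide-I sub-band windows are a convention; fractions are only
  comparable within one window set.
- The sizing model's plug-flow and height-averaging assumptions bias
  absolute R_H from real images; recovery of the forward model's own output
  is exact by construction.
- `compute_phi()` reports a single φ per mask; per-vesicle statistics
  require per-vesicle masks (e.g. via `detect_condensates()` on the marker
  channel or user-supplied regions).
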