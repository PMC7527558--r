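---
title: "Methods: micro-CT lung biomarkers for the silicosis model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micro-CT lung biomarkers for the silicosis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Oropharyngeal instillation of crystalline silica (5 mg per mouse: 40 µL of a
0.125 mg/µL suspension) produces a persistent, non-resolving centrilobular
fibrosis in mice. Respiratory-gated in vivo micro-CT can follow that disease
in each animal over months through four scan-derived biomarkers computed
over a lung volume of interest (VOI): mean lung density (HU), aerated lung
volume, non-aerated lung volume, and their sum, the total lung volume (mL).
`silicoct` implements the full quantification chain — Hounsfield
calibration, retrospective respiratory gating, VOI volumetrics — together
with the downstream study statistics, and a synthetic-data module that
generates every input with known ground truth so the chain is testable end
to end without animal data.

# Hounsfield calibration

The scanner's reconstructed grayscale indices are mapped to Hounsfield
units by a two-point affine fit through a water/air phantom (an air-filled
1.5 mL tube inside a water-filled 50 mL tube). The "main grayscale index" of
each reference VOI is taken as its full-stack histogram mode (ties broken
toward the lower index, a documented convention; the term is not otherwise
defined by scanner software). Water maps to 0 HU and air to −1000 HU, so

$$\mathrm{HU}(g) = \frac{1000}{g_w - g_a}\,(g - g_w),$$

which for the protocol anchors $g_w = 133$, $g_a = 9$ gives a slope of
8.0645 HU per grayscale step and places the −223 HU classification
threshold at grayscale 105.35. Calibrated volumes keep HU as reals — no
integer re-quantization — so thresholding happens once, in HU space,
without double-rounding bias. One phantom calibrates the whole study
(per-protocol, not per-scan calibration).

# Retrospective gating

Projections are acquired in list mode: 9 projections per view, views at
0.9° steps over 220° (245 views, 2205 events), 55 ms exposure each, while
the animal breathes at 150 breaths/min (400 ms period). Each event is
assigned the respiratory phase of its exposure midpoint,
$\varphi = ((t - t_0) \bmod T)/T$, and sorted into four half-open bins
*centered* on the quarter phases: bin $k$ covers
$[(k-\tfrac12)/4, (k+\tfrac12)/4) \bmod 1$. Centering the bins on quarter
phases makes end-expiration ($\varphi = 0$, the volume minimum of the
waveform) a bin center; edge-aligned bins would leave it on a boundary and
create a tie between the two flanking bins. The end-expiration bin is the
one whose center is nearest phase 0 on the circle (equivalently, the bin
minimizing the mean of the volume waveform over its interval), ties broken
toward the lower index. The vendor's time-based sorting algorithm is
proprietary and undescribed, so the respiratory timebase is taken as known
(it is, for generated data); deriving the breathing signal from projection
data is out of scope.

# VOI volumetrics

The lung VOI is built from the generator's label masks (aerated lung plus
lesions, heart and main vessels excluded), mirroring manual delineation; a
slab-restricted variant mirrors the landmark rule (clavicle–sternum section
to a plane through the liver) for delineation-sensitivity checks. Over the
VOI of a calibrated end-expiration volume:

* **aerated volume** — voxels strictly below −223 HU;
* **non-aerated volume** — voxels at or above −223 HU (a voxel at exactly
  the threshold counts non-aerated; the tie rule is a documented choice);
* **total volume** — their sum, computed as that sum so the conservation
  identity is exact in floating point;
* **mean lung density** — the arithmetic mean HU over the whole VOI (both
  classes), since it is reported alongside, not within, the class volumes.

Volumes are voxel counts × (voxel size mm)³/1000 mL, with no
partial-volume weighting. Because aerated voxels are those *below* the
threshold, raising the threshold can only grow the aerated class and shrink
the non-aerated class, with a constant sum — the direction the monotonicity
tests assert.

# The synthetic-data module

The generator emulates the study's data structure, not its imaging physics
(no projections, reconstruction, scatter or beam hardening — volumes are
generated directly):

* **Calibration phantom** — nested air/water cylinders with Gaussian
  grayscale noise, rounded to integer indices and clipped at 0. Rounded
  Gaussian noise preserves the histogram modes at the anchors, which is all
  the calibration consumes.
* **Thorax** — an elliptical soft-tissue body, a lung ellipsoid whose
  analytic volume matches the requested lung volume, an optional heart
  sphere, and hyperdense lesions as non-overlapping spheres placed by
  seeded rejection sampling (spheres are the minimal shape with analytic
  volume; placement coordinates are normalized to the lung so lesions
  scale with it across breathing phases). Voxels belong to the compartment
  containing their center — no partial-volume mixing — so ground truth is
  exactly label count × voxel volume and the zero-noise recovery oracle is
  exact. Compartment densities (lung −500 HU, lesions +30 HU, soft tissue
  +40 HU) straddle −223 HU by construction; in-vivo density spreads are
  not published, so these are flagged as plausible synthetic values.
* **Breathing** — aerated lung volume follows
  $v(\varphi) = V_{ee}\,(1 + f_t \sin^2 \pi\varphi)$, smooth, periodic,
  with its unique minimum at end-expiration. The default tidal fraction
  0.4 follows from the ventilation protocol (10 mL/kg tidal volume, a
  ~25 g mouse, ~0.6 mL end-expiratory lung volume). Lesions do not inflate.
* **Cohort** — the published design: scans at weeks 0–5 weekly then
  biweekly to 15; endpoint cohorts 6/6, 6/10, 6/8, 6/8 (control/silica) at
  weeks 1, 5, 9, 15; monotone missingness by sacrifice only (survival was
  100%). The published baseline silica headcount (34) exceeds the cohort
  sum (32); `extra_animals` adds scanned-only animals rather than guessing
  the fate of the difference.

## Trajectories and endpoint links

Silica trajectories are parametric: non-aerated volume jumps to a week-1
peak (+0.18 mL) and relaxes with a 2-week constant to a stable plateau at
85% of the peak; aerated volume dips at week 1 (−0.08 mL, 2-week decay)
then overshoots baseline (+0.10 mL amplitude, 6-week rise); the total is
their sum and is strictly increasing from week 1 by construction (the dip
recovery outpaces the peak relaxation). Controls drift by 0.1–0.2% per
week (aging). Each animal scales its disease deviations by a severity
factor (SD 0.25), carries a small baseline intercept (SD 0.02 mL), and
every scan adds 0.01 mL measurement noise. These magnitudes are mouse-scale
choices made once; no published numeric curves exist to copy.

Endpoint readouts are linked to the *measured* imaging biomarker at the
sacrifice scan through a standardized linear-plus-noise model:
$y = \mu_y + \sigma_y\,(r\,z_x + \sqrt{1 - r^2}\,\varepsilon)$, where
$z_x$ standardizes the biomarker by its analytic pooled mean and SD across
silica endpoint animals (a mixture over the four cohorts). The sample
Pearson correlation therefore converges to the target $r$ as cohorts grow,
and the defaults are the reported coefficients: aerated↔IC 0.6612,
total↔η 0.4027, non-aerated↔Tiffeneau 0.7764 in magnitude,
non-aerated↔{BAL protein, serum SP-D, OH-proline}
{0.5557, 0.8445, 0.4187}. The Tiffeneau link slope is negative — the index
falls as non-aerated volume rises — while the reported coefficient is
printed unsigned; the package computes the signed $r$ and reports the
magnitude where the printed convention is matched. The raw
forced-oscillation and forced-expiration parameters (G, H, FEV~0.1~, FVC)
are emitted instead of the indices, so `derive_indices()` (η = G/H,
Tiffeneau = FEV~0.1~/FVC) carries the links downstream exactly as the real
analysis chain would. BAL differentials score 200 cells per animal
(binomial); the true silica neutrophil fraction decays from 45% at week 1
to 20% at week 15, controls sit at 1.5%.

What the generator does *not* emulate: reconstruction artifacts, cardiac
motion, delineation error, non-Gaussian biological tails, or cytokine
kinetics (analytes are generic linked columns). Passing recovery tests
therefore validates the computational chain, not the biology of real
scans.

# Statistics

Pearson correlations are computed on complete pairs of silica endpoint
animals pooled across cohorts (matching the published correlation
analysis), with two-sided p from the t transform on $n-2$ df and Sidak
adjustment $1 - (1-p)^m$; $m$ is always an explicit input, never inferred.
The longitudinal group×time interaction test is a *delegated* stage: a
random-intercept linear mixed model with Satterthwaite denominator df
(lme4/lmerTest), with optional Sidak-adjusted per-week contrasts via
emmeans. Its output is validated for sanity only — power above 0.9 at the
study cohort sizes under the default effect sizes, and a type-I rate within
0.05 ± 0.03 under the null — not for agreement with any proprietary
implementation; sphericity-correction internals are out of scope.

# Numerical choices and degenerate inputs

* Histogram-mode ties break toward the lower grayscale index; bin-center
  ties toward the lower bin.
* A voxel at exactly −223 HU is non-aerated.
* Equal or inverted calibration anchors, empty VOIs/event tables,
  misaligned grids, inverted slabs, duplicate (animal, week) keys, and
  unfittable designs raise typed errors rather than returning values.
* Lesion packing uses rejection sampling with per-axis center margins and
  up to 10 restarts; infeasible burdens fail with a packing error.
* All randomness flows from one root seed through named sub-streams
  (`stream_seed`), so identical seeds give bit-identical tables and
  volumes and adding draws to one stage does not perturb another.

# Problem sizes

The volumetric math is voxel-size-agnostic, so tests and the default
pipeline run desk-scale grids: 48³–96³ voxels at 0.2–0.4 mm (full-scale
50 µm generation is supported, not required). The default pipeline renders
one representative animal per group at weeks 0, 1, 5 and 15 with four
phase volumes each and a representative lesion burden (15%, 24 nodules);
cohort-level quantities come from the table-level simulator, which is the
object the recovery checks exercise at 200 replicates of the published
design and at pooled n = 2000.

# Known limitations

* Spherical lesions with center-assignment voxelization understate
  partial-volume effects of real centrilobular nodules (a boundary-blur
  option is deliberately absent to keep voxel-count oracles exact).
* The gating stage assumes the respiratory timebase is known; it does not
  extract a breathing signal from projections.
* Endpoint links are linear with Gaussian noise and mild clipping at
  physiological bounds; clipping attenuates extreme target correlations by
  under 0.02.
* The imaging arm and the cohort simulator share trajectory parameters but
  are separate pathways; only the imaging arm exercises NIfTI IO and VOI
  extraction, only the cohort pathway has endpoint readouts.
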