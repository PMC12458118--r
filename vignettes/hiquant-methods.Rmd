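---
title: "Quantifying neonatal hypoxic-ischemic injury: T2 relaxometry, region-split segmentation, and evoked-potential metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hiquant methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiquant)
```

## The problem

After a neonatal hypoxic-ischemic (H-I) insult, cytotoxic edema appears as
T2-hyperintense tissue on MRI. Within an edematous region two compartments
matter clinically and experimentally: the *ischemic core* (severely
injured, long T2) and the *penumbra* (injured but potentially salvageable,
intermediate T2). Longitudinally, part of the injured hemisphere is lost
outright. In parallel, cortical slice electrophysiology shows that the
surviving tissue at the lesion border becomes pathologically
hyperexcitable — a post-hypoxic potentiation of glutamatergic field
potentials — and expression of the AMPA-receptor subunit gene *Gria2*
falls in the injured cortex.

`hiquant` packages the quantitative machinery for such a study: voxelwise
T2 relaxometry, automatic core/penumbra segmentation, hemisphere-based
lesion volumetrics, evoked field-potential metrics, and delta-delta-Ct
expression analysis — plus a synthetic-data module that generates MRI
phantoms and fEPSP sweeps with known ground truth, so every stage is
testable without scanner or amplifier data.

## T2 relaxometry

Each voxel of a multi-echo spin-echo acquisition is modelled as a
mono-exponential decay

$$S(TE) = S_0 \, e^{-TE/T_2},$$

fit per voxel across the echo train. Two fitting routes are provided:

* **loglinear** — ordinary least squares of $\ln S$ on $TE$. Fast and
  closed-form, but biased when magnitude noise is non-negligible, and
  undefined for non-positive intensities.
* **nonlinear** (default) — least squares on the untransformed signal by
  variable projection: for a candidate decay rate $r = 1/T_2$ the optimal
  amplitude is $\hat S_0(r) = \sum S e_i / \sum e_i^2$ with
  $e_i = e^{-r\,TE_i}$, so the problem reduces to a one-dimensional
  minimization over $r$ (solved by `stats::optimize` to a tolerance of
  $10^{-10}$ on $r$, bracketed a factor of five either side of the
  loglinear initialization).

No noise-floor offset term is included: the model is a plain exponential.
Fit failures — non-positive decay-rate estimates, degenerate signals —
are recorded in the `valid` mask rather than raised as errors, so one bad
voxel cannot abort a map. On noiseless data the two methods agree exactly
and recover the generating parameters to numerical precision; the test
suite verifies the noisy-data behaviour against an exhaustive grid-search
least-squares oracle run on identical draws. An `omit_first_echo` switch
is provided because some multi-echo protocols discard the first echo
(stimulated-echo contamination); all echoes are used by default.

## Hierarchical region-split segmentation

The segmentation operates on the T2 map restricted to a lesion
(edema) region of interest — in a real study a manual outline, in testing
the phantom's ground-truth lesion. Restricting to a mask keeps
cerebrospinal fluid and skull-stripping errors out of the histogram. The
procedure is recursive:

1. Build the region's T2 histogram (default bin width 1 ms) and smooth it
   with a Gaussian kernel (default bandwidth 2 ms). These defaults put
   roughly twenty bins between the two physiological thresholds, enough
   to resolve them while suppressing sampling noise.
2. Find the region's modes: local maxima of the smoothed counts, filtered
   by topographic prominence (default: at least 5% of the tallest bin). A
   peak's prominence is its height above the higher of the two minima
   separating it from the nearest taller bars; a global maximum keeps its
   full height. Edge bins may be modes.
3. If at least two modes qualify, split the region at the *valley* — the
   global minimum of the smoothed counts strictly between the two most
   prominent modes (ties broken toward lower T2) — into the
   $T_2 \le \text{valley}$ and $T_2 > \text{valley}$ sub-regions, and
   recurse into both.
4. Stop when a region is unimodal, when a split would create a child
   smaller than `min_region_voxels` (default 30, small enough to follow
   genuine substructure but large enough for a meaningful histogram), or
   at `max_depth` (default 6).

Each terminal leaf is then classified by its own histogram mode: **core**
when the mode exceeds 56 ms, **penumbra** otherwise. Finally any voxel
whose own T2 is below 33 ms is relabeled **uninjured**, as a voxelwise
override. Both comparisons are strict (`> 56`, `< 33`), and the
boundary semantics are pinned by tests. Classification is applied to
terminal leaves only, after the recursion has finished; the thresholds are
exposed in `segmentation_params()` and on the command line.

Several choices here were genuinely open and are worth recording. The
valley detector needs a smoothing and prominence rule because raw counts
of small regions are too ragged for a literal minimum scan; smoothing plus
prominence filtering is the minimal robust choice, and every knob is a
parameter. The tie-break sending values equal to the valley into the
lower child makes the recursion deterministic. "Mode" is read literally
as the T2 at the smoothed-histogram peak of the region, not the region
mean or median. The whole recursion is order-independent and is tested
against a brute-force loop-based re-implementation of the same stated
rules.

## Volumetrics

Class volumes are exact voxel counts times the voxel volume. Lost tissue
is estimated by hemisphere subtraction: split the brain mask at a
sagittal midline column and take

$$V_\text{lost} = \max(0,\; V_\text{contralateral} - V_\text{ipsilateral}).$$

Read literally, "injured minus intact" would be negative when tissue is
lost; the sign here follows the biology (and the symmetric-difference
reading of the measurement), and clipping at zero prevents ipsilateral
edema swelling from reporting negative loss — swelling instead raises a
flag. Core and penumbra are excluded from the lost class by construction:
those voxels are still present in the mask, so they never enter the
difference. Hemisphere splitting assumes the volume is already aligned so
that one column index separates the hemispheres; cross-timepoint
registration is out of scope. `longitudinal_table()` emits the tidy
long-format table (subject, group, timepoint, class, volume) and a
group mean ± SD summary ready for external repeated-measures ANOVA; the
ANOVA itself is deliberately not reimplemented.

## Evoked field potentials

An extracellular cortical sweep contains, after the truncated stimulus
artifact: a presynaptic volley burst (VB), a monosynaptic field potential
FP1 at 4–6 ms latency, and a polysynaptic FP2 at 6–10 ms, all negative
deflections. Measurement conventions:

* baseline = mean voltage over the 5 ms before the stimulus;
* samples within 0.5 ms after each stimulus are blanked (artifact);
* amplitude = baseline minus the window minimum, clamped at zero
  (baseline-to-trough; a peak-to-peak option exists because the
  literature is split on the convention);
* latency = time of that minimum, relative to the stimulus;
* windows: VB [1, 4) ms, FP1 [4, 6] ms, FP2 (6, 10] ms. VB is measured
  as a presynaptic control but carries no downstream statistic.

Input-output curves collect FP1/FP2 amplitudes over the standard
recruitment protocol (0 to 650 µA in 50 µA steps, 14 levels) and are
summarized by the trapezoidal area under the curve — with only 14 points
and a plateauing shape, trapezoids are the defensible quadrature.
Paired-pulse facilitation uses two stimuli (default 50 µA, 75 ms apart)
and reports $100\,(A_2 - A_1)/A_1$ on FP1, the monosynaptic component
(switchable); an absent first response makes PPF undefined and is
reported as missing, not an error. The border-versus-contralateral
contrast (`hltp_contrast()`) reports mean AUC per side and their ratio —
the descriptive statistic that feeds the study-level ANOVA.

## The synthetic-data module

The phantom emulates the acquisition scale of a small-animal study:
0.12 × 0.12 mm in-plane voxels, 0.5 mm slices, ten echoes at
TE = 10…100 ms. Two ellipsoidal hemisphere halves form the brain; an
ellipsoidal core plus a surrounding shell of penumbra sit inside the
ipsilateral hemisphere. Per-voxel T2 is drawn from the owning class
(uninjured 30 ± 1.5 ms, penumbra 45 ± 2.5 ms, core 70 ± 3 ms — means
chosen to sit clearly on the correct sides of the 33/56 ms thresholds,
with the uninjured class below 33 ms by the staging convention),
truncated at 1 ms. Noise is Rician,
$\sqrt{(S+n_1)^2+n_2^2}$ with independent Gaussians — the standard model
for magnitude-reconstructed MRI; the default scale is 2% of $S_0$
(SNR 50), and recovery tests also run at SNR 20. Tissue loss is emulated
by deleting the posterior-most non-lesion ipsilateral voxels, row by row
(a wedge) — the simplest geometry that exercises the hemisphere
subtraction while keeping the lost volume disjoint from core and
penumbra, so the ground-truth bookkeeping (classes + lost + outside =
grid) stays exact.

Synthetic sweeps render each component as a negative raised-cosine (Hann)
pulse with compact support. Only amplitudes and latencies are measured
downstream, so the pulse shape is a free choice; compact support was
chosen over Gaussian-family shapes so that noiseless components cannot
overlap, which makes exact amplitude/latency recovery a provable property
rather than an approximation. Amplitudes follow the saturating
recruitment sigmoid $A(I) = A_{max}/(1+e^{-k(I-I_{1/2})})$ with defaults
$I_{1/2} = 200$ µA, $k = 0.015$ µA⁻¹, saturation amplitudes
VB 0.3 / FP1 1.2 / FP2 0.8 mV and noise 0.02 mV — free parameters chosen
as typical for cortical slice fEPSPs, since no absolute amplitudes or
sigmoid parameters are available to copy. The `potentiation_factor`
scales FP1/FP2 saturation amplitude to emulate post-hypoxic potentiation;
`cnqx` zeroes FP1/FP2 only and `ttx` zeroes everything after the
artifact, mirroring the pharmacological dissection used to identify the
components. The paired-pulse generator scales the second response by
`facilitation_factor` (default 1.3, a typical modest cortical PPF).

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: anatomy beyond ellipsoids, partial-volume
voxels, B0/B1 artifacts, multi-compartment T2 decay, inter-animal
geometric variability (cohort phantoms share geometry and differ only in
noise and imposed effects), stimulus-artifact ringing, and slow drifts or
line noise in the recordings.

## Numerical choices and degenerate inputs

* Histogram bins are left-closed with the last bin closed; values on a
  bin edge go right, ties in mode/valley scans go to lower T2.
* The Gaussian smoothing kernel is truncated at four bandwidths and
  renormalized at the histogram edges, so edge bins are not suppressed.
* The T2 optimizer brackets the loglinear rate by a factor of five each
  way; a voxel whose loglinear fit fails (non-positive signal or
  non-negative slope) is invalid rather than refit from an arbitrary
  start.
* Empty effective masks, duplicate I-O currents, overlapping paired
  pulses, unknown label codes, and midlines outside the grid are rejected
  with diagnostics; per-scan failures inside the cohort pipeline are
  collected and reported while the run continues.
* One seed drives every stochastic stage; generation is bit-reproducible
  for a fixed spec, and the demo workspace hashes identically across
  re-runs.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run on reduced grids chosen to
exercise every code path at comfortable statistical power: phantoms of
40 × 40 × 8 voxels (≈ 470 lesion voxels), 20-phantom recovery cohorts,
10⁴ replicate voxels for the noisy-fit oracle comparison, 8 input-output
series per recording side, and Ct tables of 6 samples per group. These
sizes are the package's own defaults for its checks; all functions accept
full-scan grids (64 × 64 × 20 and beyond) unchanged.

## Known limitations

* The segmentation assumes the lesion mask is trustworthy; it inherits
  any CSF or skull contamination the mask lets through.
* Hemisphere volumetrics require a column-aligned midline; tilted brains
  must be resampled upstream.
* The mono-exponential T2 model ignores multi-compartment decay; in real
  edema the fitted T2 is an effective value.
* PPF is computed on FP1 by default; studies computing it on the whole
  field response will differ systematically.
* The ddCt implementation assumes perfect amplification efficiency
  (the classical method); efficiency-corrected models are out of scope.
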