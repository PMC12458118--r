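# hiquant

Quantification of experimental neonatal hypoxic-ischemic (H-I) brain
injury from multi-echo T2-weighted MRI and cortical slice
electrophysiology.

After a neonatal H-I insult, cytotoxic edema shows up as T2-hyperintense
tissue. `hiquant` turns multi-echo MRI and evoked-potential recordings of
such experiments into the standard quantitative outcomes:

* **T2 relaxometry** — voxelwise mono-exponential fits
  S(TE) = S₀·exp(−TE/T₂), loglinear or nonlinear (variable projection
  with loglinear initialization), with per-voxel validity masks.
* **Hierarchical region-split segmentation** — the edematous region of
  interest is recursively split at the valley between the two dominant
  modes of its smoothed T2 histogram; terminal regions whose mode exceeds
  56 ms are labeled *ischemic core*, the rest *penumbra*, and voxels with
  T₂ < 33 ms are relabeled *uninjured* (both thresholds strict and
  configurable).
* **Volumetrics** — class volumes (voxels × voxel volume), lost tissue by
  hemisphere subtraction max(0, V_contra − V_ipsi), and tidy longitudinal
  tables ready for repeated-measures ANOVA.
* **Evoked field potentials** — volley-burst / FP1 (4–6 ms) / FP2
  (6–10 ms) component detection with artifact blanking, input-output
  curves over the 0–650 µA protocol with trapezoidal area under the
  curve, paired-pulse facilitation 100·(A₂−A₁)/A₁, and the
  border-vs-contralateral AUC ratio that quantifies post-hypoxic
  potentiation.
* **Expression** — delta-delta-Ct fold changes (2^−ΔΔCt) for a target
  gene against a housekeeping gene and reference group.
* **Synthetic data** — multi-echo MRI phantoms (ellipsoidal hemispheres,
  core + penumbra lesion, Rician noise, optional tissue loss) and
  synthetic fEPSP sweeps with known ground truth, so the whole pipeline
  is testable end to end without scanner data.

## Worked example

```r
library(hiquant)

# a noisy phantom with known lesion geometry
spec <- phantom_spec(grid_shape = c(40, 40, 8), noise_sigma = 20, seed = 42)
ph   <- make_phantom(spec)

# fit the T2 map inside the lesion ROI, segment, and measure volumes
map <- fit_t2_map(ph$volume, brain_mask = ph$lesion_mask)
seg <- segment_lesion(map, ph$lesion_mask)
print(seg$tree)
#> [depth 0] n=472 mode=45.50 ms split @ 58.50 ms
#>   [depth 1] n=356 mode=45.50 ms leaf
#>   [depth 1] n=116 mode=71.50 ms leaf
class_volumes(seg)
#>       class n_voxels volume_mm3
#> 1 uninjured        0     0.0000
#> 2  penumbra      356     2.5632
#> 3      core      116     0.8352
ph$truth$true_volumes
#> uninjured  penumbra      core
#>   30.0096    2.5632    0.8352
```

The recursion found one valley (at 58.5 ms), producing a 45.5 ms-mode
leaf (penumbra, ≤ 56 ms) and a 71.5 ms-mode leaf (core, > 56 ms); at this
noise level (2% of S₀) every lesion voxel lands in its true class, so the
measured volumes match the generator's ground truth exactly. (Uninjured
tissue is outside the lesion mask here, hence 0 within it.)

```r
# evoked potentials: I-O curve area and paired-pulse facilitation
curve <- build_io_curve(make_io_series(
  ephys_spec(potentiation_factor = 1.5, seed = 1)))
curve$auc_fp1
#> [1] 814.8  # mV*uA; 1.5x the unpotentiated area

ppf <- paired_pulse_facilitation(make_paired_pulse(
  ephys_spec(noise_sd = 0, facilitation_factor = 1.5)))
ppf$ppf_percent
#> [1] 50
```

`run_demo(seed, out_dir)` builds a complete seeded workspace — a
two-group imaging cohort with a treatment-linked core reduction, ephys
recordings with and without border potentiation, and a Ct table — runs
every stage, and writes `summary.txt`; re-runs with the same seed are
bit-identical. A thin command-line wrapper around the same functions is
installed at `inst/cli/hiquant.R` (subcommands `simulate-phantom`,
`fit-t2`, `segment`, `volumes`, `ephys-measure`, `ephys-io`, `ddct`,
`demo`).

## Documentation

The methods vignette (`vignettes/hiquant-methods.Rmd`) describes the
models, the segmentation procedure and its tie-breaks, the measurement
conventions, what the synthetic-data module does and does not emulate,
and the package's known limitations.
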