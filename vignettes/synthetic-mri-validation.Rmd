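---
title: "Validating synthetic MRI relaxometry: models, simulation design, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating synthetic MRI relaxometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthmri)
```

## The problem

Synthetic MRI estimates proton density (PD), T1 and T2 in every voxel from
a single multi-dynamic multi-echo acquisition, then *resynthesizes* any
spin-echo contrast (T1-weighted, T2-weighted, FLAIR) by plugging chosen
TR/TE/TI values into signal equations. The clinical appeal is speed — one
four-minute scan replaces several weighted acquisitions — but the synthetic
contrasts are only as good as the fitted relaxation times. Two questions
follow:

1. **Accuracy and repeatability.** How close are synthetic-scan T1/T2
   values to conventional spin-echo reference measurements, across the
   range of relaxation times found in brain tissue, and how stable are they
   across sessions and days? This is answered with CuSO~4~ tube phantoms.
2. **Diagnostic contrast.** Do the known inaccuracies (concentrated in
   long-T1/T2, CSF-like ranges) damage the contrast of clinically relevant
   regions, in particular ischemic stroke lesions? This is answered with a
   thalamus-standardized contrast-to-noise ratio (CNR) comparison.

No patient or scanner data are available to this package; everything
downstream of the physics is driven by simulation plus one packaged table
of published-quality phantom measurements (reference values and 14
synthetic sessions for 7 T1 tubes and 7 T2 tubes). The package therefore
ships generators for all inputs the analyses need, and the analyses
themselves are ordinary, reusable functions.

## Signal models and their assumptions

All times are milliseconds; signals are arbitrary units.

* Inversion-recovery spin echo (`ir_se_signal()`):
  \(S(TI) = PD\,\lvert 1 - 2e^{-TI/T_1} + e^{-TR/T_1}\rvert\).
* Transverse decay (`t2_decay()`): \(S(TE) = S_0\, e^{-TE/T_2}\).
* Contrast synthesis (`synthesize_weighted()`): the product of the two
  when a TI exists, and the saturation-recovery form
  \(PD\,(1 - e^{-TR/T_1})\,e^{-TE/T_2}\) otherwise. Background voxels
  (label 0) synthesize to exactly 0.

Assumptions, deliberately simple and stated once:

* **Magnitude convention.** Scanner images are magnitude images, so
  user-facing signals are absolute values; the signed IR model is used
  internally for fitting after polarity restoration.
* **Perfect inversion.** The IR bracket uses the factor exactly 2; no
  inversion-efficiency parameter is modelled.
* **Effective timings only.** Fast-spin-echo echo-train and partition
  effects are ignored; each contrast is characterized by its effective
  TR/TE/TI. Likewise no B0/B1 inhomogeneity, slice profile or stimulated
  echoes (the multi-echo T2 fit optionally drops the first echo, where
  stimulated-echo contamination usually lands; the default keeps all 20
  echoes).
* The vendor's actual synthesis equations are proprietary; the standard
  spin-echo forms above are this package's documented stand-in.

`null_t1_for_sequence()` inverts the IR bracket by bracketed root search
(`uniroot` on [1, 10·TR] plus a few Newton polishing steps), returning the
T1 a FLAIR TI is designed to null. With the default FLAIR timing
(TI 2472 / TR 9000) the nulled T1 is ≈ 4276 ms — close to the default CSF
T1 of 4300 ms, which is why the default brain phantom suppresses CSF well.

## The synthetic-data generators

### Tube phantoms

`default_t1_phantom()` / `default_t2_phantom()` describe two tanks of
normal saline, each holding seven sealed cylindrical tubes (cross-section
7.1 cm², height 6 cm, arranged on a 50 mm ring) of aqueous CuSO~4~ at
1.0–0.2 mM (T1 range ≈ 1100–2300 ms) and 20–5 mM (T2 range ≈ 50–240 ms).
The concentration→relaxation mapping is the fast-exchange relaxivity law
\(1/T = 1/T_{solvent} + r\,C\). No relaxivity constants are tabulated with
the phantom data, so `calibrate_relaxivity()` fits them by ordinary least
squares of \(1/T_{reference}\) against \(C\) on the packaged table: with
those data, \(r_1 \approx 0.51\), \(r_2 \approx 0.92\;s^{-1}mM^{-1}\),
solvent T1 ≈ 2881 ms, solvent T2 ≈ 50300 ms. The T2 intercept is an
extrapolation artifact of a seven-point regression, not a physical water
T2; it is a calibration parameter only, and both it and the relaxivities
are overridable. Saline PD and the default tank values are likewise chosen
as plausible, not taken from any measurement.

### Brain phantom

`build_brain_phantom()` rasterizes schematic anatomy: nested ellipsoids
(CSF rim, gray matter shell, white matter core), two slab-like lateral
ventricles, two ellipsoidal thalami, and one spherical chronic-stroke
lesion carved from white matter. Default grid 128 × 128 × 20 voxels, 192 mm
in-plane field of view, 5 mm slices with a 1 mm gap encoded as 6 mm slice
spacing (phantom tanks use a 160 mm field of view). Default tissue values
(PD / T1 ms / T2 ms) are plausible 3T numbers chosen once: WM 0.70/850/70,
GM 0.85/1350/95, CSF 1.00/4300/2000, thalamus 0.85/1200/85, lesion
0.90/1600/180 (prolonged relative to its WM host, as chronic infarcts
are). The geometry is *not* anatomical: because all maps are built on one
shared grid, the registration/normalization chain a real study needs is
replaced by construction. Consequences: passing tests show correctness of
the physics, fitting and statistics on piecewise-constant tissue; they say
nothing about segmentation error, partial-volume mixing at real tissue
interfaces, flow, or motion.

### Noise

`add_rician_noise()` implements the magnitude noise model
\(\sqrt{(S+n_1)^2 + n_2^2}\) with i.i.d. Gaussian channel noise of sd σ —
Rayleigh in background (mean σ√(π/2), sd σ√(2−π/2)), Gaussian-like at high
SNR. Noise is i.i.d. across voxels and volumes; a seed is a required
argument wherever randomness exists, and all pipeline seeds derive from
the single config seed.

### The synthetic-scan bias model

The packaged table shows that synthetic-scan values drift from the
reference as relaxation times grow (≈ +24% for the longest-T1 tube). To
let end-to-end simulations reproduce that pattern, `derive_bias_table()`
turns each table row into a multiplicative factor (mean synthetic /
reference) and `synthetic_scan_bias()` applies it to true values,
interpolating linearly over the *reference relaxation time* with
nearest-neighbour extrapolation outside the tabulated range. Keying the
interpolation on the relaxation time rather than on concentration lets one
bias table serve both tubes (where concentration is known) and brain
tissues (where it is meaningless); inside the tabulated range the two
parameterizations are equivalent because the relaxivity law is monotone.

## Relaxometry fitting

`fit_t1_ir()` and `fit_t2_me()` are two-parameter nonlinear least squares
(amplitude + relaxation time), Levenberg–Marquardt via minpack.lm with
ftol/ptol 10⁻¹⁰ and at most 200 iterations, safeguarded by a profiled
1-D search: for fixed relaxation time the optimal amplitude is closed-form,
so a log-spaced grid plus `optimize()` bounds the global minimum and wins
whenever LM stalls in a worse local minimum. Estimates are bounded to
[1, 20000] ms (T1) and [1, 5000] ms (T2); estimates on a bound, constant
input, or all-zero input yield a `converged = FALSE` result rather than an
error.

Start values are derivative-free heuristics: T1 from the null-point
identity (TI of the minimum-magnitude sample divided by ln 2), T2 from the
log-slope through the first and last positive echoes.

Magnitude IR data lose sign, so `restore_polarity()` flips all samples up
to a flip index near the minimum-magnitude sample; the two candidate
indexes (minimum point on the negative or positive branch) are decided by
trial-fit residual, ties toward the earlier index, and the whole choice is
verified in tests against exhaustive search over all flip indexes. Whether
the original analysis fitted magnitude or restored data is unknown; both
paths exist (`polarity = "restore"` is the default, `"magnitude"` fits the
absolute-value model directly).

`fit_maps()` applies the scalar fits voxelwise under a mask; for
homogeneous tube phantoms, `roi_time_courses()` + scalar fits (the route
the pipeline uses) is equivalent and far cheaper.

## Validation statistics

* `percent_difference()`:
  100 · (T_synthetic − T_reference) / T_reference, signed.
* `friedman_test()` wraps `stats::friedman.test` (mid-ranks, chi-square
  approximation, df = k − 1). One addition: a design in which *every*
  block is completely tied has no rank information at all and is returned
  as statistic 0, p = 1, instead of the 0/0 the tie-corrected formula
  produces. The packaged table contains exactly one such row (T2, 15 mM,
  interday layout).
* `bonferroni()`: min(1, m·p), reject when the adjusted p is below α.

`build_validation_report()` aggregates the 14 synthetic sessions per row by
their **mean** before computing the percent difference. The source table's
caption speaks of average values but never states the aggregation; the
mean-of-14 choice reproduces all three headline bounds (T1 > 20% at
0.2 mM; T2 < 10% for 11–20 mM; T2 > 20% for 7–9 mM) and is configurable to
per-session differences. Two repeatability layouts are computed because
the original blocking is not defined anywhere: interday (per row, k = 2
days × n = 7 sessions, Bonferroni over 14 rows) and intersession (per
quantity and day, k = 7 sessions × n = 7 concentrations, Bonferroni over
4 tests). On the packaged table no interday test survives correction
(minimum adjusted p ≈ 0.114). One intersession cell (T1, day 1) does flag
a consistent session-to-session drift — an honest feature of the printed
numbers under this blocking; it is reported, not suppressed.

Two claims about that table are deliberately *not* reproduced as bounds:
the 5–8% difference sometimes quoted for 0.7–1.0 mM T1 recomputes to
between −8.2% and −1.2% under any aggregation here, so those rows carry a
flag column in the report instead.

## The CNR comparison

`standardized_cnr()` is (region mean − thalamus mean) / thalamus sd, with
the sample (n−1) standard deviation throughout (no convention is stated in
the field; this is the common default). The ratio is exactly invariant
under positive affine intensity transforms, which is the point of
standardizing: scanner gain and offset cancel. Noiseless input (thalamus
sd 0) is an error by contract, never ±Inf.

`run_brain_experiment()` simulates a matched cohort (default 18 subjects)
in two modes sharing each subject's anatomy and tissue parameters —
per-subject variability is a multiplicative log-normal jitter (sd 0.02) on
every tissue's PD/T1/T2:

* **clinical**: contrasts synthesized from the true tissue values;
* **synthetic**: the table-derived bias first applied to the long-T1/T2
  tissues (CSF by default), then synthesized;

each mode with an independent Rician noise realization (σ = 0.01 a.u.
against tissue signals of order 0.1–0.6). Per subject and contrast the
CNRs of WM, GM, CSF and lesion are computed against the thalamus, and
`compare_modes()` runs one Friedman test per region × contrast cell
(subjects as blocks, modes as treatments) with Bonferroni correction over
the 12-cell family. Because only CSF parameters differ between modes, any
rejection outside CSF would be a false positive; the CSF shift on
T2-weighted and FLAIR images is large and direction-consistent across
subjects (the FLAIR TI no longer nulls the biased CSF T1), while on
T1-weighted images the CSF signal is so small that the shift drowns in ROI
noise. The experiment therefore reproduces the qualitative pattern —
CSF significant on T2w and FLAIR only, lesions unaffected — which is the
designed direction of the comparison, not a fitted outcome. Magnitudes of
patient-data CNRs are out of scope; real cohorts carry anatomy,
registration error and artifact structure this simulation does not.

## Numerical and design choices, in one place

* Estimation bounds [1, 20000] / [1, 5000] ms; LM tolerances 10⁻¹⁰, 200
  iterations; profile grid 400 points, log-spaced.
* Polarity-restoration ties break toward the earlier flip index.
* Root search for nulled T1: bracket [1, 10·TR], error when the bracket
  has no sign change (a null requires 2·TI < TR).
* Rician noise seeds: one per volume, derived from the config seed by
  fixed offsets; `with_seed()` never disturbs the caller's RNG state.
* The phantom-validation *simulation* mode runs on a 64 × 64 × 8 grid with
  ROI-mean fitting (7 tubes × 14 sessions × 2 phantoms); the brain cohort
  uses the full default 128 × 128 × 20 grid. These sizes are the package's
  default study dimensions and complete in seconds on one core.
* Reports contain no timestamps, so identical configurations produce
  byte-identical output files; a provenance record (config hash, seed,
  package version) accompanies every run.

## Known limitations

Piecewise-constant tissue and schematic geometry (no partial volume, no
anisotropy, no flow); perfect inversion and mono-exponential decay;
i.i.d. noise (no parallel-imaging spatial correlation); the bias model is
a one-dimensional multiplicative interpolation of 14 table rows, so it
captures the magnitude-vs-relaxation-time trend but no spatial or
sequence-specific artifact structure (e.g. the granular FLAIR artifacts
reported for synthetic scans are not modelled). The end-to-end simulation
mode reproduces the accuracy *pattern*; its exact percent differences
differ from the table's because tube "truth" comes from the smooth
relaxivity law while the table's reference column scatters around it.
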