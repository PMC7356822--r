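# synthmri

Simulation and phantom validation of **synthetic MRI relaxometry** in R.

Synthetic MRI fits proton density (PD), T1 and T2 in every voxel from a
single multi-dynamic multi-echo scan, then resynthesizes any spin-echo
contrast by plugging chosen timings into signal equations:

- inversion-recovery spin echo:
  `S(TI) = PD · |1 − 2·exp(−TI/T1) + exp(−TR/T1)| · exp(−TE/T2)`
- saturation recovery (no inversion pulse):
  `S = PD · (1 − exp(−TR/T1)) · exp(−TE/T2)`

The technique is fast, but its contrasts are only as trustworthy as the
fitted relaxation times. This package implements the full validation
workflow for radiology physicists and imaging methodologists:

- **signal models** for simulation and contrast synthesis (T1w, T2w,
  FLAIR presets; FLAIR TI 2472 ms nulls T1 ≈ 4276 ms at TR 9000 ms);
- **generators** for CuSO₄ tube phantoms (relaxivity law
  `1/T = 1/T_solvent + r·C`, calibrated from a packaged reference table),
  brain-like label maps (WM/GM/CSF/thalamus/stroke lesion) and Rician
  magnitude noise — every input is simulated, nothing is downloaded;
- **relaxometry**: nonlinear least-squares T1 fitting of 16-point
  inversion-recovery series (with polarity restoration of magnitude data)
  and T2 fitting of 20-echo multi-echo series;
- **validation statistics**: signed percent differences against
  conventional references, Friedman repeatability tests, Bonferroni
  correction;
- **CNR analysis**: thalamus-standardized contrast-to-noise ratios,
  `CNR = (mean_region − mean_thalamus) / sd_thalamus`, compared between
  simulated clinical-like and synthetic-like acquisition modes across a
  matched cohort.

See `vignettes/synthetic-mri-validation.Rmd` for the models, assumptions
and design choices.

## Worked example

```r
library(synthmri)

## concentration -> relaxation mapping, calibrated from the packaged table
model <- calibrate_relaxivity()
model
#> <relaxivity_model> r1=0.5093, r2=0.9198 /s/mM; solvent T1=2881.4, T2=50284 ms
relaxation_from_concentration(0.2, model)$t1   # longest-T1 tube
#> [1] 2227.6

## fit T1 from a noisy simulated inversion-recovery series
tis <- ir_series_protocol()$timings            # 100 ... 4000 ms, 16 points
y <- add_rician_noise(ir_se_signal(tis, tr = 10000, t1 = 2117.2, pd = 1),
                      sigma = 0.01, seed = 7)
fit_t1_ir(acquisition_series(y, tis, mode = "IR", tr = 10000))
#> <fit_result> estimate=2097 ms, amplitude=1.008, resid=0.0507, converged (n=16)

## full phantom validation from the packaged table
res <- run_phantom_validation(run_config("phantom_validation", seed = 1,
                                         output_dir = tempfile()))
res$report
#> <validation_report>
#>    quantity concentration_mM reference synthetic_mean percent_difference
#> 1        T1              1.0    1131.5       1116.800            -1.2992
#> ...
#> 7        T1              0.2    2117.2       2642.214            24.7976
#> ...
#> 12       T2              9.0     126.7        100.750           -20.4815
#> 13       T2              7.0     166.9        122.407           -26.6584
#> 14       T2              5.0     230.3        252.693             9.7233
#> interday significant rows: 0/14; intersession: 1/4 (alpha=0.05, Bonferroni)
```

The report shows the accuracy pattern the phantoms were designed to probe:
synthetic values track the references closely for mid-range relaxation
times but drift past 20% for the longest T1 (0.2 mM) and the 7–9 mM T2
tubes — the CSF-like end of the scale — while interday repeatability shows
no significant differences after Bonferroni correction.

The brain-side experiment simulates a matched 18-subject cohort and
compares thalamus-standardized CNRs between modes:

```r
br <- run_brain_experiment(run_config("brain_cnr", seed = 1,
                                      output_dir = tempfile()))
subset(br$report$tests, reject, c(region, contrast, p_adjusted))
#>   region contrast   p_adjusted
#>      csf    FLAIR 0.0002654409
#>      csf      T2w 0.0002654409
```

Only CSF on T2-weighted and FLAIR contrasts is flagged; WM, GM and the
stroke lesion show no significant CNR differences — inaccurate CSF
relaxometry does not disturb lesion contrast.

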