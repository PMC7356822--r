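Package: synthmri
Title: Simulation and Phantom Validation of Synthetic MRI Relaxometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates quantitative MR relaxometry experiments and validates
    synthetic (calculated) MRI contrasts against conventional spin-echo
    references. Provides closed-form inversion-recovery and multi-echo
    spin-echo signal models, generators for CuSO4 tube phantoms and
    brain-like digital phantoms with Rician magnitude noise, nonlinear
    least-squares T1/T2 fitting with polarity restoration, percent-difference
    and Friedman/Bonferroni repeatability statistics, and thalamus-
    standardized contrast-to-noise ratio comparisons between simulated
    clinical and synthetic acquisition modes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
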