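test_that("relaxation times follow the relaxivity law", {
  m <- relaxivity_model(r1 = 0.5, r2 = 0.9, t1_solvent = 2800,
                        t2_solvent = 2000)
  # zero concentration returns the solvent values
  r0 <- relaxation_from_concentration(0, m)
  expect_equal(r0$t1, 2800)
  expect_equal(r0$t2, 2000)
  # strictly decreasing in concentration
  cc <- seq(0, 25, by = 0.5)
  r <- relaxation_from_concentration(cc, m)
  expect_true(all(diff(r$t1) < 0))
  expect_true(all(diff(r$t2) < 0))
  expect_error(relaxation_from_concentration(-1, m),
               class = "synthmri_error")
})

test_that("calibration recovers an exact generating model from two pairs", {
  gen <- relaxivity_model(r1 = 0.62, r2 = 1.1, t1_solvent = 3100,
                          t2_solvent = 2200)
  cc <- c(T1 = 0.3, T1 = 1.2, T2 = 4, T2 = 18)
  tab <- data.frame(
    quantity = names(cc),
    concentration_mM = unname(cc),
    reference = c(relaxation_from_concentration(cc[1:2], gen)$t1,
                  relaxation_from_concentration(cc[3:4], gen)$t2))
  fit <- calibrate_relaxivity(tab)
  expect_equal(fit$r1, gen$r1, tolerance = 1e-9)
  expect_equal(fit$r2, gen$r2, tolerance = 1e-9)
  expect_equal(fit$t1_solvent, gen$t1_solvent, tolerance = 1e-9)
  expect_equal(fit$t2_solvent, gen$t2_solvent, tolerance = 1e-9)
})

test_that("calibration equals the simple-regression slope on the packaged table", {
  tab <- load_reference_table()
  fit <- calibrate_relaxivity(tab)
  for (q in c("T1", "T2")) {
    rows <- tab[tab$quantity == q, ]
    ols <- stats::lm(I(1 / reference) ~ concentration_mM, data = rows)
    slope <- unname(coef(ols)[2]) * 1000   # per-ms -> per-s relaxivity
    expect_equal(if (q == "T1") fit$r1 else fit$r2, slope,
                 tolerance = 1e-10)
    expect_equal(if (q == "T1") fit$t1_solvent else fit$t2_solvent,
                 1 / unname(coef(ols)[1]), tolerance = 1e-8)
  }
  # singular design: all concentrations equal
  bad <- data.frame(quantity = c("T1", "T1", "T2", "T2"),
                    concentration_mM = c(1, 1, 5, 9),
                    reference = c(1000, 1100, 60, 80))
  expect_error(calibrate_relaxivity(bad), class = "synthmri_error")
})

test_that("calibrated model predicts the tabulated references", {
  fit <- calibrate_relaxivity()
  # spot checks at the range ends
  expect_equal(relaxation_from_concentration(1.0, fit)$t1, 1131.5,
               tolerance = 0.10)
  expect_equal(relaxation_from_concentration(20.0, fit)$t2, 58.5,
               tolerance = 0.10)
  # linearity of 1/T vs C across the whole table: median relative error
  tab <- load_reference_table()
  rel_err <- vapply(seq_len(nrow(tab)), function(i) {
    r <- relaxation_from_concentration(tab$concentration_mM[i], fit)
    pred <- if (tab$quantity[i] == "T1") r$t1 else r$t2
    abs(pred - tab$reference[i]) / tab$reference[i]
  }, numeric(1))
  expect_lt(median(rel_err[tab$quantity == "T1"]), 0.15)
  expect_lt(median(rel_err[tab$quantity == "T2"]), 0.15)
})

test_that("cylinder phantom maps are piecewise constant and ordered", {
  model <- calibrate_relaxivity()
  spec <- default_t1_phantom(grid_shape = c(48, 48, 6))
  maps <- build_cylinder_phantom(spec, model)
  conc <- vapply(spec$tubes, `[[`, numeric(1), "concentration")
  t1_by_tube <- vapply(seq_along(conc), function(i) {
    v <- maps$t1[maps$label == i + 1L]
    expect_gt(length(v), 0)
    expect_equal(length(unique(v)), 1L)   # piecewise constancy
    v[1]
  }, numeric(1))
  expect_equal(t1_by_tube,
               vapply(conc, function(cc)
                 relaxation_from_concentration(cc, model)$t1, numeric(1)))
  # seven distinct plateaus, ordered inversely with concentration
  expect_equal(length(unique(t1_by_tube)), 7L)
  expect_equal(order(t1_by_tube), order(conc, decreasing = TRUE))
  # voxel counts conserved over labels
  counts <- table(maps$label)
  expect_equal(sum(counts), prod(dim(maps$label)))
})

test_that("degenerate and invalid phantom specs behave as contracted", {
  # empty tube list: uniform saline tank
  maps <- build_cylinder_phantom(phantom_spec(grid_shape = c(24, 24, 4)))
  expect_setequal(unique(as.vector(maps$label)), c(0L, 1L))
  expect_equal(unique(maps$t1[maps$label == 1L]), 2800)
  # overlapping tubes rejected
  spec <- phantom_spec(tubes = list(tube_spec(1, center = c(0, 0)),
                                    tube_spec(2, center = c(5, 0))),
                       grid_shape = c(24, 24, 4))
  expect_error(build_cylinder_phantom(spec), class = "synthmri_error")
})

test_that("brain phantom has all regions with the expected ordering", {
  spec <- brain_phantom_spec(grid_shape = c(64, 64, 12))
  maps <- build_brain_phantom(spec)
  lb <- brain_labels()
  for (nm in names(lb)) expect_gt(sum(maps$label == lb[[nm]]), 0)
  t1_of <- function(nm) unique(maps$t1[maps$label == lb[[nm]]])
  expect_gt(t1_of("csf"), t1_of("gm"))
  expect_gt(t1_of("gm"), t1_of("wm"))
  counts <- table(maps$label)
  expect_equal(sum(counts), prod(dim(maps$label)))
})

test_that("FLAIR suppresses CSF in the default brain phantom", {
  maps <- build_brain_phantom(brain_phantom_spec(grid_shape = c(64, 64, 12)))
  img <- synthesize_weighted(maps, contrast_presets()$FLAIR)
  lb <- brain_labels()
  csf <- mean(img[maps$label == lb[["csf"]]])
  wm <- mean(img[maps$label == lb[["wm"]]])
  expect_lt(csf, 0.1 * wm)
})

test_that("a lesion sharing all WM parameters is invisible", {
  wm <- tissue_params(pd = 0.70, t1 = 850, t2 = 70)
  spec_eq <- brain_phantom_spec(wm = wm, lesion = wm,
                                grid_shape = c(48, 48, 10))
  spec_no <- brain_phantom_spec(wm = wm, lesion_radius = NULL,
                                grid_shape = c(48, 48, 10))
  img_eq <- synthesize_weighted(build_brain_phantom(spec_eq),
                                contrast_presets()$T2w)
  img_no <- synthesize_weighted(build_brain_phantom(spec_no),
                                contrast_presets()$T2w)
  expect_identical(img_eq, img_no)
})

test_that("oversized lesions are rejected", {
  expect_error(build_brain_phantom(
    brain_phantom_spec(grid_shape = c(48, 48, 10), lesion_radius = 200)),
    class = "synthmri_error")
})

test_that("Rician noise has Rayleigh background moments", {
  sigma <- 2
  bg <- add_rician_noise(numeric(2e5), sigma, seed = 42)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.01)
  expect_equal(sd(bg), sigma * sqrt(2 - pi / 2), tolerance = 0.01)
  expect_true(all(bg >= 0))
})

test_that("Rician noise approaches Gaussian at high SNR", {
  s <- 100; sigma <- 1
  x <- add_rician_noise(rep(s, 1e6), sigma, seed = 9)
  expect_equal(mean(x), s, tolerance = 1e-3)
})

test_that("noise is reproducible, identity at sigma 0, and independent", {
  img <- matrix(runif(100), 10)
  expect_identical(add_rician_noise(img, 0, seed = 1), img)
  a <- add_rician_noise(img, 0.5, seed = 123)
  b <- add_rician_noise(img, 0.5, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a, add_rician_noise(img, 0.5, seed = 124)))
  # spatial independence: lag-1 autocorrelation vanishes
  x <- add_rician_noise(numeric(1e6), 1, seed = 5)
  n <- length(x)
  expect_lt(abs(cor(x[-1], x[-n])), 0.01)
})

test_that("simulated acquisitions equal noiseless synthesis at sigma 0", {
  maps <- build_cylinder_phantom(
    default_t1_phantom(grid_shape = c(24, 24, 4)))
  proto <- ir_series_protocol(timings = c(100, 500, 1500, 4000))
  ser <- simulate_acquisition(maps, proto, sigma = 0)
  for (i in seq_along(proto$timings)) {
    expect_identical(ser$data[, , , i],
                     synthesize_weighted(maps, sequence_params(
                       tr = proto$tr, te = proto$te,
                       ti = proto$timings[i])))
  }
  # determinism under a fixed seed
  s1 <- simulate_acquisition(maps, proto, sigma = 0.02, seed = 77)
  s2 <- simulate_acquisition(maps, proto, sigma = 0.02, seed = 77)
  expect_identical(s1$data, s2$data)
  expect_error(simulate_acquisition(maps, list(), sigma = 0),
               class = "synthmri_error")
})

test_that("background voxels of a noisy acquisition are Rayleigh", {
  shape <- c(50, 50, 40)   # 1e5 voxels, all background
  maps <- quant_maps(array(0, shape), array(1, shape), array(1, shape),
                     array(0L, shape))
  proto <- me_series_protocol(timings = c(10, 50))
  sigma <- 2
  ser <- simulate_acquisition(maps, proto, sigma = sigma, seed = 3)
  expect_equal(mean(ser$data[, , , 1]), sigma * sqrt(pi / 2),
               tolerance = 0.01)
})

test_that("table-derived bias factors reproduce the accuracy pattern", {
  bt1 <- derive_bias_table(quantity = "T1")
  bt2 <- derive_bias_table(quantity = "T2")
  # empty table is the identity
  expect_identical(synthetic_scan_bias(c(800, 2000), NULL), c(800, 2000))
  expect_identical(synthetic_scan_bias(1500, bt1[0, ]), 1500)
  # longest-T1 tube (0.2 mM): synthetic overestimates by > 20%
  expect_gt(synthetic_scan_bias(2117.2, bt1) / 2117.2, 1.20)
  # shortest-T2 tube (20 mM): synthetic within 10%
  expect_lt(abs(synthetic_scan_bias(58.5, bt2) / 58.5 - 1), 0.10)
  # nearest-neighbour extrapolation beyond the tabulated range
  expect_equal(synthetic_scan_bias(4300, bt1) / 4300,
               max(bt1$factor)[1], tolerance = 1e-12)
})
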