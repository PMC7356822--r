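signed_ir <- function(tis, tr, t1, a = 1) {
  a * (1 - 2 * exp(-tis / t1) + exp(-tr / t1))
}

test_that("polarity restoration leaves recovered or degenerate data alone", {
  tis <- ir_tis()
  # fully recovered curve: all samples already positive
  y <- signed_ir(tis, 10000, 100)   # short T1: positive at every printed TI
  expect_true(all(y > 0))
  expect_identical(restore_polarity(y, tis), y)
  # constant data returned unchanged
  expect_identical(restore_polarity(rep(2, 5), c(1, 2, 3, 4, 5)), rep(2, 5))
})

test_that("polarity restoration flips the pre-null samples", {
  tis <- ir_tis()
  t1 <- 1300   # null at ~901 ms: between samples 5 (800) and 6 (900)
  s <- signed_ir(tis, 10000, t1)
  y <- abs(s)
  restored <- restore_polarity(y, tis, tr = 10000)
  expect_equal(abs(restored), y, tolerance = 1e-12)
  expect_identical(sign(restored), sign(s))
  # output crosses zero at most once
  expect_lte(sum(diff(sign(restored)) != 0), 1)
})

test_that("chosen flip index matches the exhaustive residual search", {
  tis <- ir_tis()
  for (seed in 1:10) {
    t1 <- 800 + 150 * seed
    truth <- signed_ir(tis, 10000, t1, a = 1)
    set.seed(seed)
    y <- abs(truth + 0.01 * rnorm(length(tis)))
    restored <- restore_polarity(y, tis, tr = 10000)
    expect_identical(flip_index_of(restored),
                     brute_force_flip(y, tis, 10000))
  }
})

test_that("noiseless T1 recovery is exact across the protocol range", {
  tis <- ir_tis()
  for (t1 in c(200, 500, 1000, 2000, 4000, 1131.5, 2117.2)) {
    y <- abs(signed_ir(tis, 10000, t1, a = 3))
    fit <- fit_t1_ir(make_scalar_series(y, tis, "IR"))
    expect_true(fit$converged)
    expect_lt(abs(fit$estimate - t1) / t1, 1e-3)
    expect_equal(fit$amplitude, 3, tolerance = 1e-4)
  }
})

test_that("magnitude-model T1 fitting works without polarity restoration", {
  tis <- ir_tis()
  y <- abs(signed_ir(tis, 10000, 1500, a = 2))
  fit <- fit_t1_ir(make_scalar_series(y, tis, "IR"),
                   polarity = "magnitude")
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate - 1500) / 1500, 1e-3)
})

test_that("degenerate IR input yields a non-converged result, not an error", {
  tis <- ir_tis()
  expect_false(fit_t1_ir(make_scalar_series(rep(0, 16), tis,
                                            "IR"))$converged)
  expect_false(fit_t1_ir(make_scalar_series(rep(5, 16), tis,
                                            "IR"))$converged)
})

test_that("two-point T2 fit equals the closed-form log ratio", {
  s <- make_scalar_series(c(100, 100 * exp(-1)), c(10, 110), "ME")
  fit <- fit_t2_me(s)
  expect_true(fit$converged)
  expect_equal(fit$estimate, 100, tolerance = 1e-6)
})

test_that("noiseless T2 recovery is exact across the protocol range", {
  tes <- me_tes()
  for (t2 in c(30, 60, 120, 240, 58.5)) {
    y <- t2_decay(tes, t2, s0 = 5)
    fit <- fit_t2_me(make_scalar_series(y, tes, "ME"))
    expect_true(fit$converged)
    expect_lt(abs(fit$estimate - t2) / t2, 1e-3)
  }
  # constant series: not converged
  expect_false(fit_t2_me(make_scalar_series(rep(1, 20), tes,
                                            "ME"))$converged)
  # all non-positive: not converged
  expect_false(fit_t2_me(make_scalar_series(rep(0, 20), tes,
                                            "ME"))$converged)
})

test_that("dropping the first echo is honoured", {
  tes <- me_tes()
  y <- t2_decay(tes, 80, s0 = 2)
  y[1] <- y[1] * 1.3   # stimulated-echo style contamination
  full <- fit_t2_me(make_scalar_series(y, tes, "ME"))
  dropped <- fit_t2_me(make_scalar_series(y, tes, "ME"),
                       drop_first_echo = TRUE)
  expect_equal(dropped$estimate, 80, tolerance = 1e-6)
  expect_gt(abs(full$estimate - 80), abs(dropped$estimate - 80))
})

test_that("fits are invariant to uniform signal scaling", {
  tis <- ir_tis(); tes <- me_tes()
  set.seed(4)
  y1 <- abs(signed_ir(tis, 10000, 1200) + 0.005 * rnorm(16))
  f1 <- fit_t1_ir(make_scalar_series(y1, tis, "IR"))
  f10 <- fit_t1_ir(make_scalar_series(10 * y1, tis, "IR"))
  expect_equal(f10$estimate, f1$estimate, tolerance = 1e-9)
  expect_equal(f10$amplitude, 10 * f1$amplitude, tolerance = 1e-9)
  y2 <- t2_decay(tes, 90) + abs(0.002 * rnorm(20))
  f2 <- fit_t2_me(make_scalar_series(y2, tes, "ME"))
  f20 <- fit_t2_me(make_scalar_series(10 * y2, tes, "ME"))
  expect_equal(f20$estimate, f2$estimate, tolerance = 1e-9)
})

test_that("noisy T1 fits agree with the dense grid-search oracle", {
  tis <- ir_tis()
  errs <- numeric(20)
  for (i in 1:20) {
    set.seed(100 + i)
    y <- abs(signed_ir(tis, 10000, 1500) + 0.01 * rnorm(16))
    fit <- fit_t1_ir(make_scalar_series(y, tis, "IR"))
    ys <- restore_polarity(y, tis, 10000)
    oracle <- grid_search_t1(ys, tis, 10000)
    expect_lt(abs(fit$estimate - oracle), 1)
    errs[i] <- fit$estimate - 1500
  }
  expect_lt(abs(mean(errs)) / 1500, 0.01)
})

test_that("T2 is overestimated at low SNR under Rician noise", {
  tes <- me_tes()
  t2 <- 60; sigma <- 1; a <- 5 * sigma   # SNR 5
  est <- vapply(1:500, function(i) {
    y <- add_rician_noise(t2_decay(tes, t2, a), sigma, seed = 2000 + i)
    fit_t2_me(make_scalar_series(y, tes, "ME"))$estimate
  }, numeric(1))
  expect_gt(mean(est), t2)   # noise floor inflates the tail
})

test_that("voxelwise maps equal independent scalar fits", {
  tis <- c(100, 400, 900, 1600, 2800, 4000)
  shape <- c(2, 1, 1)
  data <- array(0, c(shape, length(tis)))
  t1s <- c(700, 1900)
  for (v in 1:2) data[v, 1, 1, ] <- abs(signed_ir(tis, 10000, t1s[v]))
  ser <- acquisition_series(data, tis, mode = "IR", tr = 10000)
  mask <- array(TRUE, shape)
  maps <- fit_maps(ser, mask)
  for (v in 1:2) {
    scalar <- fit_t1_ir(make_scalar_series(data[v, 1, 1, ], tis, "IR"))
    expect_identical(maps$estimate[v, 1, 1], scalar$estimate)
  }
  # masked-out voxel is exactly 0
  mask2 <- mask; mask2[2, 1, 1] <- FALSE
  maps2 <- fit_maps(ser, mask2)
  expect_identical(maps2$estimate[2, 1, 1], 0)
  expect_error(fit_maps(ser, array(FALSE, shape)),
               class = "synthmri_error")
})

test_that("noiseless phantom maps close the loop to the relaxivity law", {
  model <- calibrate_relaxivity()
  spec <- default_t2_phantom(grid_shape = c(24, 24, 2))
  maps <- build_cylinder_phantom(spec, model)
  ser <- simulate_acquisition(maps, me_series_protocol(), sigma = 0)
  # fit a thin slab of two tubes voxelwise
  mask <- maps$label %in% c(2L, 8L) & slice.index(maps$label, 3) == 1L
  dim(mask) <- dim(maps$label)
  fitted <- fit_maps(ser, mask)
  for (tube in c(1L, 7L)) {
    cc <- spec$tubes[[tube]]$concentration
    want <- relaxation_from_concentration(cc, model)$t2
    got <- fitted$estimate[maps$label == tube + 1L &
                             slice.index(maps$label, 3) == 1L]
    expect_lt(max(abs(got - want) / want), 1e-3)
  }
})
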