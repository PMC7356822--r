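# Reference quantification: nonlinear least-squares estimation of T1 from
# inversion-recovery series and T2 from multi-echo series, mirroring the
# conventional-scan analysis stage. Fits are two-parameter (amplitude +
# relaxation time); the amplitude is linear in the model, which both the
# Levenberg-Marquardt path and the grid fallback exploit.

T1_BOUNDS <- c(1, 20000)
T2_BOUNDS <- c(1, 5000)

# Profiled sum of squares: for fixed relaxation time the optimal amplitude
# is <y, f>/<f, f>. Returns list(sse, amplitude).
profiled_sse <- function(y, f) {
  ff <- sum(f * f)
  if (ff == 0) return(list(sse = sum(y^2), amplitude = 0))
  a <- sum(y * f) / ff
  list(sse = sum((y - a * f)^2), amplitude = a)
}

# 1-D minimization of the profiled objective over the relaxation time:
# coarse log-spaced grid then optimize() on the bracketing interval.
profile_fit <- function(y, basis_fun, bounds, n_grid = 400) {
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_grid))
  sse <- vapply(grid, function(tt) profiled_sse(y, basis_fun(tt))$sse,
                numeric(1))
  i <- which.min(sse)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  opt <- optimize(function(tt) profiled_sse(y, basis_fun(tt))$sse,
                  c(lo, hi), tol = 1e-8)
  est <- opt$minimum
  list(estimate = est, amplitude = profiled_sse(y, basis_fun(est))$amplitude,
       sse = opt$objective)
}

# Levenberg-Marquardt refinement of (A, T) with profile fallback.
lm_fit <- function(y, basis_fun, start_t, start_a, bounds) {
  res_fn <- function(p) y - p[1] * basis_fun(p[2])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(start_a, start_t), fn = res_fn,
      lower = c(-Inf, bounds[1]), upper = c(Inf, bounds[2]),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 200)),
    error = function(e) NULL)
  pf <- profile_fit(y, basis_fun, bounds)
  if (!is.null(fit)) {
    sse_lm <- sum(res_fn(fit$par)^2)
    if (sse_lm <= pf$sse + 1e-12 * (1 + pf$sse))
      return(list(estimate = fit$par[2], amplitude = fit$par[1],
                  sse = sse_lm))
  }
  pf
}

not_converged <- function(n) {
  fit_result(estimate = NA_real_, amplitude = NA_real_,
             residual_norm = NA_real_, converged = FALSE, n_points = n)
}

series_vector <- function(series) {
  if (!inherits(series, "acquisition_series"))
    stop_synthmri("`series` must be an acquisition_series", "invalid_series")
  y <- series$data
  if (!is.null(dim(y)) && length(dim(y)) > 1L)
    stop_synthmri("scalar fit expects a single time course; use fit_maps() for volumes",
                  "invalid_series")
  as.numeric(y)
}

#' Restore the polarity of magnitude inversion-recovery data
#'
#' Magnitude IR images lose the sign of the longitudinal magnetization:
#' early-TI samples that were negative appear positive. This flips the sign
#' of all samples up to a flip index near the minimum-magnitude sample. Two
#' candidate flip indexes (the minimum point belonging to the negative or
#' the positive branch) are tried and the one with the smaller trial-fit
#' residual wins; ties break toward the earlier index. Monotone data that
#' need no flip are returned unchanged.
#'
#' @param signals Magnitude signals, one per TI.
#' @param tis Inversion times, ms, strictly increasing.
#' @param tr Repetition time, ms.
#' @return Signed signals; `abs()` of the output equals the input
#'   pointwise and the output changes sign at most once.
#' @export
restore_polarity <- function(signals, tis, tr = 10000) {
  n <- length(signals)
  if (n < 3L)
    stop_synthmri("polarity restoration needs >= 3 points", "invalid_series")
  if (length(tis) != n)
    stop_synthmri("`signals` and `tis` lengths differ", "series_mismatch")
  if (sd(signals) == 0) return(signals)
  m <- which.min(abs(signals))      # earliest minimum on ties
  basis <- function(t1) ir_bracket(tis, tr, t1)
  sse_for_flip <- function(f) {
    s <- signals * ifelse(seq_len(n) <= f, -1, 1)
    profile_fit(s, basis, T1_BOUNDS, n_grid = 150)$sse
  }
  cand <- unique(pmax(0L, pmin(n, c(m - 1L, m))))
  sse <- vapply(cand, sse_for_flip, numeric(1))
  best <- cand[which.min(sse)]      # which.min takes the earlier on ties
  signals * ifelse(seq_len(n) <= best, -1, 1)
}

#' Fit T1 from an inversion-recovery series
#'
#' Nonlinear least squares of the two-parameter IR model
#' `S(TI) = A * (1 - 2 exp(-TI/T1) + exp(-TR/T1))` (perfect inversion,
#' fixed TR term). By default the magnitude data are polarity-restored
#' first and the signed model is fitted; `polarity = "magnitude"` fits
#' `A * |...|` directly instead. Start values come from the null-point
#' heuristic `T1 ~ TI_min-magnitude / ln 2`.
#'
#' @param series An [acquisition_series] with mode `"IR"` holding a single
#'   time course.
#' @param polarity `"restore"` (default) or `"magnitude"`.
#' @return A `fit_result` with the T1 estimate (ms), amplitude, residual
#'   norm and convergence flag. Degenerate (constant or all-zero) input
#'   yields a non-converged result, not an error.
#' @export
fit_t1_ir <- function(series, polarity = c("restore", "magnitude")) {
  polarity <- match.arg(polarity)
  y <- series_vector(series)
  if (series$mode != "IR")
    stop_synthmri("fit_t1_ir needs an IR-mode series", "invalid_series")
  n <- length(y)
  if (n < 3L)
    stop_synthmri("T1 fit needs >= 3 points", "invalid_series")
  if (any(!is.finite(y)))
    stop_synthmri("non-finite signal values", "invalid_series")
  if (sd(y) == 0 || all(y == 0)) return(not_converged(n))
  tis <- series$timings; tr <- series$tr
  start_t <- min(max(tis[which.min(abs(y))] / log(2), T1_BOUNDS[1] * 2),
                 T1_BOUNDS[2] / 2)
  if (polarity == "restore") {
    ys <- restore_polarity(y, tis, tr)
    basis <- function(t1) ir_bracket(tis, tr, t1)
  } else {
    ys <- y
    basis <- function(t1) abs(ir_bracket(tis, tr, t1))
  }
  fit <- lm_fit(ys, basis, start_t, max(abs(ys)), T1_BOUNDS)
  est <- fit$estimate
  conv <- is.finite(est) && est > T1_BOUNDS[1] && est < T1_BOUNDS[2]
  fit_result(estimate = est, amplitude = fit$amplitude,
             residual_norm = sqrt(fit$sse), converged = conv, n_points = n)
}

#' Fit T2 from a multi-echo series
#'
#' Nonlinear least squares of `S(TE) = A * exp(-TE/T2)`. The start value is
#' the log-slope through the first and last echoes with positive signal.
#' The first echo can be excluded (`drop_first_echo = TRUE`) when
#' stimulated-echo contamination of multi-echo trains is a concern; the
#' default fits all echoes.
#'
#' @param series An [acquisition_series] with mode `"ME"` holding a single
#'   time course.
#' @param drop_first_echo Drop the first echo before fitting.
#' @return A `fit_result` with the T2 estimate (ms). Constant series or
#'   series with no positive signal yield a non-converged result.
#' @export
fit_t2_me <- function(series, drop_first_echo = FALSE) {
  y <- series_vector(series)
  if (series$mode != "ME")
    stop_synthmri("fit_t2_me needs an ME-mode series", "invalid_series")
  tes <- series$timings
  if (drop_first_echo && length(y) > 2L) {
    y <- y[-1]; tes <- tes[-1]
  }
  n <- length(y)
  if (n < 2L)
    stop_synthmri("T2 fit needs >= 2 points", "invalid_series")
  if (any(!is.finite(y)))
    stop_synthmri("non-finite signal values", "invalid_series")
  if (sd(y) == 0 || all(y <= 0)) return(not_converged(n))
  pos <- which(y > 0)
  i1 <- pos[1]; i2 <- pos[length(pos)]
  start_t <- if (i2 > i1 && y[i1] > y[i2])
    (tes[i2] - tes[i1]) / log(y[i1] / y[i2]) else mean(tes)
  start_t <- min(max(start_t, T2_BOUNDS[1] * 2), T2_BOUNDS[2] / 2)
  basis <- function(t2) exp(-tes / t2)
  fit <- lm_fit(y, basis, start_t, max(y), T2_BOUNDS)
  est <- fit$estimate
  conv <- is.finite(est) && est > T2_BOUNDS[1] && est < T2_BOUNDS[2]
  fit_result(estimate = est, amplitude = fit$amplitude,
             residual_norm = sqrt(fit$sse), converged = conv, n_points = n)
}

scalar_series <- function(y, series) {
  acquisition_series(as.numeric(y), series$timings, mode = series$mode,
                     tr = series$tr, te = series$te)
}

#' Voxelwise relaxometry maps
#'
#' Applies the scalar T1 or T2 fit (chosen by the series mode) to every
#' voxel inside a mask. Voxels outside the mask are exactly 0.
#'
#' @param series An [acquisition_series] whose `data` is a 4D array.
#' @param mask Logical array on the series grid; must select at least one
#'   voxel.
#' @param ... Passed to [fit_t1_ir()] / [fit_t2_me()].
#' @return A list of arrays (`estimate`, `amplitude`, `residual_norm`,
#'   `converged`) on the series grid, class `fit_maps`.
#' @export
fit_maps <- function(series, mask, ...) {
  if (!inherits(series, "acquisition_series") ||
      length(dim(series$data)) != 4L)
    stop_synthmri("`series` must hold a 4D volume stack", "invalid_series")
  shape <- dim(series$data)[1:3]
  if (!identical(dim(mask), shape))
    stop_synthmri("mask is not on the series grid", "grid_mismatch")
  idx <- which(mask)
  if (!length(idx))
    stop_synthmri("mask selects no voxels", "empty_mask")
  n_t <- dim(series$data)[4]
  mat <- matrix(series$data, ncol = n_t)[idx, , drop = FALSE]
  fitter <- if (series$mode == "IR") fit_t1_ir else fit_t2_me
  est <- array(0, shape); amp <- array(0, shape)
  rn <- array(0, shape); conv <- array(FALSE, shape)
  for (k in seq_along(idx)) {
    fr <- fitter(scalar_series(mat[k, ], series), ...)
    est[idx[k]] <- ifelse(is.na(fr$estimate), 0, fr$estimate)
    amp[idx[k]] <- ifelse(is.na(fr$amplitude), 0, fr$amplitude)
    rn[idx[k]] <- ifelse(is.na(fr$residual_norm), 0, fr$residual_norm)
    conv[idx[k]] <- isTRUE(fr$converged)
  }
  structure(list(estimate = est, amplitude = amp, residual_norm = rn,
                 converged = conv, mode = series$mode),
            class = "fit_maps")
}

#' Per-label mean time courses of a series
#'
#' Extracts the mean signal across all voxels of each requested label at
#' every timing — the ROI-based quantification route used for tube
#' phantoms, where each tube is homogeneous.
#'
#' @param series A 4D [acquisition_series].
#' @param label Integer label array on the series grid.
#' @param ids Label ids to extract.
#' @return A matrix, one row per id (rownames = ids), one column per
#'   timing.
#' @export
roi_time_courses <- function(series, label, ids) {
  shape <- dim(series$data)[1:3]
  if (!identical(dim(label), shape))
    stop_synthmri("label map is not on the series grid", "grid_mismatch")
  n_t <- dim(series$data)[4]
  mat <- matrix(series$data, ncol = n_t)
  out <- t(vapply(ids, function(id) {
    v <- label == id
    if (!any(v))
      stop_synthmri(sprintf("label %d absent from label map", id),
                    "missing_label")
    colMeans(mat[as.vector(v), , drop = FALSE])
  }, numeric(n_t)))
  rownames(out) <- ids
  out
}
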