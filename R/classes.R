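#' Spin-echo sequence parameters
#'
#' Container for the effective timing parameters of one spin-echo
#' acquisition. All times are in milliseconds. `ti = NULL` means a
#' non-inversion sequence (e.g. plain T2-weighted fast spin echo).
#'
#' @param tr Repetition time, ms; must be positive and exceed `te` and `ti`.
#' @param te Echo time, ms, non-negative.
#' @param ti Inversion time, ms, or `NULL` for sequences without an
#'   inversion pulse.
#' @param label Free-text contrast label, e.g. `"T1w"` or `"T2-FLAIR"`.
#' @return An object of class `sequence_params`.
#' @examples
#' sequence_params(tr = 1800, te = 23, ti = 750, label = "T1w")
#' @export
sequence_params <- function(tr, te, ti = NULL, label = "") {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop_synthmri("`tr` must be a single positive finite number (ms)",
                  "invalid_protocol")
  if (!is.numeric(te) || length(te) != 1L || !is.finite(te) || te < 0)
    stop_synthmri("`te` must be a single non-negative finite number (ms)",
                  "invalid_protocol")
  if (te >= tr)
    stop_synthmri("`te` must be smaller than `tr`", "invalid_protocol")
  if (!is.null(ti)) {
    if (!is.numeric(ti) || length(ti) != 1L || !is.finite(ti) || ti < 0)
      stop_synthmri("`ti` must be NULL or a single non-negative number (ms)",
                    "invalid_protocol")
    if (ti >= tr)
      stop_synthmri("`ti` must be smaller than `tr`", "invalid_protocol")
  }
  structure(list(tr = tr, te = te, ti = ti, label = as.character(label)),
            class = "sequence_params")
}

#' @export
print.sequence_params <- function(x, ...) {
  cat(sprintf("<sequence_params> %s TR=%g ms, TE=%g ms%s\n",
              if (nzchar(x$label)) paste0("[", x$label, "]") else "",
              x$tr, x$te,
              if (is.null(x$ti)) "" else sprintf(", TI=%g ms", x$ti)))
  invisible(x)
}

#' Tissue relaxation parameters
#'
#' Proton density (arbitrary units) and T1/T2 relaxation times (ms) of one
#' tissue class. Physically plausible tissue has `t2 <= t1`; violating that
#' raises a warning, not an error, so exotic test configurations remain
#' expressible.
#'
#' @param pd Proton density, arbitrary units, non-negative.
#' @param t1 Longitudinal relaxation time, ms, positive.
#' @param t2 Transverse relaxation time, ms, positive.
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params(pd = 0.7, t1 = 850, t2 = 70)
#' @export
tissue_params <- function(pd, t1, t2) {
  for (nm in c("pd", "t1", "t2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_synthmri(sprintf("`%s` must be a single finite number", nm),
                    "invalid_tissue")
  }
  if (pd < 0) stop_synthmri("`pd` must be non-negative", "invalid_tissue")
  if (t1 <= 0 || t2 <= 0)
    stop_synthmri("`t1` and `t2` must be positive (ms)", "invalid_tissue")
  if (t2 > t1)
    warning("t2 > t1 is physically implausible for tissue", call. = FALSE)
  structure(list(pd = pd, t1 = t1, t2 = t2), class = "tissue_params")
}

#' Co-registered quantitative maps
#'
#' Bundles PD, T1, T2 and an integer label volume sharing one voxel grid.
#' Label 0 is background by convention; background voxels synthesize to 0.
#'
#' @param pd,t1,t2 Numeric arrays of identical dimension: proton density
#'   (a.u.), T1 (ms), T2 (ms). T1/T2 may be 0 in background voxels.
#' @param label Integer array of the same dimension; 0 = background.
#' @param voxdim Voxel dimensions in mm (length 3). The default encodes
#'   5 mm slices with a 1 mm gap as 6 mm slice spacing.
#' @param label_names Optional named integer vector mapping region names to
#'   label ids.
#' @return An object of class `quant_maps`.
#' @export
quant_maps <- function(pd, t1, t2, label,
                       voxdim = c(1.25, 1.25, 6),
                       label_names = NULL) {
  dims <- dim(pd)
  if (is.null(dims)) {
    pd <- as.array(pd); t1 <- as.array(t1); t2 <- as.array(t2)
    label <- as.array(label)
    dims <- dim(pd)
  }
  for (nm in c("t1", "t2", "label")) {
    v <- get(nm)
    if (!identical(dim(v), dims))
      stop_synthmri(sprintf("map `%s` is not on the same grid as `pd`", nm),
                    "grid_mismatch")
  }
  if (length(voxdim) != 3L || any(!is.finite(voxdim)) || any(voxdim <= 0))
    stop_synthmri("`voxdim` must be 3 positive voxel sizes in mm",
                  "invalid_grid")
  structure(list(pd = pd, t1 = t1, t2 = t2,
                 label = label, voxdim = as.numeric(voxdim),
                 label_names = label_names),
            class = "quant_maps")
}

#' @export
print.quant_maps <- function(x, ...) {
  cat(sprintf("<quant_maps> grid %s, voxel %s mm, %d labels\n",
              paste(dim(x$pd), collapse = "x"),
              paste(signif(x$voxdim, 3), collapse = "x"),
              length(unique(as.vector(x$label)))))
  invisible(x)
}

#' Acquisition series (varying TI or TE)
#'
#' A stack of magnitude images (or scalar signals) acquired while a single
#' timing parameter varies: the inversion time for mode `"IR"`, the echo
#' time for mode `"ME"`.
#'
#' @param data Signals: a numeric vector (one voxel), a matrix with one row
#'   per voxel, or a 4D array whose last dimension indexes the timing list.
#' @param timings Strictly increasing TI or TE values, ms.
#' @param mode `"IR"` (inversion recovery, timings are TIs) or `"ME"`
#'   (multi-echo, timings are TEs).
#' @param tr Repetition time shared by all volumes, ms.
#' @param te Echo time shared by all volumes of an IR series, ms.
#' @return An object of class `acquisition_series`.
#' @export
acquisition_series <- function(data, timings, mode = c("IR", "ME"),
                               tr = 10000, te = 0) {
  mode <- match.arg(mode)
  timings <- as.numeric(timings)
  if (length(timings) < 2L)
    stop_synthmri("need at least two timing points", "invalid_series")
  if (any(!is.finite(timings)) || any(diff(timings) <= 0))
    stop_synthmri("`timings` must be finite and strictly increasing",
                  "invalid_series")
  n_t <- length(timings)
  nd <- length(dim(data))
  n_data <- if (is.null(dim(data))) length(data)
            else dim(data)[nd]
  if (n_data != n_t)
    stop_synthmri(sprintf(
      "series has %d volumes but %d timings", n_data, n_t),
      "series_mismatch")
  structure(list(data = data, timings = timings, mode = mode,
                 tr = tr, te = te),
            class = "acquisition_series")
}

#' @export
print.acquisition_series <- function(x, ...) {
  cat(sprintf("<acquisition_series> mode %s, %d timings (%g..%g ms), TR=%g\n",
              x$mode, length(x$timings), min(x$timings), max(x$timings),
              x$tr))
  invisible(x)
}

# Internal constructor for fit results.
fit_result <- function(estimate, amplitude, residual_norm, converged,
                       n_points) {
  structure(list(estimate = estimate, amplitude = amplitude,
                 residual_norm = residual_norm, converged = converged,
                 n_points = n_points),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> estimate=%.4g ms, amplitude=%.4g, resid=%.3g, %s (n=%d)\n",
    x$estimate, x$amplitude, x$residual_norm,
    if (isTRUE(x$converged)) "converged" else "NOT converged", x$n_points))
  invisible(x)
}

#' Relaxivity model for a paramagnetic solute
#'
#' Fast-exchange relaxivity law: `1/T = 1/T_solvent + r * C` for
#' concentration `C` in mM. Relaxivities are in s^-1 mM^-1; solvent times
#' in ms.
#'
#' @param r1,r2 Longitudinal / transverse relaxivity, s^-1 mM^-1, positive.
#' @param t1_solvent,t2_solvent Solvent relaxation times at zero solute,
#'   ms, positive. These are calibration intercepts, not necessarily the
#'   physical relaxation times of pure water.
#' @return An object of class `relaxivity_model`.
#' @seealso [calibrate_relaxivity()], [relaxation_from_concentration()]
#' @export
relaxivity_model <- function(r1, r2, t1_solvent, t2_solvent) {
  vals <- c(r1 = r1, r2 = r2, t1_solvent = t1_solvent,
            t2_solvent = t2_solvent)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_synthmri("all relaxivity model parameters must be positive",
                  "invalid_relaxivity")
  if (r2 < r1)
    warning("r2 < r1 is unusual for a paramagnetic solute", call. = FALSE)
  structure(list(r1 = r1, r2 = r2, t1_solvent = t1_solvent,
                 t2_solvent = t2_solvent),
            class = "relaxivity_model")
}

#' @export
print.relaxivity_model <- function(x, ...) {
  cat(sprintf(
    "<relaxivity_model> r1=%.4g, r2=%.4g /s/mM; solvent T1=%.5g, T2=%.5g ms\n",
    x$r1, x$r2, x$t1_solvent, x$t2_solvent))
  invisible(x)
}
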