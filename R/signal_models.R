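# Closed-form spin-echo signal models. These serve double duty: forward
# simulation of acquisitions and resynthesis of weighted contrasts from
# quantitative maps. Magnitude convention throughout: scanner images are
# magnitude images, so user-facing signals are absolute values; the signed
# IR model is exposed internally for curve fitting.

# Signed inversion-recovery bracket: 1 - 2 exp(-ti/t1) + exp(-tr/t1).
# Vectorized; assumes perfect inversion (factor exactly 2).
ir_bracket <- function(ti, tr, t1) {
  1 - 2 * exp(-ti / t1) + exp(-tr / t1)
}

ir_se_signal_signed <- function(ti, tr, t1, pd) {
  pd * ir_bracket(ti, tr, t1)
}

#' Inversion-recovery spin-echo signal
#'
#' Magnitude signal of an inversion-recovery spin-echo sequence with
#' perfect inversion and full sampling of the recovery:
#' `S = pd * |1 - 2 exp(-ti/t1) + exp(-tr/t1)|`. The echo-time decay is
#' deliberately not included here; compose with [t2_decay()] or use
#' [synthesize_weighted()] for complete contrasts.
#'
#' @param ti Inversion time, ms (may be 0). Vectorized.
#' @param tr Repetition time, ms, positive.
#' @param t1 Longitudinal relaxation time, ms, positive.
#' @param pd Proton density / amplitude, arbitrary units, non-negative.
#' @return Non-negative magnitude signal, arbitrary units.
#' @examples
#' # null point: TI = T1 * ln 2 when TR >> T1
#' ir_se_signal(ti = 1000 * log(2), tr = 1e6, t1 = 1000, pd = 1)
#' @export
ir_se_signal <- function(ti, tr, t1, pd = 1) {
  if (any(!is.finite(ti)) || any(ti < 0))
    stop_synthmri("`ti` must be finite and >= 0", "invalid_protocol")
  if (any(!is.finite(tr)) || any(tr <= 0))
    stop_synthmri("`tr` must be finite and positive", "invalid_protocol")
  if (any(!is.finite(t1)) || any(t1 <= 0))
    stop_synthmri("`t1` must be finite and positive", "invalid_tissue")
  if (any(!is.finite(pd)) || any(pd < 0))
    stop_synthmri("`pd` must be finite and >= 0", "invalid_tissue")
  abs(ir_se_signal_signed(ti, tr, t1, pd))
}

#' Mono-exponential transverse decay
#'
#' `S = s0 * exp(-te/t2)`: the echo-time dependence of a spin-echo signal.
#'
#' @param te Echo time, ms, non-negative. Vectorized.
#' @param t2 Transverse relaxation time, ms, positive.
#' @param s0 Signal at zero echo time, arbitrary units, non-negative.
#' @return Signal, arbitrary units; equals `s0` at `te = 0` and is
#'   monotonically non-increasing in `te`.
#' @examples
#' t2_decay(te = 99.3, t2 = 58.5, s0 = 100)
#' @export
t2_decay <- function(te, t2, s0 = 1) {
  if (any(!is.finite(te)) || any(te < 0))
    stop_synthmri("`te` must be finite and >= 0", "invalid_protocol")
  if (any(!is.finite(t2)) || any(t2 <= 0))
    stop_synthmri("`t2` must be finite and positive", "invalid_tissue")
  if (any(!is.finite(s0)) || any(s0 < 0))
    stop_synthmri("`s0` must be finite and >= 0", "invalid_tissue")
  s0 * exp(-te / t2)
}

#' Synthesize a weighted contrast from quantitative maps
#'
#' Applies the spin-echo signal equations voxelwise to co-registered
#' PD/T1/T2 maps. With an inversion pulse (`seq$ti` present) the voxel
#' signal is `pd * |1 - 2 exp(-ti/t1) + exp(-tr/t1)| * exp(-te/t2)`;
#' without one it is the saturation-recovery form
#' `pd * (1 - exp(-tr/t1)) * exp(-te/t2)`. Background voxels (label 0)
#' are exactly 0.
#'
#' @param maps A [quant_maps] object.
#' @param seq A [sequence_params] object.
#' @return A numeric array of magnitude signal on the grid of `maps`.
#' @examples
#' m <- quant_maps(pd = array(1, c(2, 2, 1)), t1 = array(1000, c(2, 2, 1)),
#'                 t2 = array(100, c(2, 2, 1)), label = array(1L, c(2, 2, 1)))
#' synthesize_weighted(m, sequence_params(tr = 4545, te = 110, label = "T2w"))
#' @export
synthesize_weighted <- function(maps, seq) {
  if (!inherits(maps, "quant_maps"))
    stop_synthmri("`maps` must be a quant_maps object", "invalid_maps")
  if (!inherits(seq, "sequence_params"))
    stop_synthmri("`seq` must be a sequence_params object",
                  "invalid_protocol")
  fg <- maps$label != 0L
  out <- array(0, dim(maps$pd))
  if (!any(fg)) return(out)
  pd <- maps$pd[fg]; t1 <- maps$t1[fg]; t2 <- maps$t2[fg]
  if (any(t1 <= 0) || any(t2 <= 0))
    stop_synthmri("non-positive T1/T2 inside foreground labels",
                  "invalid_tissue")
  s <- if (!is.null(seq$ti)) {
    pd * abs(ir_bracket(seq$ti, seq$tr, t1))
  } else {
    pd * (1 - exp(-seq$tr / t1))
  }
  if (seq$te > 0) s <- s * exp(-seq$te / t2)
  out[fg] <- s
  out
}

#' T1 nulled by an inversion-recovery sequence
#'
#' Finds the T1 whose signal is suppressed by the given TI/TR combination,
#' i.e. the root of the signed IR bracket. This is the T1 a FLAIR TI is
#' designed to null (CSF suppression).
#'
#' @param seq A [sequence_params] with a non-null `ti`.
#' @return The nulled T1 in ms, such that
#'   `ir_se_signal(seq$ti, seq$tr, t1, 1)` is below 1e-9.
#' @examples
#' null_t1_for_sequence(sequence_params(tr = 9000, te = 92, ti = 2472))
#' @export
null_t1_for_sequence <- function(seq) {
  if (!inherits(seq, "sequence_params") || is.null(seq$ti))
    stop_synthmri("`seq` must be a sequence_params with `ti` set",
                  "invalid_protocol")
  f <- function(t1) ir_bracket(seq$ti, seq$tr, t1)
  lo <- 1; hi <- 10 * seq$tr
  if (f(lo) * f(hi) > 0)
    stop_synthmri("IR bracket has no sign change in [1, 10*tr]; no nulled T1",
                  "no_null_point")
  root <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  # polish: uniroot tol is on t1; one Newton step ensures |signal| < 1e-9
  for (i in 1:5) {
    g <- f(root)
    if (abs(g) < 1e-12) break
    dg <- (f(root + 1e-6) - f(root - 1e-6)) / 2e-6
    if (!is.finite(dg) || dg == 0) break
    root <- root - g / dg
  }
  root
}
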