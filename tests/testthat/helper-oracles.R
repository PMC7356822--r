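# Independent oracles used to cross-check the package's fitting and
# statistics code. These are deliberately separate implementations: plain
# grid searches and textbook rank formulas, no calls into the package's
# optimization path.

# Dense grid-search minimizer for the signed IR model. For every candidate
# T1 on the grid the best amplitude is the closed-form least-squares
# solution; returns the grid T1 with smallest SSE.
grid_search_t1 <- function(y, tis, tr, grid = seq(500, 3000, by = 0.5)) {
  best_sse <- Inf; best_t1 <- NA_real_
  for (t1 in grid) {
    f <- 1 - 2 * exp(-tis / t1) + exp(-tr / t1)
    a <- sum(y * f) / sum(f * f)
    sse <- sum((y - a * f)^2)
    if (sse < best_sse) {
      best_sse <- sse; best_t1 <- t1
    }
  }
  best_t1
}

# Same idea for the mono-exponential T2 model.
grid_search_t2 <- function(y, tes, grid = seq(5, 500, by = 0.5)) {
  best_sse <- Inf; best_t2 <- NA_real_
  for (t2 in grid) {
    f <- exp(-tes / t2)
    a <- sum(y * f) / sum(f * f)
    sse <- sum((y - a * f)^2)
    if (sse < best_sse) {
      best_sse <- sse; best_t2 <- t2
    }
  }
  best_t2
}

# Textbook Friedman statistic (no tie correction; for use on continuous
# data where ties have probability zero): chi-square approximation with
# k - 1 degrees of freedom.
friedman_reference <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  stat <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
  list(statistic = stat, df = k - 1,
       p_value = pchisq(stat, k - 1, lower.tail = FALSE))
}

# Exhaustive polarity-restoration oracle: try every flip index and keep
# the one whose grid-fit residual is smallest.
brute_force_flip <- function(y, tis, tr, grid = seq(200, 5000, by = 2)) {
  n <- length(y)
  sse_flip <- vapply(0:(n - 1), function(f) {
    s <- y * ifelse(seq_len(n) <= f, -1, 1)
    t1 <- grid_search_t1(s, tis, tr, grid)
    fb <- 1 - 2 * exp(-tis / t1) + exp(-tr / t1)
    a <- sum(s * fb) / sum(fb * fb)
    sum((s - a * fb)^2)
  }, numeric(1))
  (0:(n - 1))[which.min(sse_flip)]
}

# Flip index actually chosen by restore_polarity, recovered from signs.
flip_index_of <- function(signed) sum(signed < 0)

make_scalar_series <- function(y, timings, mode, tr = 10000, te = 0) {
  acquisition_series(as.numeric(y), timings, mode = mode, tr = tr, te = te)
}

ir_tis <- function() ir_series_protocol()$timings
me_tes <- function() me_series_protocol()$timings
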