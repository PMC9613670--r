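# Independent reference implementations used as oracles in tests.
# These are deliberately naive (full-matrix, loop-based) and share no code
# with the package internals they check.

# Full-matrix banded DTW by textbook dynamic programming.
dtw_oracle <- function(a, b, w) {
  n <- length(a)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) > w) next
      cost <- abs(a[i] - b[j])
      best <- if (i == 1 && j == 1) 0 else {
        min(if (i > 1 && abs(i - 1 - j) <= w) D[i - 1, j] else Inf,
            if (j > 1 && abs(i - j + 1) <= w) D[i, j - 1] else Inf,
            if (i > 1 && j > 1) D[i - 1, j - 1] else Inf)
      }
      D[i, j] <- best + cost
    }
  }
  D[n, n]
}

# Two-tailed Fisher exact p by direct enumeration of the hypergeometric
# pmf from log-factorials (no dhyper), summing tables no more probable
# than the observed one.
fisher_oracle_p <- function(a, b, c_, d) {
  m <- a + b; n_ <- c_ + d; k <- a + c_; N <- m + n_
  if (m == 0 || n_ == 0 || k == 0 || k == N) return(1)
  lchoose2 <- function(n, x) lgamma(n + 1) - lgamma(x + 1) - lgamma(n - x + 1)
  support <- max(0, k - n_):min(k, m)
  logp <- lchoose2(m, support) + lchoose2(n_, k - support) - lchoose2(N, k)
  p <- exp(logp)
  p_obs <- p[support == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Small labeled-percentile fixture for evaluation tests.
make_labeled <- function(p_plus, p_minus, movement = "passive") {
  data.frame(
    epoch_id = sprintf("e%03d", seq_len(length(p_plus) + length(p_minus))),
    movement_type = movement,
    clinician_label = rep(c("clin_plus", "clin_minus"),
                          c(length(p_plus), length(p_minus))),
    percentile = c(p_plus, p_minus),
    stringsAsFactors = FALSE)
}

# Minimal keypoint table: landmarks move along given x/y matrices.
make_track <- function(x, y, likelihood = NULL, frame_rate = 60) {
  if (is.null(likelihood))
    likelihood <- matrix(1, nrow(x), ncol(x), dimnames = dimnames(x))
  keypoint_table(x, y, likelihood, frame_rate)
}

# Shared small session config for synthetic tests (short epochs keep the
# suite fast; the generator's clinical defaults are exercised separately).
test_config <- function(...) {
  args <- list(epoch_duration_s = 5, seed = 20260920)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(session_config, args)
}
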