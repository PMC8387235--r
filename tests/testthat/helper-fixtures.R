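# Shared fixtures and independent oracles used across the suite.

# Homogeneous Poisson spike train on [0, t_total) at rate hz.
poisson_train <- function(hz, t_total, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, hz * t_total)
  sort(runif(n, 0, t_total))
}

# Regularly spaced non-overlapping events.
regular_events <- function(n, dur_s, gap_s, t0 = 30) {
  starts <- t0 + (seq_len(n) - 1) * (dur_s + gap_s)
  tibble::tibble(t_start_s = starts, t_end_s = starts + dur_s)
}

# Independent two-sided Fisher oracle: full hypergeometric enumeration with
# the point-probability rule (probabilities <= observed, with the same
# relative tolerance convention as fisher.test).
fisher_two_sided_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Straight-line trajectory through given way-points at a fixed sample rate.
line_trajectory <- function(xs, ys, t_end, fs = 5) {
  tt <- seq(0, t_end, by = 1 / fs)
  frac <- tt / t_end
  tibble::tibble(
    t_s = tt,
    x_cm = approx(seq(0, 1, length.out = length(xs)), xs, xout = frac)$y,
    y_cm = approx(seq(0, 1, length.out = length(ys)), ys, xout = frac)$y
  )
}

# Fraction of true intervals overlapped by at least one detected interval.
interval_sensitivity <- function(truth, detected) {
  if (nrow(truth) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(detected$t_start_s < truth$t_end_s[i] &
          detected$t_end_s > truth$t_start_s[i])
  }, logical(1))
  mean(hit)
}
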