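#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test. The two-sided p value uses the
#' point-probability rule (sum of all tables with the observed margins whose
#' probability does not exceed that of the observed table), the most common
#' convention. A table with an empty margin carries no information and
#' returns p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (refers to the
#'   \[1,1\] cell).
#' @return The p value.
#' @export
#' @examples
#' fisher_exact(matrix(c(7, 2, 2, 8), 2, byrow = TRUE))
fisher_exact <- function(table, alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    abort("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table, alternative = alternative)$p.value
}

#' One-sided test of a non-zero activated fraction
#'
#' Tests whether observing `k` activated units out of `n` is compatible
#' with a null population in which zero units are activated, via a
#' one-sided Fisher's exact test on the table \[\[k, n-k\], \[0, n\]\]
#' (observed population against an equal-sized all-null reference). The
#' construction is isolated here so alternative null constructions can be
#' swapped in.
#'
#' @param k Number of activated units.
#' @param n Total units.
#' @return Tibble `k`, `n`, `p_one_sided`.
#' @export
#' @examples
#' fraction_activated_test(9, 21)
fraction_activated_test <- function(k, n) {
  if (n <= 0) abort("n must be positive")
  if (k < 0 || k > n) abort("k must lie in [0, n]")
  p <- fisher_exact(matrix(c(k, n - k, 0, n), 2, 2, byrow = TRUE),
                    alternative = "greater")
  tibble(k = k, n = n, p_one_sided = p)
}

# Constrained MLE of p2 under H0: p1 = rho * p2 (profile for the score test).
koopman_p2_tilde <- function(rho, x1, n1, x2, n2) {
  a <- rho * (n1 + n2)
  b <- -(rho * n1 + x1 + n2 + rho * x2)
  cc <- x1 + x2
  (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# Koopman asymptotic score statistic for H0: p1/p2 = rho (chi-square, 1 df).
koopman_score_stat <- function(rho, x1, n1, x2, n2) {
  p2t <- koopman_p2_tilde(rho, x1, n1, x2, n2)
  p1t <- rho * p2t
  p1h <- x1 / n1
  p2h <- x2 / n2
  v <- p1t * (1 - p1t) / n1 + rho^2 * p2t * (1 - p2t) / n2
  if (v <= 0) return(Inf)
  (p1h - rho * p2h)^2 / v
}

#' Koopman asymptotic score confidence interval for a relative risk
#'
#' Confidence limits for the ratio of two binomial proportions
#' `rho = p1 / p2` as the roots in `rho` of the asymptotic score statistic
#' equalling the chi-square(1) critical value, with the constrained MLE of
#' the proportions under `p1 = rho * p2` in closed form. Roots are located
#' by bisection on `log(rho)` to a tolerance of 1e-8. When `x2 = 0` the
#' upper limit is unbounded (`Inf`); when both counts are zero the interval
#' is undefined.
#'
#' @param x1,n1 Successes and size in the numerator group.
#' @param x2,n2 Successes and size in the denominator group.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble `estimate` (`x1/n1 / (x2/n2)`), `lo`, `hi`,
#'   `conf_level`.
#' @export
#' @examples
#' koopman_ci(9, 21, 35, 541)
koopman_ci <- function(x1, n1, x2, n2, conf_level = 0.95) {
  if (n1 <= 0 || n2 <= 0) abort("group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) abort("counts out of range")
  if (x1 == 0 && x2 == 0) {
    warn("interval undefined: both groups have zero events")
    return(tibble(estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                  conf_level = conf_level))
  }
  crit <- qchisq(conf_level, df = 1)
  est <- if (x2 > 0) (x1 / n1) / (x2 / n2) else Inf
  f <- function(log_rho) koopman_score_stat(exp(log_rho), x1, n1, x2, n2) -
    crit

  # an interior point where the statistic is below the critical value
  mid <- if (is.finite(est) && est > 0) log(est) else
    log(max(1e-6, (x1 + 0.5) / n1) / max(1e-6, (x2 + 0.5) / n2))

  bisect <- function(lo, hi, increasing) {
    # f(lo) and f(hi) must bracket 0
    for (i in 1:200) {
      m <- (lo + hi) / 2
      if (hi - lo < 1e-10) break
      fm <- f(m)
      pos <- fm > 0
      if (pos == increasing) hi <- m else lo <- m
    }
    exp((lo + hi) / 2)
  }

  # lower endpoint: statistic decreases towards mid
  lo <- if (x1 == 0) 0 else {
    a <- mid
    while (f(a) < 0 && a > mid - 60) a <- a - 2
    if (f(a) < 0) 0 else bisect(a, mid, increasing = FALSE)
  }
  hi <- if (x2 == 0) Inf else {
    b <- mid
    while (f(b) < 0 && b < mid + 60) b <- b + 2
    if (f(b) < 0) Inf else bisect(mid, b, increasing = TRUE)
  }
  tibble(estimate = est, lo = lo, hi = hi, conf_level = conf_level)
}

#' Compare activated fractions between two unit populations
#'
#' Bundles the two-sided Fisher exact test on the 2x2 activation table, the
#' relative risk `(k1/n1) / (k2/n2)` as effect size, and its Koopman
#' asymptotic score confidence interval.
#'
#' @param k1,n1 Activated count and size of the first population (e.g.
#'   OT-PVN units).
#' @param k2,n2 Activated count and size of the second population (e.g. all
#'   PVN units).
#' @param conf_level Confidence level for the CI.
#' @return An `activation_comparison` object (see [tidy.activation_comparison()]).
#' @export
#' @examples
#' compare_activation(9, 21, 35, 541)
compare_activation <- function(k1, n1, k2, n2, conf_level = 0.95) {
  p <- fisher_exact(matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2, byrow = TRUE))
  ci <- koopman_ci(k1, n1, k2, n2, conf_level)
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                 p_two_sided = p, rr = ci$estimate,
                 ci = ci, conf_level = conf_level),
            class = "activation_comparison")
}

#' @export
print.activation_comparison <- function(x, ...) {
  cat(sprintf("<activation_comparison> %d/%d vs %d/%d\n",
              x$k1, x$n1, x$k2, x$n2))
  cat(sprintf("  RR = %.3g [%.3g, %.3g] (%g%% Koopman score CI), Fisher p = %.3g\n",
              x$rr, x$ci$lo, x$ci$hi, 100 * x$conf_level, x$p_two_sided))
  invisible(x)
}

#' @rdname compare_activation
#' @param x An `activation_comparison` object.
#' @param ... Unused.
#' @export
tidy.activation_comparison <- function(x, ...) {
  tibble(k1 = x$k1, n1 = x$n1, k2 = x$k2, n2 = x$n2,
         relative_risk = x$rr, conf_low = x$ci$lo, conf_high = x$ci$hi,
         p_value = x$p_two_sided)
}

#' @rdname compare_activation
#' @export
glance.activation_comparison <- function(x, ...) {
  tibble(relative_risk = x$rr, p_value = x$p_two_sided,
         conf_level = x$conf_level)
}

#' Log-rank comparison of retrieval-onset curves
#'
#' Standard two-group (or k-group) log-rank (Mantel-Cox) test over discrete
#' onset days with right censoring, with ties handled by the discrete-day
#' hypergeometric formulation. Delegates to [survival::survdiff()].
#'
#' @param onsets Tibble `day` (onset day, or last observed day if
#'   censored), `event` (TRUE when onset observed), `group`.
#' @return An `onset_logrank` object with `chi2`, `df`, `p` and the fitted
#'   `survdiff` object.
#' @export
#' @examples
#' d <- tibble::tibble(day = c(1, 2, 2, 3, 4, 4),
#'                     event = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
#'                     group = rep(c("a", "b"), each = 3))
#' logrank_onset(d)
logrank_onset <- function(onsets) {
  stopifnot(all(c("day", "event", "group") %in% names(onsets)))
  if (any(onsets$day <= 0)) abort("days must be positive")
  if (!any(onsets$event)) {
    warn("no events in pooled data: p undefined")
    return(structure(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                          fit = NULL), class = "onset_logrank"))
  }
  fit <- survival::survdiff(
    survival::Surv(day, event) ~ group,
    data = as.data.frame(onsets))
  df <- length(fit$n) - 1
  structure(list(chi2 = unname(fit$chisq), df = df,
                 p = pchisq(fit$chisq, df, lower.tail = FALSE),
                 fit = fit),
            class = "onset_logrank")
}

#' @export
print.onset_logrank <- function(x, ...) {
  cat(sprintf("<onset_logrank> chi2 = %.4g (df %d), p = %.3g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' @rdname logrank_onset
#' @param x An `onset_logrank` object.
#' @param ... Unused.
#' @export
tidy.onset_logrank <- function(x, ...) {
  if (is.null(x$fit))
    return(tibble(group = character(), n = integer(), observed = double(),
                  expected = double()))
  tibble(group = sub("^group=", "", names(x$fit$n)),
         n = as.integer(x$fit$n),
         observed = as.double(x$fit$obs),
         expected = as.double(x$fit$exp))
}

#' @rdname logrank_onset
#' @export
glance.onset_logrank <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p_value = x$p)
}

#' Chronic oral dose rate
#'
#' Dose received from drug delivered in drinking water:
#' `concentration * intake / mass`, in mg/kg/day. With CNO at 25 mg/l, a
#' ~6 ml daily water intake and a ~30 g mouse this is ~5 mg/kg/day.
#'
#' @param concentration_mg_per_l Drug concentration in the water (mg/l).
#' @param intake_l_per_day Daily water intake (l/day).
#' @param mass_kg Body mass (kg).
#' @return Dose in mg/kg/day.
#' @export
#' @examples
#' chronic_dose_rate(25, 0.006, 0.030)  # 5
chronic_dose_rate <- function(concentration_mg_per_l, intake_l_per_day,
                              mass_kg) {
  if (any(mass_kg <= 0)) abort("mass must be positive")
  if (any(concentration_mg_per_l < 0) || any(intake_l_per_day < 0))
    abort("concentration and intake must be non-negative")
  concentration_mg_per_l * intake_l_per_day / mass_kg
}
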