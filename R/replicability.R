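# Replication-rate statistics, null expectations, binomial tests,
# effective replicability, heterogeneity, direction consistency and
# publication-bias bounds.

#' Observed replication rate
#'
#' @param n_success number of successful replication attempts.
#' @param n_attempts total number of attempts (> 0).
#' @return the exact ratio \code{n_success / n_attempts}.
#' @export
replication_rate <- function(n_success, n_attempts) {
  if (any(n_attempts <= 0)) stop("'n_attempts' must be > 0", call. = FALSE)
  if (any(n_success < 0 | n_success > n_attempts)) {
    stop("'n_success' must lie in [0, n_attempts]", call. = FALSE)
  }
  n_success / n_attempts
}

#' Expected positive replications under the no-association null
#'
#' Convention \code{"alpha"} (the default) counts any significant result as
#' a false-positive replication and returns \code{n * alpha}; convention
#' \code{"alpha_half"} additionally requires the same risk-allele direction
#' (probability 1/2 under the null) and returns \code{n * alpha / 2}.
#'
#' @param n_attempts number of attempts.
#' @param alpha significance threshold.
#' @param convention \code{"alpha"} or \code{"alpha_half"}.
#' @return expected null count (real).
#' @export
expected_null_count <- function(n_attempts, alpha,
                                convention = c("alpha", "alpha_half")) {
  convention <- match.arg(convention)
  check_fraction(alpha, "alpha")
  if (any(n_attempts < 0)) stop("'n_attempts' must be >= 0", call. = FALSE)
  n_attempts * alpha / (if (convention == "alpha_half") 2 else 1)
}

#' One-sided binomial test against the null replication rate
#'
#' Exact upper-tail binomial p-value \eqn{P[X \ge k]} for observing
#' \code{n_success} or more successes in \code{n_attempts} attempts when
#' each succeeds with probability \code{alpha} under the null hypothesis of
#' no shared associations.
#'
#' @inheritParams replication_rate
#' @param alpha null success probability.
#' @return p-value.
#' @export
binomial_null_test <- function(n_success, n_attempts, alpha) {
  check_fraction(alpha, "alpha")
  stats::pbinom(n_success - 1, n_attempts, alpha, lower.tail = FALSE)
}

#' Effective replicability rate
#'
#' Observed positive replications divided by the power-expected number:
#' the replication rate after correcting for the statistical power of the
#' attempts. Values above 1 are allowed (sampling noise) and flagged via
#' the \code{"above_one"} attribute.
#'
#' @param n_success observed positive replications.
#' @param expected_power power-expected number of replications (> 0),
#'   e.g. \code{expected_replications(...)$expected}.
#' @return the ratio, with attribute \code{above_one}.
#' @export
effective_replicability <- function(n_success, expected_power) {
  if (any(expected_power <= 0)) {
    stop("'expected_power' must be > 0", call. = FALSE)
  }
  out <- n_success / expected_power
  attr(out, "above_one") <- out > 1
  out
}

#' Risk-allele direction consistency test
#'
#' Proportion of attempts observing the same risk allele as the discovery
#' study, with a two-sided exact binomial test against the 50% expected
#' under independent (population-specific) causal variants.
#'
#' @param n_same_direction attempts with the same risk allele.
#' @param n_attempts total attempts.
#' @return list with \code{proportion} and \code{p_value}.
#' @export
direction_consistency_test <- function(n_same_direction, n_attempts) {
  if (n_attempts <= 0 || n_same_direction < 0 || n_same_direction > n_attempts) {
    stop("invalid counts", call. = FALSE)
  }
  list(proportion = n_same_direction / n_attempts,
       p_value = stats::binom.test(n_same_direction, n_attempts,
                                   p = 0.5)$p.value)
}

#' Heterogeneity of replicability across diseases
#'
#' Chi-square test of homogeneity on the diseases x (success, failure)
#' table. When any expected cell is below 5 the p-value is computed by
#' Monte-Carlo resampling (\code{B} resamples). Diseases with zero attempts
#' are dropped with a message.
#'
#' @param per_disease data.frame with columns \code{disease},
#'   \code{n_success}, \code{n_attempts}.
#' @param B Monte-Carlo resamples when expected cells are sparse.
#' @return list with \code{statistic}, \code{p_value}, \code{method},
#'   \code{dropped} (diseases removed).
#' @export
disease_heterogeneity_test <- function(per_disease, B = 10000) {
  stopifnot(all(c("disease", "n_success", "n_attempts") %in% names(per_disease)))
  zero <- per_disease$n_attempts == 0
  dropped <- per_disease$disease[zero]
  if (any(zero)) {
    message("dropping ", sum(zero), " disease(s) with zero attempts: ",
            paste(dropped, collapse = ", "))
    per_disease <- per_disease[!zero, , drop = FALSE]
  }
  if (nrow(per_disease) < 2) {
    stop("need at least two diseases with attempts", call. = FALSE)
  }
  tab <- cbind(success = per_disease$n_success,
               failure = per_disease$n_attempts - per_disease$n_success)
  rownames(tab) <- per_disease$disease
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ct <- stats::chisq.test(tab, simulate.p.value = TRUE, B = B)
    method <- sprintf("chi-square homogeneity, Monte-Carlo p (B=%d)", B)
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    method <- "chi-square homogeneity"
  }
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       method = method, dropped = dropped)
}

#' Publication-bias bounding arithmetic
#'
#' Bounds the impact of selective reporting of replication attempts.
#' In the extreme scenario where all \code{observed} positive replications
#' are type I errors, they represent a fraction
#' \code{alpha * p_same_dir} (significance times the null probability of
#' drawing the same risk allele) of a large pool of attempts:
#' \code{implied_pool = observed / (alpha * p_same_dir)}, with an exact
#' (Garwood, chi-square quantile) Poisson confidence interval on the count
#' scaled by the same factor. \code{implied_unreported} is the pool minus
#' the observed positives. Conversely, assuming every plausibly unreported
#' attempt (\code{n_unreported_max}) was a failed replication gives the
#' lower-bound replicability rate
#' \code{observed / (n_gathered + n_unreported_max)}.
#'
#' @param observed number of observed positive replications.
#' @param alpha significance threshold.
#' @param p_same_dir null probability of observing the same risk allele
#'   (0.5 by default).
#' @param n_gathered replication attempts actually gathered.
#' @param n_unreported_max maximum number of unreported attempts.
#' @param conf confidence level for the Poisson interval.
#' @param ci_method \code{"exact"} (Garwood) or \code{"normal"}
#'   approximation.
#' @return object of class \code{bias_bound}: list with \code{observed},
#'   \code{implied_pool}, \code{implied_unreported}, \code{pool_ci_low},
#'   \code{pool_ci_high}, \code{lower_bound_rate} and the inputs.
#' @export
publication_bias_bounds <- function(observed, alpha = 0.05, p_same_dir = 0.5,
                                    n_gathered, n_unreported_max,
                                    conf = 0.95,
                                    ci_method = c("exact", "normal")) {
  ci_method <- match.arg(ci_method)
  if (observed < 0) stop("'observed' must be >= 0", call. = FALSE)
  rate0 <- alpha * p_same_dir
  if (rate0 <= 0) stop("alpha * p_same_dir must be > 0", call. = FALSE)
  implied_pool <- observed / rate0
  lo_a <- (1 - conf) / 2
  if (ci_method == "exact") {
    count_lo <- if (observed == 0) 0 else stats::qchisq(lo_a, 2 * observed) / 2
    count_hi <- stats::qchisq(1 - lo_a, 2 * (observed + 1)) / 2
  } else {
    z <- stats::qnorm(1 - lo_a)
    count_lo <- max(0, observed - z * sqrt(observed))
    count_hi <- observed + z * sqrt(observed)
  }
  structure(list(
    observed = observed, alpha = alpha, p_same_dir = p_same_dir,
    implied_pool = implied_pool,
    implied_unreported = implied_pool - observed,
    pool_ci_low = count_lo / rate0, pool_ci_high = count_hi / rate0,
    n_gathered = n_gathered, n_unreported_max = n_unreported_max,
    lower_bound_rate = observed / (n_gathered + n_unreported_max),
    conf = conf, ci_method = ci_method), class = "bias_bound")
}

#' @export
print.bias_bound <- function(x, ...) {
  cat(sprintf("Publication-bias bound (alpha=%g, P[same direction]=%g)\n",
              x$alpha, x$p_same_dir))
  cat(sprintf("  observed positives: %d\n", x$observed))
  cat(sprintf("  implied pool if all were false positives: %s (%.0f%% CI %s-%s, %s)\n",
              format(round_half_up(x$implied_pool)), 100 * x$conf,
              format(round_half_up(x$pool_ci_low)),
              format(round_half_up(x$pool_ci_high)), x$ci_method))
  cat(sprintf("  implied unreported attempts: %s\n",
              format(round_half_up(x$implied_unreported))))
  cat(sprintf("  lower-bound replicability: %.1f%% (%d out of %d)\n",
              round_half_up(100 * x$lower_bound_rate, 1), x$observed,
              x$n_gathered + x$n_unreported_max))
  invisible(x)
}

#' Replicability summary for a set of attempts
#'
#' Convenience wrapper combining the observed rate, the null expectation,
#' the exact binomial null test and (when the power-expected count is
#' supplied) the effective replicability rate.
#'
#' @inheritParams replication_rate
#' @param alpha replication significance threshold.
#' @param expected_power optional power-expected number of replications.
#' @param null_convention passed to \code{\link{expected_null_count}}.
#' @return object of class \code{replicability_summary}.
#' @export
replicability_summary <- function(n_success, n_attempts, alpha = 0.05,
                                  expected_power = NULL,
                                  null_convention = "alpha") {
  out <- list(
    n_attempts = n_attempts, n_success = n_success, alpha = alpha,
    rate = replication_rate(n_success, n_attempts),
    expected_null = expected_null_count(n_attempts, alpha, null_convention),
    p_binomial = binomial_null_test(n_success, n_attempts, alpha),
    expected_power = expected_power,
    effective_rate = if (!is.null(expected_power))
      as.numeric(effective_replicability(n_success, expected_power)) else NA_real_)
  structure(out, class = "replicability_summary")
}

#' @export
print.replicability_summary <- function(x, ...) {
  cat(sprintf("Replicability: %d/%d = %.1f%% at alpha=%g\n",
              x$n_success, x$n_attempts, round_half_up(100 * x$rate, 1),
              x$alpha))
  cat(sprintf("  null expectation: %s positives (binomial P %s)\n",
              format(round_half_up(x$expected_null, 1)),
              format.pval(x$p_binomial, digits = 3)))
  if (!is.null(x$expected_power) && !is.na(x$effective_rate)) {
    cat(sprintf("  power-expected: %.1f -> effective replicability %.1f%%%s\n",
                x$expected_power,
                round_half_up(100 * x$effective_rate, 1),
                if (x$effective_rate > 1) " (above 1, flagged)" else ""))
  }
  invisible(x)
}
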