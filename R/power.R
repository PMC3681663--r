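# Replication power for a case-control allelic test under a log-additive
# (per-allele odds ratio) model.

#' Analytic replication power for a case-control allelic test
#'
#' Probability that a replication study of given size declares the same risk
#' allele significant. Under a log-additive model with per-allele odds ratio
#' \eqn{\psi} and risk-allele frequency \eqn{p_0} in the replication
#' population (controls), the case risk-allele frequency is
#' \deqn{p_1 = \psi p_0 / (1 + p_0(\psi - 1)),}
#' and the allelic test is a two-proportion z-test on allele counts
#' (\eqn{2n} alleles per group). With
#' \eqn{SE = \sqrt{p_1(1-p_1)/(2 n_{cases}) + p_0(1-p_0)/(2 n_{controls})}}
#' and non-centrality \eqn{ncp = (p_1 - p_0)/SE}, same-direction power at
#' two-sided level \eqn{\alpha} is
#' \deqn{\Phi(|ncp| - z_{1-\alpha/2}),}
#' i.e. the probability that the test is significant \emph{and} the
#' estimated effect carries the sign of \eqn{\log\psi}. At \eqn{\psi = 1}
#' this is exactly \eqn{\alpha/2}. Disease prevalence is ignored (the
#' control frequency is taken as the population frequency), the standard
#' low-prevalence approximation.
#'
#' @param or_true per-allele odds ratio \eqn{\psi > 0}, referenced to the
#'   discovery risk allele.
#' @param raf risk-allele frequency in the replication population,
#'   strictly inside (0, 1).
#' @param n_cases,n_controls numbers of cases and controls.
#' @param alpha two-sided significance level.
#' @param direction \code{"same"} counts only significance in the discovery
#'   direction (the replication-success criterion); \code{"any"} adds the
#'   opposite-direction tail \eqn{\Phi(-|ncp| - z_{1-\alpha/2})}.
#' @return power in [0, 1], vectorised over the inputs.
#' @export
replication_power <- function(or_true, raf, n_cases, n_controls,
                              alpha = 0.05, direction = c("same", "any")) {
  direction <- match.arg(direction)
  if (any(!is.finite(or_true) | or_true <= 0)) {
    stop("'or_true' must be > 0", call. = FALSE)
  }
  if (any(!is.finite(raf) | raf <= 0 | raf >= 1)) {
    stop("'raf' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(n_cases) | n_cases <= 0) ||
      any(!is.finite(n_controls) | n_controls <= 0)) {
    stop("'n_cases'/'n_controls' must be positive", call. = FALSE)
  }
  check_fraction(alpha, "alpha")
  p0 <- raf
  p1 <- or_true * p0 / (1 + p0 * (or_true - 1))
  se <- sqrt(p1 * (1 - p1) / (2 * n_cases) + p0 * (1 - p0) / (2 * n_controls))
  ncp <- (p1 - p0) / se
  zc <- stats::qnorm(1 - alpha / 2)
  pow <- stats::pnorm(abs(ncp) - zc)
  if (direction == "any") pow <- pow + stats::pnorm(-abs(ncp) - zc)
  pow
}

#' Non-centrality of the replication allelic test
#'
#' The mean of the replication z-statistic under the alternative; shared
#' between \code{\link{replication_power}} and the database simulator so
#' that analytic and simulated power agree by construction.
#'
#' @inheritParams replication_power
#' @return non-centrality parameter (signed).
#' @export
replication_ncp <- function(or_true, raf, n_cases, n_controls) {
  p0 <- raf
  p1 <- or_true * p0 / (1 + p0 * (or_true - 1))
  se <- sqrt(p1 * (1 - p1) / (2 * n_cases) + p0 * (1 - p0) / (2 * n_controls))
  (p1 - p0) / se
}

#' Power-expected number of positive replications
#'
#' Fills the per-attempt \code{power} column (if absent) and returns the
#' expected number of positive replications: the sum of per-attempt powers,
#' equivalently the number of attempts times the average power.
#'
#' @param attempts attempts data.frame. If \code{power} is missing or
#'   incomplete it is computed from \code{or_discovery} (joined from
#'   \code{associations} when not already a column),
#'   \code{raf_replication_pop}, \code{n_cases}, \code{n_controls}.
#' @param associations optional associations data.frame supplying
#'   \code{or_discovery} by \code{snp_id}.
#' @param alpha significance level used for the power calculation.
#' @param direction passed to \code{\link{replication_power}}.
#' @return list with \code{expected} (sum of powers), \code{mean_power},
#'   \code{n} and \code{attempts} (with \code{power} filled).
#' @export
expected_replications <- function(attempts, associations = NULL,
                                  alpha = 0.05, direction = "same") {
  if (nrow(attempts) == 0) {
    return(list(expected = 0, mean_power = NA_real_, n = 0L,
                attempts = attempts))
  }
  if (is.null(attempts$power) || anyNA(attempts$power)) {
    or_d <- attempts$or_discovery
    if (is.null(or_d)) {
      if (is.null(associations)) {
        stop("no 'power' column and no way to compute it: supply ",
             "'associations' (for or_discovery) or a pre-filled power column",
             call. = FALSE)
      }
      or_d <- associations$or_discovery[match(attempts$snp_id,
                                              associations$snp_id)]
    }
    attempts$power <- replication_power(or_d, attempts$raf_replication_pop,
                                        attempts$n_cases, attempts$n_controls,
                                        alpha = alpha, direction = direction)
  }
  list(expected = sum(attempts$power), mean_power = mean(attempts$power),
       n = nrow(attempts), attempts = attempts)
}
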