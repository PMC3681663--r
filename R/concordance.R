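# Cross-ancestry effect-size concordance: Spearman correlation and OLS of
# log(OR), windowed replicability profiles and small-vs-large discovery
# stratification.

spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant ranks: Spearman correlation undefined", call. = FALSE)
  }
  stats::cor(rx, ry)
}

spearman_p <- function(x, y, rho) {
  n <- length(x)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    # exact permutation null distribution of the rank statistic
    suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                     exact = TRUE)$p.value)
  } else {
    if (abs(rho) >= 1) return(0)
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
}

#' Concordance of effect sizes across ancestries
#'
#' Spearman rank correlation (average-rank ties method) and ordinary
#' least-squares regression of the replication log(OR) on the discovery
#' log(OR). Both log-ORs must be referenced to the discovery risk allele.
#' Spearman p-values use the exact permutation distribution for n <= 10
#' without ties and a t-approximation otherwise; the regression fits an
#' intercept and reports the slope.
#'
#' @param pairs data.frame with columns \code{log_or_discovery},
#'   \code{log_or_replication} and, when subsetting, \code{success}.
#' @param subset \code{"all"} or \code{"nonsignificant_only"}
#'   (attempts that failed to replicate).
#' @return list with \code{n}, \code{rho}, \code{rho_p}, \code{slope},
#'   \code{slope_se}, \code{slope_p}, \code{intercept}.
#' @export
concordance_stats <- function(pairs, subset = c("all", "nonsignificant_only")) {
  subset <- match.arg(subset)
  if (subset == "nonsignificant_only") {
    if (is.null(pairs$success)) stop("'success' column required", call. = FALSE)
    pairs <- pairs[!pairs$success, , drop = FALSE]
  }
  keep <- is.finite(pairs$log_or_discovery) & is.finite(pairs$log_or_replication)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  x <- pairs$log_or_discovery
  y <- pairs$log_or_replication
  rho <- spearman_rho(x, y)
  fit <- stats::lm(y ~ x)
  # exact fits trigger a harmless "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))$coefficients
  list(n = nrow(pairs), rho = rho, rho_p = spearman_p(x, y, rho),
       slope = unname(sm["x", "Estimate"]),
       slope_se = unname(sm["x", "Std. Error"]),
       slope_p = unname(sm["x", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]))
}

#' Windowed replicability profile along OR or MAF
#'
#' Classifies replication attempts into sliding windows along the discovery
#' odds ratio (transformed as \code{max(OR, 1/OR)} so risk alleles always
#' read OR > 1) or the replication-population minor allele frequency, and
#' reports per window the mean power, the observed replication rate and the
#' effective replicability (observed / mean power). Windows with fewer than
#' \code{min_attempts} attempts are suppressed.
#'
#' @param attempts data.frame with \code{power}, \code{success} and either
#'   \code{or_discovery} (axis \code{"OR"}) or \code{raf_replication_pop}
#'   (axis \code{"MAF"}, folded to the minor allele).
#' @param axis \code{"OR"} or \code{"MAF"}.
#' @param width,step window width and step on the axis.
#' @param min_attempts minimum attempts for a window to be emitted.
#' @return data.frame with one row per emitted window: \code{axis},
#'   \code{center}, \code{width}, \code{n_attempts}, \code{mean_power},
#'   \code{observed_rate}, \code{effective_rate}.
#' @export
windowed_replicability_profile <- function(attempts, axis = c("OR", "MAF"),
                                           width = 0.3, step = 0.05,
                                           min_attempts = 20) {
  axis <- match.arg(axis)
  if (width <= 0) stop("'width' must be > 0", call. = FALSE)
  if (step <= 0) stop("'step' must be > 0", call. = FALSE)
  if (is.null(attempts$power) || anyNA(attempts$power)) {
    stop("attempts must carry a filled 'power' column", call. = FALSE)
  }
  value <- if (axis == "OR") {
    v <- attempts$or_discovery
    if (is.null(v)) stop("axis 'OR' needs column 'or_discovery'", call. = FALSE)
    pmax(v, 1 / v)
  } else {
    v <- attempts$raf_replication_pop
    if (is.null(v)) stop("axis 'MAF' needs column 'raf_replication_pop'",
                         call. = FALSE)
    pmin(v, 1 - v)
  }
  centers <- seq(min(value), max(value) + step / 2, by = step)
  rows <- lapply(centers, function(cc) {
    inw <- value >= cc - width / 2 & value < cc + width / 2
    n <- sum(inw)
    if (n < min_attempts) return(NULL)
    mp <- mean(attempts$power[inw])
    obs <- mean(attempts$success[inw])
    data.frame(axis = axis, center = cc, width = width, n_attempts = n,
               mean_power = mp, observed_rate = obs,
               effective_rate = obs / mp)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(axis = character(), center = numeric(),
                      width = numeric(), n_attempts = integer(),
                      mean_power = numeric(), observed_rate = numeric(),
                      effective_rate = numeric())
  }
  out
}

#' Compare small and large discovery studies
#'
#' Splits attempts by the total sample size of the discovery study at
#' \code{n_threshold} (default 10,000 individuals) and compares the MAF and
#' transformed OR (\code{max(OR, 1/OR)}) distributions between the strata
#' with two-sided Mann-Whitney (Wilcoxon rank-sum) tests, plus effect-size
#' concordance within each stratum.
#'
#' @param pairs data.frame with \code{discovery_n_total}, \code{maf},
#'   \code{or_discovery}, \code{log_or_discovery}, \code{log_or_replication}
#'   (and optionally \code{success}).
#' @param n_threshold discovery sample-size threshold separating
#'   \code{"small"} from \code{"large"} studies.
#' @return list with \code{n} (per-stratum counts), \code{maf_test},
#'   \code{or_test} (each: means plus Wilcoxon p) and \code{concordance}
#'   per stratum (\code{NULL}, with a message, for strata of < 3 pairs).
#' @export
stratified_comparison <- function(pairs, n_threshold = 10000) {
  if (is.null(pairs$discovery_n_total)) {
    stop("'discovery_n_total' column required", call. = FALSE)
  }
  stratum <- ifelse(pairs$discovery_n_total >= n_threshold, "large", "small")
  or_t <- pmax(pairs$or_discovery, 1 / pairs$or_discovery)
  wil <- function(v) {
    suppressWarnings(stats::wilcox.test(v[stratum == "small"],
                                        v[stratum == "large"])$p.value)
  }
  gmean <- function(v) c(small = mean(v[stratum == "small"]),
                         large = mean(v[stratum == "large"]))
  conc <- lapply(c(small = "small", large = "large"), function(s) {
    sub <- pairs[stratum == s, , drop = FALSE]
    if (nrow(sub) < 3) {
      message("stratum '", s, "': fewer than 3 pairs, concordance skipped")
      return(NULL)
    }
    concordance_stats(sub)
  })
  list(n = table(stratum),
       maf_test = list(mean = gmean(pairs$maf), p_value = wil(pairs$maf)),
       or_test = list(mean = gmean(or_t), p_value = wil(or_t)),
       concordance = conc)
}
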