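# varLD-style comparison of LD patterns between two populations: signed-r2
# matrices, eigenvalue-difference raw scores, sliding-window scans,
# permutation p-values, MAF-matched genomic backgrounds and per-offset
# group comparisons.

#' Signed r-squared LD matrix for a SNP window
#'
#' Pairwise linkage disequilibrium among SNPs: Pearson correlation r of the
#' phased haplotype allele indicators, reported as \eqn{sign(r) r^2}. The
#' diagonal is 1. SNPs monomorphic in the window get zero off-diagonal
#' entries and are flagged in the \code{"monomorphic"} attribute; SNPs with
#' all alleles missing are an error.
#'
#' @param panel a \code{\link{hap_panel}} or haplotype matrix
#'   (haplotypes x SNPs).
#' @param snp_range integer indices of the SNP window (default: all SNPs).
#' @return symmetric matrix with attribute \code{monomorphic} (indices
#'   within the window).
#' @export
signed_r2_matrix <- function(panel, snp_range = NULL) {
  m <- if (inherits(panel, "hap_panel")) panel$alleles else as.matrix(panel)
  if (!is.null(snp_range)) m <- m[, snp_range, drop = FALSE]
  if (ncol(m) < 2) stop("need at least 2 SNPs", call. = FALSE)
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    nm <- colnames(m)[all_missing] %||% paste0("snp", which(all_missing))
    stop("SNP(s) with all alleles missing: ",
         paste(utils::head(nm, 5), collapse = ", "), call. = FALSE)
  }
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  mono <- which(sds == 0)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  s <- sign(r) * r^2
  if (length(mono)) {
    s[mono, ] <- 0
    s[, mono] <- 0
  }
  diag(s) <- 1
  s <- (s + t(s)) / 2
  attr(s, "monomorphic") <- mono
  s
}

#' Raw varLD score between two LD matrices
#'
#' Summary of the difference in LD patterns between two populations over
#' the same SNP window: both signed-r2 matrices are eigen-decomposed, the
#' eigenvalues ranked in descending order, and the score is the sum of
#' absolute differences between the ranked eigenvalues. It is a
#' pseudometric: non-negative, symmetric and zero iff the spectra match.
#'
#' @param m1,m2 symmetric matrices of identical dimension.
#' @return non-negative raw score.
#' @export
varld_raw_score <- function(m1, m2) {
  if (!all(dim(m1) == dim(m2))) stop("dimension mismatch", call. = FALSE)
  e1 <- eigen(m1, symmetric = TRUE, only.values = TRUE)$values
  e2 <- eigen(m2, symmetric = TRUE, only.values = TRUE)$values
  sum(abs(e1 - e2))
}

window_bounds <- function(center, window) {
  half <- window %/% 2
  if (window %% 2 == 0) c(center - half + 1, center + half)
  else c(center - half, center + half)
}

resolve_focal <- function(panel, focal_snp) {
  if (is.numeric(focal_snp)) return(as.integer(focal_snp))
  idx <- match(focal_snp, panel$snp$snp_id)
  if (is.na(idx)) stop("focal SNP '", focal_snp, "' not in panel", call. = FALSE)
  idx
}

#' Sliding-window LD/heterozygosity divergence scan around a focal SNP
#'
#' Scores 50-SNP windows (by default) sliding in 5-SNP steps from
#' \code{span} SNPs upstream to \code{span} SNPs downstream of a focal SNP:
#' for each window the raw varLD score between the two populations and the
#' difference in average heterozygosity (population 1 minus population 2).
#' With the defaults (window 50, step 5, span 300) the scan evaluates 121
#' consecutive windows and needs 650 flanking SNPs; windows that would run
#' off the panel are dropped with a warning.
#'
#' @param panel1,panel2 \code{\link{hap_panel}} objects sharing a SNP map.
#' @param focal_snp SNP id or index of the focal (associated) SNP.
#' @param window number of SNPs per window.
#' @param step step between window centers, in SNPs.
#' @param span scan reach each side of the focal SNP, in SNPs.
#' @param n_perm if > 0, also compute a permutation empirical p-value per
#'   window (see \code{\link{permutation_pvalue}}).
#' @param seed optional seed for the permutations.
#' @return data.frame of class \code{window_scan}: \code{focal_snp},
#'   \code{offset} (window center minus focal index, SNPs),
#'   \code{window_snps}, \code{varld_raw}, \code{het_diff},
#'   \code{n_monomorphic}, \code{empirical_p}.
#' @export
sliding_window_scan <- function(panel1, panel2, focal_snp, window = 50,
                                step = 5, span = 300, n_perm = 0,
                                seed = NULL) {
  if (!identical(panel1$snp$snp_id, panel2$snp$snp_id)) {
    stop("panels must share the same SNP map", call. = FALSE)
  }
  focal <- resolve_focal(panel1, focal_snp)
  n_snp <- ncol(panel1$alleles)
  centers <- focal + seq(-span, span, by = step)
  ok <- vapply(centers, function(cc) {
    b <- window_bounds(cc, window)
    b[1] >= 1 && b[2] <= n_snp
  }, logical(1))
  if (!all(ok)) {
    warning(sprintf("scan truncated: %d of %d windows lack flanking SNPs",
                    sum(!ok), length(ok)))
    centers <- centers[ok]
  }
  het1 <- heterozygosity(panel1)
  het2 <- heterozygosity(panel2)
  focal_id <- panel1$snp$snp_id[focal]
  if (n_perm > 0 && !is.null(seed)) set.seed(seed)
  rows <- lapply(centers, function(cc) {
    b <- window_bounds(cc, window)
    idx <- b[1]:b[2]
    s1 <- signed_r2_matrix(panel1, idx)
    s2 <- signed_r2_matrix(panel2, idx)
    ep <- NA_real_
    if (n_perm > 0) {
      ep <- permutation_pvalue(panel1, panel2, idx, n_perm = n_perm)$p_value
    }
    data.frame(focal_snp = focal_id, offset = cc - focal,
               window_snps = window,
               varld_raw = varld_raw_score(s1, s2),
               het_diff = mean(het1[idx]) - mean(het2[idx]),
               n_monomorphic = length(attr(s1, "monomorphic")) +
                 length(attr(s2, "monomorphic")),
               empirical_p = ep)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_scan", class(out))
  out
}

#' Permutation empirical p-value for the LD difference in one window
#'
#' Tests the null hypothesis that the LD correlations among the window's
#' SNPs are equal in the two populations by relabelling diploid individuals
#' (both haplotypes move together) across populations, preserving sample
#' sizes, and recomputing the raw varLD score. The empirical p-value is
#' \eqn{(1 + \#\{perm \ge obs\}) / (n_{perm} + 1)}.
#'
#' @param panel1,panel2 \code{\link{hap_panel}} objects sharing a SNP map.
#' @param snp_range integer indices of the SNP window.
#' @param n_perm number of permutations.
#' @param seed optional seed.
#' @return list with \code{p_value}, \code{observed}, \code{n_perm},
#'   \code{perm_scores}.
#' @export
permutation_pvalue <- function(panel1, panel2, snp_range, n_perm = 1000,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- n_individuals(panel1)
  n2 <- n_individuals(panel2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 individuals per population", call. = FALSE)
  a1 <- panel1$alleles[, snp_range, drop = FALSE]
  a2 <- panel2$alleles[, snp_range, drop = FALSE]
  combined <- rbind(a1, a2)
  observed <- varld_raw_score(signed_r2_matrix(a1), signed_r2_matrix(a2))
  # haplotype row pairs per individual
  ind_rows <- function(ind) rbind(2 * ind - 1, 2 * ind)
  n_tot <- n1 + n2
  perm_scores <- vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(n_tot)
    r1 <- as.vector(ind_rows(perm[seq_len(n1)]))
    r2 <- as.vector(ind_rows(perm[n1 + seq_len(n2)]))
    varld_raw_score(signed_r2_matrix(combined[r1, , drop = FALSE]),
                    signed_r2_matrix(combined[r2, , drop = FALSE]))
  }, numeric(1))
  list(p_value = (1 + sum(perm_scores >= observed)) / (n_perm + 1),
       observed = observed, n_perm = n_perm, perm_scores = perm_scores)
}

#' MAF-matched random genomic background for window p-values
#'
#' Builds groups of random SNPs from a genome panel whose minor allele
#' frequencies (in population 1) match those of the focal SNPs within
#' \code{tol}, and computes the permutation empirical p-value of the
#' central window around each selected SNP. The across-group median and
#' 2.5\%/97.5\% envelope of the empirical cumulative distribution of
#' p-values provide the genome-wide expectation band.
#'
#' @param focal_mafs minor allele frequencies of the focal SNPs (each group
#'   slot is matched to one, cycling if \code{group_size} differs).
#' @param panel1,panel2 genome-scale \code{\link{hap_panel}} pair.
#' @param n_groups number of random groups.
#' @param group_size SNPs per group (sampled without replacement within a
#'   group).
#' @param tol MAF matching tolerance; when no candidate matches, the
#'   tolerance is widened to \code{tol_wide} with a warning, then errors.
#' @param tol_wide fallback tolerance.
#' @param window central window size in SNPs.
#' @param n_perm permutations per window.
#' @param seed optional seed.
#' @return list with \code{groups} (data.frame: \code{group}, \code{slot},
#'   \code{snp_index}, \code{maf}, \code{empirical_p}) and \code{envelope}
#'   (data.frame: \code{p}, \code{median}, \code{lo}, \code{hi} of the
#'   across-group ECDF at a p grid).
#' @export
maf_matched_background <- function(focal_mafs, panel1, panel2,
                                   n_groups = 100, group_size = 47,
                                   tol = 0.02, tol_wide = 0.05,
                                   window = 50, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- allele_freq(panel1)
  maf <- pmin(p, 1 - p)
  n_snp <- length(maf)
  half_lo <- window %/% 2
  eligible <- seq_len(n_snp)
  bounds_ok <- vapply(eligible, function(i) {
    b <- window_bounds(i, window)
    b[1] >= 1 && b[2] <= n_snp
  }, logical(1))
  eligible <- eligible[bounds_ok]
  rows <- vector("list", n_groups * group_size)
  k <- 0
  for (g in seq_len(n_groups)) {
    used <- integer()
    for (slot in seq_len(group_size)) {
      target <- focal_mafs[(slot - 1) %% length(focal_mafs) + 1]
      cand <- eligible[abs(maf[eligible] - target) <= tol]
      cand <- setdiff(cand, used)
      if (!length(cand)) {
        warning(sprintf(
          "group %d slot %d: no candidate within +/-%g of MAF %.3f; widening to +/-%g",
          g, slot, tol, target, tol_wide))
        cand <- setdiff(eligible[abs(maf[eligible] - target) <= tol_wide], used)
        if (!length(cand)) {
          stop(sprintf("no MAF-matched candidate for focal MAF %.3f", target),
               call. = FALSE)
        }
      }
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      used <- c(used, pick)
      b <- window_bounds(pick, window)
      ep <- permutation_pvalue(panel1, panel2, b[1]:b[2],
                               n_perm = n_perm)$p_value
      k <- k + 1
      rows[[k]] <- data.frame(group = g, slot = slot, snp_index = pick,
                              maf = maf[pick], empirical_p = ep)
    }
  }
  groups <- do.call(rbind, rows[seq_len(k)])
  grid <- seq(0, 1, by = 0.01)
  ecdfs <- vapply(split(groups$empirical_p, groups$group),
                  function(pv) stats::ecdf(pv)(grid),
                  numeric(length(grid)))
  envelope <- data.frame(
    p = grid,
    median = apply(ecdfs, 1, stats::median),
    lo = apply(ecdfs, 1, stats::quantile, probs = 0.025),
    hi = apply(ecdfs, 1, stats::quantile, probs = 0.975))
  list(groups = groups, envelope = envelope)
}

#' Per-offset comparison of window scores between two groups of regions
#'
#' For every window offset shared by the two groups, compares the
#' distributions of scores (raw varLD by default) with a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test, flagging offsets below the
#' significance band threshold.
#'
#' @param scores_a,scores_b \code{\link{sliding_window_scan}} outputs (or
#'   rbinds thereof across regions) for the two groups.
#' @param value column to compare (default \code{"varld_raw"};
#'   \code{"het_diff"} for heterozygosity differences).
#' @param p_flag per-offset significance threshold used for flagging.
#' @return data.frame: \code{offset}, \code{n_a}, \code{n_b},
#'   \code{median_a}, \code{median_b}, \code{statistic}, \code{p_value},
#'   \code{significant}.
#' @export
group_window_comparison <- function(scores_a, scores_b,
                                    value = "varld_raw", p_flag = 0.01) {
  if (!nrow(scores_a) || !nrow(scores_b)) stop("empty group", call. = FALSE)
  offsets <- sort(intersect(unique(scores_a$offset), unique(scores_b$offset)))
  rows <- lapply(offsets, function(off) {
    va <- scores_a[[value]][scores_a$offset == off]
    vb <- scores_b[[value]][scores_b$offset == off]
    if (length(va) < 3 || length(vb) < 3) {
      stop("need >= 3 scores per group per offset", call. = FALSE)
    }
    wt <- suppressWarnings(stats::wilcox.test(va, vb))
    data.frame(offset = off, n_a = length(va), n_b = length(vb),
               median_a = stats::median(va), median_b = stats::median(vb),
               statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < p_flag
  out
}
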