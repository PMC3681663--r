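# Two-population phased haplotype panel simulator: founder-mosaic base pool
# plus Wright-Fisher haplotype drift.

#' Configuration for the two-population haplotype simulator
#'
#' The generator emulates a pair of reference panels (one per ancestry) for
#' a region of consecutive SNPs around a focal SNP. A founding pool of
#' haplotypes is built as mosaics of \code{n_founders} founder haplotypes
#' (per-SNP allele probabilities uniform in
#' \code{(maf_floor, 1 - maf_floor)}; the mosaic template switches between
#' adjacent SNPs with probability \code{recomb_prob}, which sets the LD
#' decay). Two populations then drift independently for
#' \code{drift_generations} generations of Wright-Fisher resampling of
#' \code{2 * pop_size} haplotypes, and \code{n_per_pop} diploid individuals
#' are sampled per population. With \code{drift_generations = 0} the two
#' panels are exchangeable draws from the founding pool.
#'
#' @param n_snps SNPs in the region (must be >= 650 for a full
#'   window-50/step-5/span-300 scan).
#' @param n_hap_pool haplotypes in the founding pool.
#' @param n_founders founder haplotypes behind the mosaic pool.
#' @param n_per_pop diploid individuals per population (length 1 or 2).
#' @param drift_generations Wright-Fisher generations of independent drift
#'   per population.
#' @param pop_size diploid population size N for the drift resampling
#'   (2N haplotypes per generation).
#' @param recomb_prob per-adjacent-SNP-pair template switch probability in
#'   [0, 1] for the founding mosaic (sets the baseline LD decay).
#' @param region_morgans genetic length of the whole region in Morgans:
#'   the probability of one crossover per transmitted haplotype during a
#'   drift generation. The default 0.005 corresponds to roughly 0.5 cM,
#'   the scale of a half-megabase region.
#' @param maf_floor lower bound for founding allele probabilities.
#' @param chrom chromosome label for the SNP map.
#' @param seed integer seed.
#' @return validated list of class \code{hap_sim_config}.
#' @export
hap_sim_config <- function(n_snps = 650, n_hap_pool = 240, n_founders = 16,
                           n_per_pop = c(60, 90), drift_generations = 75,
                           pop_size = 500, recomb_prob = 0.02,
                           region_morgans = 0.005,
                           maf_floor = 0.05, chrom = "1", seed = 1) {
  check_count(n_snps, "n_snps")
  check_count(n_hap_pool, "n_hap_pool")
  check_count(n_founders, "n_founders")
  check_count(n_per_pop, "n_per_pop")
  check_count(drift_generations, "drift_generations", positive = FALSE)
  check_count(pop_size, "pop_size")
  if (recomb_prob < 0 || recomb_prob > 1) {
    stop("'recomb_prob' must lie in [0, 1]", call. = FALSE)
  }
  if (region_morgans < 0 || region_morgans > 1) {
    stop("'region_morgans' must lie in [0, 1]", call. = FALSE)
  }
  check_fraction(maf_floor, "maf_floor", open_left = FALSE)
  if (maf_floor >= 0.5) stop("'maf_floor' must be < 0.5", call. = FALSE)
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, 2)
  structure(list(n_snps = n_snps, n_hap_pool = n_hap_pool,
                 n_founders = n_founders, n_per_pop = n_per_pop,
                 drift_generations = drift_generations, pop_size = pop_size,
                 recomb_prob = recomb_prob, region_morgans = region_morgans,
                 maf_floor = maf_floor,
                 chrom = chrom, seed = as.integer(seed)),
            class = "hap_sim_config")
}

# One Wright-Fisher generation: each child haplotype copies a random parent,
# with at most one crossover per child at probability p_x per meiosis (the
# region's genetic length in Morgans, to first order). The marginal
# per-locus dynamics are plain WF resampling, so single-SNP drift
# expectations are unchanged; recombination only prevents the whole region
# from fixing as a single haplotype under long drift.
wf_generation <- function(mat, n, p_x = 0) {
  pa <- sample.int(nrow(mat), n, replace = TRUE)
  child <- mat[pa, , drop = FALSE]
  s <- ncol(mat)
  if (p_x > 0 && s > 1) {
    xover <- stats::runif(n) < p_x
    nx <- sum(xover)
    if (nx > 0) {
      pb <- sample.int(nrow(mat), nx, replace = TRUE)
      k <- sample.int(s - 1, nx, replace = TRUE)
      right <- outer(k, seq_len(s), function(kk, ss) ss > kk)
      ca <- child[xover, , drop = FALSE]
      cb <- mat[pb, , drop = FALSE]
      ca[right] <- cb[right]
      child[xover, ] <- ca
    }
  }
  child
}

wf_drift <- function(mat, generations, n_haplotypes, p_x = 0) {
  for (g in seq_len(generations)) {
    mat <- wf_generation(mat, n_haplotypes, p_x)
  }
  mat
}

#' Generate a two-population phased haplotype panel pair
#'
#' See \code{\link{hap_sim_config}} for the generative model. The returned
#' object records the founding-pool allele frequencies
#' (\code{p_founding}), which serve as the ancestral frequencies for drift
#' expectations such as \eqn{F_{ST} \approx 1 - (1 - 1/(2N))^g}.
#'
#' @param config a \code{\link{hap_sim_config}}.
#' @param local_drift optional list \code{(start, end, generations,
#'   pop = 2)}: after the global drift, the SNP segment
#'   \code{start:end} of the chosen population undergoes additional
#'   Wright-Fisher resampling of the segment haplotypes only. This
#'   localises extra allele-frequency and LD divergence inside the segment
#'   (used to emulate regions whose divergence is confined to the focal
#'   window).
#' @return list of class \code{hap_panel_pair}: \code{panels} (two
#'   \code{\link{hap_panel}}s named \code{pop1}, \code{pop2}), \code{snp}
#'   (map with \code{p_founding} and per-population monomorphism flags),
#'   \code{config}.
#' @export
gen_two_pop_haplotypes <- function(config, local_drift = NULL) {
  stopifnot(inherits(config, "hap_sim_config"))
  set.seed(config$seed)
  S <- config$n_snps
  p_allele <- stats::runif(S, config$maf_floor, 1 - config$maf_floor)
  founders <- matrix(stats::rbinom(config$n_founders * S, 1,
                                   rep(p_allele, each = config$n_founders)),
                     nrow = config$n_founders, ncol = S)
  # mosaic pool: the template path is piecewise constant with geometric
  # block lengths (switch probability recomb_prob per adjacent pair)
  pool <- matrix(0L, nrow = config$n_hap_pool, ncol = S)
  for (h in seq_len(config$n_hap_pool)) {
    switches <- stats::runif(S - 1) < config$recomb_prob
    starts <- c(1L, which(switches) + 1L)
    block_tmpl <- sample.int(config$n_founders, length(starts), replace = TRUE)
    tmpl <- rep(block_tmpl, diff(c(starts, S + 1L)))
    pool[h, ] <- founders[cbind(tmpl, seq_len(S))]
  }
  p_founding <- colMeans(pool)

  n_hap_wf <- 2 * config$pop_size
  pops <- lapply(1:2, function(i) {
    mat <- pool
    if (config$drift_generations > 0) {
      mat <- wf_drift(mat, config$drift_generations, n_hap_wf,
                      config$region_morgans)
    }
    mat
  })
  if (!is.null(local_drift)) {
    ld <- local_drift
    pop_i <- ld$pop %||% 2
    seg <- ld$start:ld$end
    seg_mat <- pops[[pop_i]][, seg, drop = FALSE]
    seg_frac <- (length(seg) - 1) / max(1, S - 1)
    seg_mat <- wf_drift(seg_mat, ld$generations, nrow(seg_mat),
                        config$region_morgans * seg_frac)
    pops[[pop_i]][, seg] <- seg_mat
  }

  pos <- cumsum(sample(400:1300, S, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  snp <- data.frame(snp_id = sprintf("snp%05d", seq_len(S)),
                    chrom = config$chrom, pos_bp = pos,
                    ref_allele = ref, alt_allele = alt,
                    p_founding = p_founding)

  panels <- lapply(1:2, function(i) {
    n_hap <- 2 * config$n_per_pop[i]
    hap <- pops[[i]][sample.int(nrow(pops[[i]]), n_hap, replace = TRUE), ,
                     drop = FALSE]
    hap_panel(hap, snp,
              sample_ids = sprintf("pop%d_ind%03d", i,
                                   seq_len(config$n_per_pop[i])),
              population = paste0("pop", i))
  })
  names(panels) <- c("pop1", "pop2")
  snp$monomorphic_pop1 <- allele_freq(panels[[1]]) %in% c(0, 1)
  snp$monomorphic_pop2 <- allele_freq(panels[[2]]) %in% c(0, 1)
  panels[[1]]$snp <- snp
  panels[[2]]$snp <- snp
  structure(list(panels = panels, snp = snp, config = config),
            class = "hap_panel_pair")
}

#' @export
print.hap_panel_pair <- function(x, ...) {
  cat(sprintf("hap_panel_pair: %d SNPs; pop1 %d + pop2 %d individuals; g=%d, N=%d, seed=%d\n",
              nrow(x$snp), length(x$panels[[1]]$sample_ids),
              length(x$panels[[2]]$sample_ids),
              x$config$drift_generations, x$config$pop_size, x$config$seed))
  invisible(x)
}

#' Hudson-type F_ST estimate between the two panels
#'
#' Ratio-of-averages Hudson estimator over SNPs:
#' numerator \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)},
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}, summed over SNPs before the
#' ratio. Used as the drift calibration readout for simulated panel pairs.
#'
#' @param pair a \code{hap_panel_pair}.
#' @return scalar F_ST estimate.
#' @export
fst_hudson <- function(pair) {
  p1 <- allele_freq(pair$panels[[1]])
  p2 <- allele_freq(pair$panels[[2]])
  n1 <- nrow(pair$panels[[1]]$alleles)
  n2 <- nrow(pair$panels[[2]]$alleles)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}
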