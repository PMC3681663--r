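# Replication-database simulator with known ground-truth causal sharing.

#' Configuration for the replication-database simulator
#'
#' Generates a studies/associations/attempts table set with a known
#' fraction \code{pi_share} of associations whose causal effect is present
#' in the replication population. Discovery records are built to pass the
#' curation filters (genome-wide significant, outside the MHC, spaced more
#' than 200 kb apart, not sex-specific). For each replication attempt the
#' test statistic is drawn as \eqn{z \sim N(ncp, 1)} when the association
#' is shared — with the same non-centrality as
#' \code{\link{replication_power}}, so simulated and analytic power agree
#' by construction — and \eqn{z \sim N(0, 1)} (true OR of 1 in the
#' replication population) when it is not.
#'
#' Defaults emulate the scale and operating point of a curated trans-ethnic
#' replication database: a few hundred attempts across tens of diseases,
#' discovery per-allele odds ratios centred near 1.2, replication sample
#' sizes of a few hundred to a few thousand giving average replication
#' power near 0.6, and a causal-sharing fraction of 0.8 (so the effective
#' replicability is close to 80\%).
#'
#' @param n_diseases number of diseases.
#' @param assoc_per_disease discovered associations per disease.
#' @param attempts_per_assoc replication attempts per association.
#' @param pi_share probability in [0, 1] that an association's causal
#'   effect is present in the replication population.
#' @param or_log_mean,or_log_sd mean and sd of the (absolute) log
#'   odds-ratio distribution of true discovery effects.
#' @param maf_range range of discovery-population minor allele frequencies
#'   (within (0, 0.5]).
#' @param n_cases_range,n_controls_range replication sample-size ranges.
#' @param raf_sd sd of the perturbation of the replication-population risk
#'   allele frequency around the discovery MAF.
#' @param alpha replication significance level (same-direction success
#'   criterion: same risk allele and p below \code{alpha}).
#' @param winners_curse if \code{TRUE}, discovery ORs are re-drawn from the
#'   discovery sampling distribution truncated at genome-wide significance
#'   (overestimating effects); by default discovery ORs are the true ones,
#'   emulating effect estimates taken from internal replication stages.
#' @param seed integer seed; all sub-streams derive from it.
#' @return validated list of class \code{db_sim_config}.
#' @export
db_sim_config <- function(n_diseases = 28, assoc_per_disease = 8,
                          attempts_per_assoc = 1, pi_share = 0.8,
                          or_log_mean = log(1.2), or_log_sd = 0.12,
                          maf_range = c(0.05, 0.5),
                          n_cases_range = c(300, 2000),
                          n_controls_range = c(300, 2000),
                          raf_sd = 0.05, alpha = 0.05,
                          winners_curse = FALSE, seed = 1) {
  check_count(n_diseases, "n_diseases")
  check_count(assoc_per_disease, "assoc_per_disease")
  check_count(attempts_per_assoc, "attempts_per_assoc")
  check_fraction(pi_share, "pi_share", open_left = FALSE, open_right = FALSE)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("'maf_range' must be an increasing pair within (0, 0.5]", call. = FALSE)
  }
  for (nm in c("n_cases_range", "n_controls_range")) {
    r <- get(nm)
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      stop("'", nm, "' must be an increasing pair of positive counts",
           call. = FALSE)
    }
  }
  check_fraction(alpha, "alpha")
  if (or_log_sd < 0) stop("'or_log_sd' must be >= 0", call. = FALSE)
  structure(list(n_diseases = n_diseases,
                 assoc_per_disease = assoc_per_disease,
                 attempts_per_assoc = attempts_per_assoc,
                 pi_share = pi_share, or_log_mean = or_log_mean,
                 or_log_sd = or_log_sd, maf_range = maf_range,
                 n_cases_range = n_cases_range,
                 n_controls_range = n_controls_range, raf_sd = raf_sd,
                 alpha = alpha, winners_curse = winners_curse,
                 seed = as.integer(seed)),
            class = "db_sim_config")
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) return(rep(as.integer(range[1]), n))
  sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a replication database with known causal sharing
#'
#' Produces the three-table set of \code{\link{load_tables}} plus a hidden
#' truth table flagging which associations are shared. Attempt p-values are
#' two-sided normal; the success flag requires the same risk allele
#' (replication z > 0, since discovery ORs are risk-allele referenced) and
#' p below \code{alpha}. For non-shared associations the attempt z-score is
#' standard normal, so p-values are Uniform(0,1) and the same-direction
#' success probability is exactly \code{alpha/2}.
#'
#' @param config a \code{\link{db_sim_config}}.
#' @return list of class \code{transrep_simdb}: \code{studies},
#'   \code{associations}, \code{attempts}, \code{truth} (data.frame
#'   \code{snp_id}, \code{shared}), \code{config}.
#' @export
gen_replication_database <- function(config) {
  stopifnot(inherits(config, "db_sim_config"))
  set.seed(config$seed)
  n_assoc <- config$n_diseases * config$assoc_per_disease
  diseases <- sprintf("disease%02d", seq_len(config$n_diseases))

  # discovery studies (one per disease, European) + replication studies
  disc_studies <- data.frame(
    study_id = sprintf("D%03d", seq_len(config$n_diseases)),
    disease = diseases, ancestry = "European",
    year = sample(2006:2012, config$n_diseases, replace = TRUE),
    n_gwas_stage = runif_int(config$n_diseases, c(2000, 20000)),
    n_replication_stage = runif_int(config$n_diseases, c(2000, 20000)),
    uses_imputation = sample(c(TRUE, FALSE), config$n_diseases, replace = TRUE),
    genomic_control_lambda = round(stats::runif(config$n_diseases, 1.0, 1.1), 3))
  rep_studies <- data.frame(
    study_id = sprintf("R%03d", seq_len(config$n_diseases *
                                          config$attempts_per_assoc)),
    disease = rep(diseases, config$attempts_per_assoc),
    ancestry = "EastAsian",
    year = sample(2008:2012, config$n_diseases * config$attempts_per_assoc,
                  replace = TRUE),
    n_gwas_stage = runif_int(config$n_diseases * config$attempts_per_assoc,
                             c(1000, 10000)),
    n_replication_stage = 0L,
    uses_imputation = FALSE, genomic_control_lambda = NA_real_)
  studies <- rbind(disc_studies, rep_studies)

  # associations: spaced > 200 kb, off the MHC, genome-wide significant
  disease <- rep(diseases, each = config$assoc_per_disease)
  chrom <- as.character(sample(c(1:5, 7:22), n_assoc, replace = TRUE))
  pos_bp <- integer(n_assoc)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos_bp[idx] <- sort(3e5 * seq_along(idx) +
                          sample.int(9e4, length(idx), replace = TRUE))
  }
  maf <- stats::runif(n_assoc, config$maf_range[1], config$maf_range[2])
  log_or_true <- abs(stats::rnorm(n_assoc, config$or_log_mean,
                                  config$or_log_sd))
  shared <- stats::runif(n_assoc) < config$pi_share
  bases <- c("A", "C", "G", "T")
  risk <- sample(bases, n_assoc, replace = TRUE)
  other <- vapply(risk, function(b) sample(setdiff(bases, b), 1), character(1))
  disc_study <- disc_studies$study_id[match(disease, disc_studies$disease)]

  or_disc_obs <- exp(log_or_true)
  if (config$winners_curse) {
    # discovery estimate from the significance-truncated sampling distribution
    n_d <- disc_studies$n_gwas_stage[match(disease, disc_studies$disease)]
    ncp_d <- replication_ncp(exp(log_or_true), maf, n_d / 2, n_d / 2)
    z_thr <- stats::qnorm(1 - 5e-8 / 2)
    u <- stats::runif(n_assoc, stats::pnorm(z_thr - ncp_d), 1)
    z_d <- ncp_d + stats::qnorm(u)
    or_disc_obs <- exp(log_or_true * pmax(z_d / pmax(ncp_d, 1e-9), 1))
  }
  associations <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(n_assoc)),
    chrom = chrom, pos_bp = pos_bp, disease = disease,
    discovery_study_id = disc_study, risk_allele = risk, other_allele = other,
    or_discovery = or_disc_obs, log_or = log(or_disc_obs),
    p_discovery = 10^-stats::runif(n_assoc, 8.5, 30),
    maf_discovery_pop = maf, sex_specific = FALSE, region_id = NA_character_)

  # attempts
  idx <- rep(seq_len(n_assoc), config$attempts_per_assoc)
  rep_no <- rep(seq_len(config$attempts_per_assoc), each = n_assoc)
  n_att <- length(idx)
  n_cases <- runif_int(n_att, config$n_cases_range)
  n_controls <- runif_int(n_att, config$n_controls_range)
  raf <- pmin(pmax(maf[idx] + stats::rnorm(n_att, 0, config$raf_sd), 0.02),
              0.98)
  psi <- exp(log_or_true[idx])
  ncp <- replication_ncp(psi, raf, n_cases, n_controls)
  z <- stats::rnorm(n_att, mean = ifelse(shared[idx], ncp, 0), sd = 1)
  p_rep <- 2 * stats::pnorm(-abs(z))
  # map z back to an effect estimate on the log-odds scale
  p0 <- raf
  p1 <- psi * p0 / (1 + p0 * (psi - 1))
  se_prop <- sqrt(p1 * (1 - p1) / (2 * n_cases) +
                    p0 * (1 - p0) / (2 * n_controls))
  pbar <- (p0 + p1) / 2
  log_or_rep <- z * se_prop / (pbar * (1 - pbar))
  power <- replication_power(psi, raf, n_cases, n_controls,
                             alpha = config$alpha)
  rep_study <- rep_studies$study_id[
    match(paste(disease[idx], rep_no),
          paste(rep_studies$disease,
                rep(seq_len(config$attempts_per_assoc),
                    each = config$n_diseases)))]
  attempts <- data.frame(
    snp_id = associations$snp_id[idx],
    replication_study_id = rep_study, ancestry = "EastAsian",
    or_replication = exp(log_or_rep), p_replication = p_rep,
    n_cases = n_cases, n_controls = n_controls,
    raf_replication_pop = raf, allele_shift_flag = raf > 0.5,
    power = power, success = z > 0 & p_rep < config$alpha)

  structure(list(studies = studies, associations = associations,
                 attempts = attempts,
                 truth = data.frame(snp_id = associations$snp_id,
                                    shared = shared),
                 config = config),
            class = c("transrep_simdb", "transrep_db"))
}

#' Write a simulated database (tables + truth + manifest) to a directory
#'
#' @param db a \code{transrep_simdb}.
#' @param dir output directory.
#' @return file paths, invisibly.
#' @export
write_simdb <- function(db, dir) {
  comments <- c(output_comments(db$config),
                sprintf("seed=%d", db$config$seed))
  paths <- write_tables(db, dir, comments = comments)
  truth_path <- file.path(dir, "truth.tsv")
  write_tsv(db$truth, truth_path, comments)
  invisible(c(paths, truth = truth_path))
}
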