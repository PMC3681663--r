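# Fixtures built in code: toy curation tables and an independent
# brute-force oracle for the discovery filters.

toy_studies <- function() {
  data.frame(
    study_id = c("S_geno", "S_imp"),
    disease = "toy",
    ancestry = "European",
    year = c(2008L, 2011L),
    n_gwas_stage = c(5000L, 12000L),
    n_replication_stage = c(4000L, 9000L),
    uses_imputation = c(FALSE, TRUE),
    genomic_control_lambda = c(1.03, NA))
}

# 20-row association table exercising every curation rule: the two
# significance thresholds, sex-specific exclusion, the MHC window and
# 200-kb transitive pruning (including the strict boundary).
toy_associations <- function() {
  mk <- function(snp, chrom, pos, study, p, sex = FALSE) {
    data.frame(snp_id = snp, chrom = chrom, pos_bp = as.integer(pos),
               disease = "toy", discovery_study_id = study,
               risk_allele = "A", other_allele = "G",
               or_discovery = 1.3, log_or = log(1.3), p_discovery = p,
               maf_discovery_pop = 0.25, sex_specific = sex,
               region_id = NA_character_)
  }
  rbind(
    mk("rs_keep1",  "1",   100000, "S_geno", 1e-8),
    mk("rs_prune1", "1",   250000, "S_geno", 1e-9),   # chains with rs_keep1
    mk("rs_edge1",  "1",   450001, "S_geno", 1e-10),  # 200001 bp: own region
    mk("rs_chain1", "2",   100000, "S_geno", 1e-8),
    mk("rs_chain2", "2",   290000, "S_geno", 1e-9),   # transitive chain 1-2-3
    mk("rs_chain3", "2",   480000, "S_geno", 1e-7),
    mk("rs_thr1",   "3",   100000, "S_geno", 2e-7),   # kept (genotyped, <5e-7)
    mk("rs_thr2",   "3",  9000000, "S_imp",  2e-7),   # dropped (imputed, >=5e-8)
    mk("rs_thr3",   "3", 18000000, "S_imp",  2e-9),   # kept (imputed, <5e-8)
    mk("rs_thr4",   "4",   100000, "S_geno", 6e-7),   # dropped (>=5e-7)
    mk("rs_mhc1",   "6", 25000000, "S_geno", 1e-12),  # MHC start
    mk("rs_mhc2",   "6", 30000000, "S_geno", 1e-20),  # MHC interior
    mk("rs_mhc3",   "6", 35000001, "S_geno", 1e-9),   # just outside MHC
    mk("rs_sex1",   "7",   100000, "S_geno", 1e-12, sex = TRUE),
    mk("rs_solo1",  "7",  5000000, "S_geno", 1e-8),
    mk("rs_tie1",   "8",   100000, "S_geno", 1e-9),
    mk("rs_tie2",   "8",   150000, "S_geno", 1e-9),   # tie: keep smaller pos
    mk("rs_far1",   "9",   100000, "S_geno", 1e-8),
    mk("rs_far2",   "9",  2000000, "S_geno", 1e-8),
    mk("rs_sex2",   "9",  2100000, "S_geno", 5e-20, sex = TRUE))
}

# Independent O(n^2) oracle for the curation filters: explicit pairwise
# adjacency + transitive closure, no shared code with the implementation.
brute_force_filter <- function(assoc, studies, p_geno = 5e-7, p_imp = 5e-8,
                               mhc_chrom = "6", mhc_lo = 25e6, mhc_hi = 35e6,
                               gap = 2e5) {
  keep <- rep(TRUE, nrow(assoc))
  keep[assoc$sex_specific] <- FALSE
  imp <- studies$uses_imputation[match(assoc$discovery_study_id,
                                       studies$study_id)]
  thr <- ifelse(imp, p_imp, p_geno)
  keep[!(assoc$p_discovery < thr)] <- FALSE
  keep[assoc$chrom == mhc_chrom & assoc$pos_bp >= mhc_lo &
         assoc$pos_bp <= mhc_hi] <- FALSE
  surv <- which(keep)
  n <- length(surv)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- assoc$disease[surv[i]] == assoc$disease[surv[j]] &&
        assoc$chrom[surv[i]] == assoc$chrom[surv[j]] &&
        abs(assoc$pos_bp[surv[i]] - assoc$pos_bp[surv[j]]) < gap
    }
  }
  reach <- adj
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach > 0)
  }
  comp <- rep(NA_integer_, n)
  next_c <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      next_c <- next_c + 1
      comp[reach[i, ]] <- next_c
    }
  }
  kept <- vapply(seq_len(next_c), function(cl) {
    members <- surv[comp == cl]
    members[order(assoc$p_discovery[members], assoc$pos_bp[members])][1]
  }, integer(1))
  sort(assoc$snp_id[kept])
}

# Small exchangeable two-population region (no drift).
exchangeable_region <- function(seed, n_snps = 50, n_per_pop = c(25, 30)) {
  gen_two_pop_haplotypes(hap_sim_config(
    n_snps = n_snps, n_hap_pool = 160, n_per_pop = n_per_pop,
    drift_generations = 0, seed = seed))
}

# Independent eigenvalue route for the varLD score oracle: shift the
# symmetric matrix to positive definite, take singular values (dgesdd),
# shift back. Avoids the symmetric eigensolver used by the implementation.
varld_score_svd_oracle <- function(m1, m2) {
  ev <- function(m) {
    shift <- sum(abs(m))  # > spectral radius, makes m + shift*I PD
    sort(svd(m + diag(shift, nrow(m)))$d - shift, decreasing = TRUE)
  }
  sum(abs(ev(m1) - ev(m2)))
}
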