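# Synthetic replication databases and two-population haplotype panels.

test_that("simulator configurations validate their ranges", {
  expect_error(db_sim_config(pi_share = 1.2), "pi_share")
  expect_error(db_sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(db_sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(db_sim_config(n_cases_range = c(500, 100)), "n_cases_range")
  expect_error(hap_sim_config(recomb_prob = 1.5), "recomb_prob")
  expect_error(hap_sim_config(maf_floor = 0.7), "maf_floor")
  expect_error(hap_sim_config(n_snps = 0), "n_snps")
})

test_that("fully shared, fully powered databases replicate almost always", {
  db <- gen_replication_database(db_sim_config(
    n_diseases = 25, assoc_per_disease = 20, pi_share = 1,
    or_log_mean = log(2), or_log_sd = 0,
    maf_range = c(0.3, 0.3), raf_sd = 0,
    n_cases_range = c(20000, 20000), n_controls_range = c(20000, 20000),
    seed = 41))
  expect_gte(nrow(db$attempts), 500)
  expect_true(all(db$attempts$power >= 0.99))
  expect_gte(mean(db$attempts$success), 0.95)
})

test_that("unshared databases replicate at the same-direction null rate alpha/2", {
  db <- gen_replication_database(db_sim_config(
    n_diseases = 28, assoc_per_disease = 12, attempts_per_assoc = 7,
    pi_share = 0, seed = 42))
  n <- nrow(db$attempts)
  expect_gte(n, 2000)
  rate <- mean(db$attempts$success)
  se <- sqrt(0.025 * 0.975 / n)
  expect_lt(abs(rate - 0.025), 3 * se)

  # p-values of unshared attempts are Uniform(0,1)
  ks <- suppressWarnings(ks.test(db$attempts$p_replication, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mixed sharing follows the power/null mixture formula", {
  db <- gen_replication_database(db_sim_config(
    n_diseases = 28, assoc_per_disease = 12, attempts_per_assoc = 7,
    pi_share = 0.5, seed = 43))
  att <- db$attempts
  shared <- db$truth$shared[match(att$snp_id, db$truth$snp_id)]
  p_attempt <- ifelse(shared, att$power, 0.025)
  expected_rate <- mean(p_attempt)
  se <- sqrt(mean(p_attempt * (1 - p_attempt)) / nrow(att))
  expect_lt(abs(mean(att$success) - expected_rate), 3 * se)
})

test_that("discovery records pass the curation filters by construction", {
  db <- gen_replication_database(db_sim_config(seed = 44))
  res <- apply_discovery_filters(db$associations, db$studies)
  expect_equal(nrow(res$excluded), 0)
  expect_equal(nrow(res$associations), nrow(db$associations))
})

test_that("zero-recombination founder mosaics carry complete within-block LD", {
  cfg <- hap_sim_config(n_snps = 30, n_founders = 2, n_hap_pool = 80,
                        recomb_prob = 0, drift_generations = 0,
                        n_per_pop = c(30, 30), seed = 45)
  pair <- gen_two_pop_haplotypes(cfg)
  hap <- pair$panels[[1]]$alleles
  poly <- which(apply(hap, 2, function(v) length(unique(v))) == 2)
  expect_gt(length(poly), 5)
  s <- signed_r2_matrix(hap[, poly])
  off <- s[upper.tri(s)]
  # two founders, no template switching: every polymorphic pair is in
  # complete (possibly repulsion-phase) LD
  expect_true(all(abs(abs(off) - 1) < 1e-10))

  # with many founders, each zero-recombination haplotype is a verbatim copy
  cfg16 <- hap_sim_config(n_snps = 25, n_founders = 16, n_hap_pool = 40,
                          recomb_prob = 0, drift_generations = 0,
                          n_per_pop = c(10, 10), seed = 46)
  pair16 <- gen_two_pop_haplotypes(cfg16)
  hap16 <- pair16$panels[[1]]$alleles
  n_distinct <- nrow(unique(hap16))
  expect_lte(n_distinct, 16)
})

test_that("Wright-Fisher drift matches the F_ST expectation 1-(1-1/2N)^g", {
  g <- 30
  N <- 150
  fst <- vapply(1:40, function(s) {
    pair <- gen_two_pop_haplotypes(hap_sim_config(
      n_snps = 40, n_hap_pool = 200, n_per_pop = c(50, 50),
      drift_generations = g, pop_size = N, seed = 500 + s))
    fst_hudson(pair)
  }, numeric(1))
  expected <- 1 - (1 - 1 / (2 * N))^g
  se <- sd(fst) / sqrt(length(fst))
  expect_lt(abs(mean(fst) - expected), 3 * se + 0.005)
})

test_that("stronger drift strictly increases the median varLD divergence", {
  gs <- c(0, 10, 50, 200)
  medians <- vapply(gs, function(g) {
    scores <- vapply(1:50, function(s) {
      pair <- gen_two_pop_haplotypes(hap_sim_config(
        n_snps = 50, n_hap_pool = 200, n_per_pop = c(30, 30),
        drift_generations = g, pop_size = 500, seed = 1000 + 17 * s + g))
      varld_raw_score(signed_r2_matrix(pair$panels[[1]]),
                      signed_r2_matrix(pair$panels[[2]]))
    }, numeric(1))
    median(scores)
  }, numeric(1))
  expect_true(all(diff(medians) > 0))
})

test_that("local drift confines extra divergence to the targeted segment", {
  base <- gen_two_pop_haplotypes(hap_sim_config(
    n_snps = 150, n_per_pop = c(30, 30), drift_generations = 0, seed = 47))
  drifted <- gen_two_pop_haplotypes(
    hap_sim_config(n_snps = 150, n_per_pop = c(30, 30),
                   drift_generations = 0, seed = 47),
    local_drift = list(start = 60, end = 90, generations = 300))
  p_base <- colMeans(base$panels[[2]]$alleles)
  p_drift <- colMeans(drifted$panels[[2]]$alleles)
  seg <- 60:90
  # outside the segment the population is untouched by the extra drift
  expect_gt(mean(abs(p_drift[seg] - base$snp$p_founding[seg])),
            mean(abs(p_drift[-seg] - base$snp$p_founding[-seg])))
})
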