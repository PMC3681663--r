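# varLD scoring, sliding scans, permutation p-values and backgrounds.

test_that("signed r2 entries reproduce canonical LD configurations", {
  # complete coupling: haplotypes 00/11 only
  coupled <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  s <- signed_r2_matrix(coupled)
  expect_equal(s[1, 2], 1)

  # equifrequent 00/01/10/11: D = 0 exactly
  equil <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  expect_equal(signed_r2_matrix(equil)[1, 2], 0)

  # repulsion-phase pair carries a negative sign
  repuls <- rbind(c(0, 1), c(0, 1), c(1, 0), c(1, 0))
  expect_equal(signed_r2_matrix(repuls)[1, 2], -1)

  # independent SNPs in a large pool decorrelate
  set.seed(42)
  indep <- cbind(rbinom(1000, 1, 0.4), rbinom(1000, 1, 0.3))
  expect_lt(abs(signed_r2_matrix(indep)[1, 2]), 0.05)
})

test_that("monomorphic and all-missing SNPs are flagged or rejected", {
  m <- cbind(c(0, 1, 0, 1), c(1, 1, 1, 1), c(0, 0, 1, 1))
  s <- signed_r2_matrix(m)
  expect_equal(attr(s, "monomorphic"), 2L)
  expect_equal(s[1, 2], 0)
  expect_equal(s[2, 3], 0)
  expect_equal(diag(s), rep(1, 3))

  m_na <- m
  m_na[, 3] <- NA
  colnames(m_na) <- c("a", "b", "snp_bad")
  expect_error(signed_r2_matrix(m_na), "snp_bad")
})

test_that("varLD raw score matches closed forms and is a pseudometric", {
  m1 <- matrix(c(1, 0.5, 0.5, 1), 2)
  m2 <- matrix(c(1, 0.1, 0.1, 1), 2)
  # 2x2 eigenvalues are 1 +/- rho: |1.5-1.1| + |0.5-0.9|
  expect_equal(varld_raw_score(m1, m2), 0.8)
  expect_equal(varld_raw_score(m1, m1), 0)
  expect_equal(varld_raw_score(m1, m2), varld_raw_score(m2, m1))
  expect_error(varld_raw_score(m1, diag(3)), "dimension")

  # invariant to a simultaneous identical SNP reordering
  set.seed(8)
  h1 <- matrix(rbinom(400, 1, 0.5), 40, 10)
  h2 <- matrix(rbinom(400, 1, 0.5), 40, 10)
  s1 <- signed_r2_matrix(h1)
  s2 <- signed_r2_matrix(h2)
  perm <- sample(10)
  expect_equal(varld_raw_score(s1[perm, perm], s2[perm, perm]),
               varld_raw_score(s1, s2), tolerance = 1e-10)
})

test_that("windowed spectra conserve the trace", {
  pair <- exchangeable_region(3, n_snps = 60)
  s <- signed_r2_matrix(pair$panels[[1]], 1:50)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev), 50, tolerance = 1e-8)
})

test_that("sliding scan yields 121 windows on a 650-SNP region and truncates otherwise", {
  pair <- gen_two_pop_haplotypes(hap_sim_config(n_snps = 650,
                                                n_per_pop = c(30, 30),
                                                seed = 4))
  sc <- sliding_window_scan(pair$panels[[1]], pair$panels[[2]], 325)
  expect_equal(nrow(sc), 121)
  expect_equal(range(sc$offset), c(-300, 300))
  expect_equal(unique(diff(sc$offset)), 5)
  expect_equal(unique(sc$window_snps), 50)

  # identical panels: zero scores everywhere
  self <- sliding_window_scan(pair$panels[[1]], pair$panels[[1]], 325)
  expect_true(all(self$varld_raw < 1e-10))
  expect_true(all(self$het_diff == 0))

  # a 600-SNP region cannot host the full 121-window scan
  pair600 <- gen_two_pop_haplotypes(hap_sim_config(n_snps = 600,
                                                   n_per_pop = c(20, 20),
                                                   seed = 5))
  expect_warning(tr <- sliding_window_scan(pair600$panels[[1]],
                                           pair600$panels[[2]], 300),
                 "truncated")
  expect_lt(nrow(tr), 121)
})

test_that("population swap flips het_diff sign but not the varLD score", {
  pair <- gen_two_pop_haplotypes(hap_sim_config(n_snps = 120,
                                                n_per_pop = c(25, 25),
                                                drift_generations = 40,
                                                pop_size = 200, seed = 6))
  a <- sliding_window_scan(pair$panels[[1]], pair$panels[[2]], 60,
                           span = 30)
  b <- sliding_window_scan(pair$panels[[2]], pair$panels[[1]], 60,
                           span = 30)
  expect_equal(b$het_diff, -a$het_diff, tolerance = 1e-12)
  expect_equal(b$varld_raw, a$varld_raw, tolerance = 1e-10)
})

test_that("permutation p-values respect their bounds and detect heavy drift", {
  pair <- exchangeable_region(7)
  pp <- permutation_pvalue(pair$panels[[1]], pair$panels[[2]], 1:50,
                           n_perm = 49, seed = 1)
  expect_gte(pp$p_value, 1 / 50)
  expect_lte(pp$p_value, 1)
  expect_equal(length(pp$perm_scores), 49)

  # strongly drifted pairs drive the empirical p to (or near) its minimum
  # in the bulk of regions; under very long drift a minority of regions
  # lose their LD contrast to recombination-drift equilibrium or fixation
  ps <- vapply(1:20, function(s) {
    drifted <- gen_two_pop_haplotypes(hap_sim_config(
      n_snps = 50, n_per_pop = c(45, 45), drift_generations = 500,
      pop_size = 200, seed = 700 + s))
    permutation_pvalue(drifted$panels[[1]], drifted$panels[[2]], 1:50,
                       n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(ps <= 0.05), 0.9)
  expect_gte(mean(ps == 1 / 100), 0.75)
})

test_that("MAF-matched backgrounds honour tolerance and group structure", {
  pair <- exchangeable_region(9, n_snps = 200, n_per_pop = c(25, 25))
  focal <- c(0.15, 0.3, 0.45)
  bg <- maf_matched_background(focal, pair$panels[[1]], pair$panels[[2]],
                               n_groups = 3, group_size = 5, tol = 0.05,
                               window = 20, n_perm = 19, seed = 2)
  expect_equal(nrow(bg$groups), 15)
  targets <- focal[(bg$groups$slot - 1) %% 3 + 1]
  expect_true(all(abs(bg$groups$maf - targets) <= 0.05 + 1e-12))
  # no SNP reused within a group
  expect_true(all(tapply(bg$groups$snp_index, bg$groups$group,
                         anyDuplicated) == 0))
  expect_equal(names(bg$envelope), c("p", "median", "lo", "hi"))
  expect_true(all(bg$envelope$lo <= bg$envelope$median + 1e-12))
  expect_error(
    suppressWarnings(
      maf_matched_background(0.99, pair$panels[[1]], pair$panels[[2]],
                             n_groups = 1, group_size = 1, tol = 1e-6,
                             tol_wide = 1e-5, window = 20, n_perm = 9)),
    "candidate")
})

test_that("per-offset group comparison reproduces exact rank-sum arithmetic", {
  mk <- function(vals) {
    data.frame(focal_snp = rep("x", length(vals)),
               offset = rep(0, length(vals)),
               window_snps = rep(50, length(vals)), varld_raw = vals,
               het_diff = rep(0, length(vals)),
               n_monomorphic = rep(0, length(vals)),
               empirical_p = rep(NA_real_, length(vals)))
  }
  res <- group_window_comparison(mk(c(1, 2, 3)), mk(c(4, 5, 6)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_false(res$significant)

  same <- group_window_comparison(mk(c(1, 2, 3)), mk(c(1, 2, 3)))
  expect_gt(same$p_value, 0.99)
  expect_error(group_window_comparison(mk(numeric(0)), mk(1:3)), "empty")
})

test_that("haplotype panels round-trip through phased VCF plus sidecar", {
  pair <- exchangeable_region(10, n_snps = 40, n_per_pop = c(6, 8))
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "panel.vcf")
  paths <- write_hap_vcf(pair$panels, vcf)
  panels <- read_hap_panels(paths[["vcf"]], paths[["pops"]])
  expect_equal(names(panels), c("pop1", "pop2"))
  expect_equal(unname(panels$pop1$alleles),
               unname(pair$panels$pop1$alleles))
  expect_equal(unname(panels$pop2$alleles),
               unname(pair$panels$pop2$alleles))
  expect_equal(panels$pop1$snp$pos_bp, pair$snp$pos_bp)
  expect_equal(panels$pop2$sample_ids, pair$panels$pop2$sample_ids)
})
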