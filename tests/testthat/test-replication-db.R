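# Data model, I/O validation and curation filters.

test_that("simulated table sets round-trip through TSV with no validation errors", {
  db <- gen_replication_database(db_sim_config(n_diseases = 4,
                                               assoc_per_disease = 5,
                                               seed = 11))
  dir <- withr::local_tempdir()
  write_simdb(db, dir)
  loaded <- load_tables(file.path(dir, "studies.tsv"),
                        file.path(dir, "associations.tsv"),
                        file.path(dir, "attempts.tsv"), quiet = TRUE)
  expect_s3_class(loaded, "transrep_db")
  expect_equal(nrow(loaded$attempts), nrow(db$attempts))
  expect_equal(loaded$associations$snp_id, db$associations$snp_id)
  expect_equal(loaded$attempts$or_replication, db$attempts$or_replication,
               tolerance = 1e-12)
})

test_that("referential and dialect violations are rejected with row context", {
  db <- gen_replication_database(db_sim_config(n_diseases = 2,
                                               assoc_per_disease = 3,
                                               seed = 12))
  bad <- db$attempts
  bad$snp_id[2] <- "rs_unknown"
  expect_error(load_tables(db$studies, db$associations, bad, quiet = TRUE),
               "rs_unknown")

  dial <- db$attempts
  dial$or_replication <- as.character(dial$or_replication)
  dial$or_replication[3] <- "1,23"
  expect_error(load_tables(db$studies, db$associations, dial, quiet = TRUE),
               "1,23")

  missing_col <- db$associations[, setdiff(names(db$associations), "or_discovery")]
  expect_error(load_tables(db$studies, missing_col, db$attempts, quiet = TRUE),
               "or_discovery")
})

test_that("discovery filters enforce thresholds, MHC window and 200-kb pruning", {
  res <- apply_discovery_filters(toy_associations(), toy_studies())
  reasons <- res$excluded

  # imputation-dependent significance thresholds, strict inequality
  expect_true("rs_thr1" %in% res$associations$snp_id)
  expect_true("rs_thr3" %in% res$associations$snp_id)
  expect_equal(reasons$reason[reasons$snp_id == "rs_thr2"], "p_threshold")
  expect_equal(reasons$reason[reasons$snp_id == "rs_thr4"], "p_threshold")

  # MHC window inclusive at both ends, coordinates outside kept
  expect_setequal(reasons$snp_id[reasons$reason == "mhc"],
                  c("rs_mhc1", "rs_mhc2"))
  expect_true("rs_mhc3" %in% res$associations$snp_id)

  # sex-specific exclusion
  expect_setequal(reasons$snp_id[reasons$reason == "sex_specific"],
                  c("rs_sex1", "rs_sex2"))

  # 200-kb chaining: lowest p wins, strict boundary keeps both, transitive
  # chains collapse, ties resolved to smaller position
  expect_false("rs_keep1" %in% res$associations$snp_id)
  expect_true(all(c("rs_prune1", "rs_edge1") %in% res$associations$snp_id))
  expect_true("rs_chain2" %in% res$associations$snp_id)
  expect_false(any(c("rs_chain1", "rs_chain3") %in% res$associations$snp_id))
  expect_true("rs_tie1" %in% res$associations$snp_id)
  expect_false("rs_tie2" %in% res$associations$snp_id)

  # every dropped row has exactly one recorded reason
  expect_equal(sort(c(res$associations$snp_id, reasons$snp_id)),
               sort(toy_associations()$snp_id))
})

test_that("filtering is idempotent and regions partition the kept SNPs", {
  db <- gen_replication_database(db_sim_config(n_diseases = 6,
                                               assoc_per_disease = 10,
                                               seed = 13))
  # inject clustered positions to make pruning non-trivial
  a <- db$associations
  a$pos_bp[2] <- a$pos_bp[1] + 150000L
  a$chrom[2] <- a$chrom[1]
  a$disease[2] <- a$disease[1]
  once <- apply_discovery_filters(a, db$studies)
  twice <- apply_discovery_filters(once$associations, db$studies)
  expect_equal(twice$associations$snp_id, once$associations$snp_id)
  expect_equal(nrow(twice$excluded), 0)
  expect_false(anyNA(once$associations$region_id))
  expect_false(anyDuplicated(once$associations$region_id) > 0)
})

test_that("risk-allele referencing inverts shifted ORs and is an involution", {
  shifted <- reference_risk_allele(2.0, reported_allele = "G",
                                   risk_allele = "A")
  expect_equal(shifted$or, 0.5)
  expect_true(shifted$shift)
  expect_equal(shifted$log_or, log(0.5))
  expect_false(shifted$direction_same)

  same <- reference_risk_allele(1.25, "A", "A")
  expect_equal(same$or, 1.25)
  expect_false(same$shift)
  expect_equal(same$log_or, log(1.25))

  unit <- reference_risk_allele(1.0, "G", "A")
  expect_true(is.na(unit$direction_same))
  expect_equal(unit$log_or, 0)

  # involution: shifting twice returns the original OR
  ors <- c(0.3, 0.8, 1, 1.7, 4.2)
  back <- reference_risk_allele(
    reference_risk_allele(ors, "G", "A")$or, "G", "A")
  expect_equal(back$or, ors)
  expect_error(reference_risk_allele(0, "A", "G"), "> 0")
})

test_that("attempt selection modes are deterministic and match a group-by oracle", {
  db <- gen_replication_database(db_sim_config(n_diseases = 10,
                                               assoc_per_disease = 6,
                                               attempts_per_assoc = 3,
                                               seed = 14))
  att <- db$attempts
  expect_identical(select_attempts(att, "all"), att)

  two <- att[1:2, ]
  two$snp_id <- "rs000001"
  two$n_cases <- c(500L, 2500L)
  two$n_controls <- c(500L, 2500L)
  sel <- select_attempts(two, "largest_per_snp")
  expect_equal(nrow(sel), 1)
  expect_equal(sel$n_cases, 2500L)

  largest <- select_attempts(att, "largest_per_snp")
  expect_equal(nrow(largest), length(unique(att$snp_id)))
  # brute-force oracle: max total n per SNP
  oracle <- tapply(att$n_cases + att$n_controls, att$snp_id, max)
  got <- largest$n_cases + largest$n_controls
  names(got) <- largest$snp_id
  expect_equal(as.vector(got[names(oracle)]), as.vector(oracle))

  powered <- select_attempts(att, "most_powered_per_snp")
  oracle_p <- tapply(att$power, att$snp_id, max)
  got_p <- powered$power
  names(got_p) <- powered$snp_id
  expect_equal(as.vector(got_p[names(oracle_p)]), as.vector(oracle_p))

  att_nop <- att
  att_nop$power <- NA_real_
  expect_error(select_attempts(att_nop, "most_powered_per_snp"), "power")

  curated <- apply_discovery_filters(db$associations, db$studies)
  per_region <- select_attempts(att, "most_powered_per_region",
                                associations = db$associations |>
                                  transform(region_id = curated$associations$region_id[
                                    match(snp_id, curated$associations$snp_id)]))
  expect_lte(nrow(per_region), nrow(powered))
})
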