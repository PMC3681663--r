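# End-to-end orchestration: configuration, stage chaining, report writing.

#' Default pipeline configuration
#'
#' Returns the full configuration list for
#' \code{\link{run_full_pipeline}}, optionally overridden by a YAML file
#' and/or a named list. Paths \code{studies}/\code{associations}/
#' \code{attempts} switch the pipeline from simulated to provided input.
#'
#' @param yaml optional path to a YAML file of overrides.
#' @param overrides optional named list of overrides (applied after YAML).
#' @return configuration list.
#' @export
pipeline_config <- function(yaml = NULL, overrides = NULL) {
  config <- list(
    studies = NULL, associations = NULL, attempts = NULL,
    alpha = 0.05, null_convention = "alpha",
    select_mode = "all",
    n_diseases = 28, assoc_per_disease = 8, attempts_per_assoc = 1,
    pi_share = 0.8,
    do_varld = FALSE, window = 50, step = 5, span = 300, n_perm = 200,
    n_unreported_max = 0,
    seed = 1, outdir = "transrep_out")
  if (!is.null(yaml)) {
    if (!file.exists(yaml)) stop("config file not found: ", yaml, call. = FALSE)
    config <- utils::modifyList(config, yaml::read_yaml(yaml))
  }
  if (!is.null(overrides)) config <- utils::modifyList(config, overrides)
  if (config$alpha <= 0 || config$alpha >= 1) {
    stop("alpha must lie in (0,1)", call. = FALSE)
  }
  config
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full replicability pipeline
#'
#' Chains curate -> power -> replicability -> publication-bias bounds ->
#' concordance (and optionally a varLD scan on simulated panels) over
#' provided TSV tables or a simulated database, writing all result tables,
#' a run manifest (config, seed, version, hash) and a human-readable
#' report to \code{config$outdir}. Outputs are deterministic for a fixed
#' configuration and seed.
#'
#' @param config configuration list from \code{\link{pipeline_config}}, or
#'   a path to a YAML file.
#' @return invisibly, a list with the stage results and
#'   \code{status = 0L}.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(yaml = config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  comments <- output_comments(config)
  out <- function(name) file.path(config$outdir, name)

  db <- stage("load", {
    if (!is.null(config$attempts)) {
      load_tables(config$studies, config$associations, config$attempts,
                  quiet = TRUE)
    } else {
      simdb <- gen_replication_database(db_sim_config(
        n_diseases = config$n_diseases,
        assoc_per_disease = config$assoc_per_disease,
        attempts_per_assoc = config$attempts_per_assoc,
        pi_share = config$pi_share, alpha = config$alpha,
        seed = derive_seed(config$seed, 1)))
      write_simdb(simdb, config$outdir)
      simdb
    }
  })

  curated <- stage("curate", {
    res <- apply_discovery_filters(db$associations, db$studies)
    write_tsv(res$excluded, out("exclusions.tsv"), comments)
    res
  })

  attempts <- stage("power", {
    keep <- db$attempts$snp_id %in% curated$associations$snp_id
    att <- db$attempts[keep, , drop = FALSE]
    att <- select_attempts(att, config$select_mode,
                           associations = curated$associations)
    er <- expected_replications(att, curated$associations,
                                alpha = config$alpha)
    att <- er$attempts
    att <- flag_success(att, alpha = config$alpha)
    write_tsv(att, out("attempts_powered.tsv"), comments)
    att
  })

  summary_res <- stage("replicability", {
    n_s <- sum(attempts$success)
    n_a <- nrow(attempts)
    smry <- replicability_summary(n_s, n_a, alpha = config$alpha,
                                  expected_power = sum(attempts$power),
                                  null_convention = config$null_convention)
    write_tsv(data.frame(n_attempts = smry$n_attempts,
                         n_success = smry$n_success,
                         rate = smry$rate, alpha = smry$alpha,
                         expected_null = smry$expected_null,
                         p_binomial = smry$p_binomial,
                         expected_power = smry$expected_power,
                         effective_rate = smry$effective_rate),
              out("summary.tsv"), comments)
    smry
  })

  bias <- stage("bias", {
    b <- publication_bias_bounds(summary_res$n_success,
                                 alpha = config$alpha,
                                 n_gathered = summary_res$n_attempts,
                                 n_unreported_max = config$n_unreported_max)
    write_tsv(data.frame(observed = b$observed,
                         implied_pool = b$implied_pool,
                         implied_unreported = b$implied_unreported,
                         pool_ci_low = b$pool_ci_low,
                         pool_ci_high = b$pool_ci_high,
                         lower_bound_rate = b$lower_bound_rate),
              out("bias.tsv"), comments)
    b
  })

  concordance <- stage("concordance", {
    pairs <- data.frame(
      log_or_discovery = curated$associations$log_or[
        match(attempts$snp_id, curated$associations$snp_id)],
      log_or_replication = log(attempts$or_replication),
      success = attempts$success)
    cs <- concordance_stats(pairs)
    write_tsv(data.frame(n = cs$n, rho = cs$rho, rho_p = cs$rho_p,
                         slope = cs$slope, slope_se = cs$slope_se,
                         slope_p = cs$slope_p, intercept = cs$intercept),
              out("concordance.tsv"), comments)
    prof <- windowed_replicability_profile(
      cbind(attempts,
            or_discovery = curated$associations$or_discovery[
              match(attempts$snp_id, curated$associations$snp_id)]),
      axis = "OR")
    write_tsv(prof, out("profile_or.tsv"), comments)
    list(stats = cs, profile = prof)
  })

  windows <- NULL
  if (isTRUE(config$do_varld)) {
    windows <- stage("varld-scan", {
      pair <- gen_two_pop_haplotypes(hap_sim_config(
        n_snps = 2 * config$span + config$window,
        seed = derive_seed(config$seed, 2)))
      focal <- config$span + config$window %/% 2
      sc <- sliding_window_scan(pair$panels[[1]], pair$panels[[2]], focal,
                                window = config$window, step = config$step,
                                span = config$span, n_perm = config$n_perm,
                                seed = derive_seed(config$seed, 3))
      write_tsv(sc, out("windows.tsv"), comments)
      sc
    })
  }

  stage("report", {
    manifest <- list(tool = "transrep", version = transrep_version(),
                     config = config, config_hash = config_hash(config))
    yaml::write_yaml(manifest, out("manifest.yaml"))
    rpt <- c(
      sprintf("transrep %s run report", transrep_version()),
      sprintf("attempts analysed: %d", summary_res$n_attempts),
      sprintf("positive replications: %d (%.1f%%)", summary_res$n_success,
              round_half_up(100 * summary_res$rate, 1)),
      sprintf("null expectation: %.2f (binomial P = %.3g)",
              summary_res$expected_null, summary_res$p_binomial),
      sprintf("power-expected replications: %.1f; effective replicability %.1f%%",
              summary_res$expected_power,
              round_half_up(100 * summary_res$effective_rate, 1)),
      sprintf("bias bound: implied pool %.0f, lower-bound rate %.1f%%",
              bias$implied_pool,
              round_half_up(100 * bias$lower_bound_rate, 1)),
      sprintf("concordance: Spearman rho %.3f, OLS slope %.3f (SE %.3f)",
              concordance$stats$rho, concordance$stats$slope,
              concordance$stats$slope_se))
    writeLines(rpt, out("report.txt"))
    NULL
  })

  invisible(list(status = 0L, db = db, curated = curated,
                 attempts = attempts, summary = summary_res, bias = bias,
                 concordance = concordance, windows = windows,
                 config = config))
}
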