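# Data model, TSV I/O and curation filters for discovery/replication records.

ANCESTRIES <- c("European", "EastAsian", "African")

studies_columns <- c(
  study_id = "character", disease = "character", ancestry = "character",
  year = "integer", n_gwas_stage = "integer", n_replication_stage = "integer",
  uses_imputation = "logical", genomic_control_lambda = "numeric")

associations_columns <- c(
  snp_id = "character", chrom = "character", pos_bp = "integer",
  disease = "character", discovery_study_id = "character",
  risk_allele = "character", other_allele = "character",
  or_discovery = "numeric", log_or = "numeric", p_discovery = "numeric",
  maf_discovery_pop = "numeric", sex_specific = "logical",
  region_id = "character")

attempts_columns <- c(
  snp_id = "character", replication_study_id = "character",
  ancestry = "character", or_replication = "numeric",
  p_replication = "numeric", n_cases = "integer", n_controls = "integer",
  raf_replication_pop = "numeric", allele_shift_flag = "logical",
  power = "numeric", success = "logical")

coerce_table <- function(df, schema, table_name) {
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop(sprintf("table '%s': missing column(s): %s", table_name,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[names(schema)]
  for (col in names(schema)) {
    v <- df[[col]]
    df[[col]] <- switch(
      schema[[col]],
      character = { v <- as.character(v); v[v == "." | v == ""] <- NA; v },
      numeric = if (is.numeric(v)) as.numeric(v)
                else strict_numeric(v, paste(table_name, col, sep = "$")),
      integer = if (is.numeric(v)) as.integer(round(v))
                else strict_integer(v, paste(table_name, col, sep = "$")),
      logical = if (is.logical(v)) v
                else strict_logical(v, paste(table_name, col, sep = "$")))
  }
  df
}

#' Load and validate a replication-database table set
#'
#' Reads (or accepts in-memory) the three tab-separated tables describing a
#' curated GWAS replication database: \code{studies}, \code{associations}
#' (one row per discovered disease-associated SNP) and \code{attempts}
#' (one row per replication attempt). Columns are type-checked with a strict
#' numeric dialect (comma decimals are an error, \code{"."} is missing) and
#' referential integrity is enforced: every attempt must point at a known
#' SNP and every study id must resolve.
#'
#' @param studies,associations,attempts file paths to TSV files, or
#'   data.frames with the schema columns.
#' @param quiet suppress the row-count log message.
#' @return a list of class \code{transrep_db} with elements
#'   \code{studies}, \code{associations}, \code{attempts}.
#' @export
load_tables <- function(studies, associations, attempts, quiet = FALSE) {
  grab <- function(x) if (is.character(x) && length(x) == 1) read_tsv_raw(x) else as.data.frame(x)
  st <- coerce_table(grab(studies), studies_columns, "studies")
  as_ <- coerce_table(grab(associations), associations_columns, "associations")
  at <- coerce_table(grab(attempts), attempts_columns, "attempts")

  bad_anc <- setdiff(stats::na.omit(unique(c(st$ancestry, at$ancestry))), ANCESTRIES)
  if (length(bad_anc)) {
    stop("unknown ancestry label(s): ", paste(bad_anc, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(as_$or_discovery) & as_$or_discovery <= 0)) {
    stop("associations$or_discovery must be > 0", call. = FALSE)
  }
  if (any(!is.na(at$or_replication) & at$or_replication <= 0)) {
    stop("attempts$or_replication must be > 0", call. = FALSE)
  }
  dangling_snp <- setdiff(at$snp_id, as_$snp_id)
  if (length(dangling_snp)) {
    stop("attempts reference unknown snp_id(s): ",
         paste(utils::head(dangling_snp, 5), collapse = ", "), call. = FALSE)
  }
  dangling_study <- setdiff(
    stats::na.omit(c(at$replication_study_id, as_$discovery_study_id)),
    st$study_id)
  if (length(dangling_study)) {
    stop("unresolved study_id(s): ",
         paste(utils::head(dangling_study, 5), collapse = ", "), call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("loaded %d studies, %d associations, %d attempts",
                    nrow(st), nrow(as_), nrow(at)))
  }
  structure(list(studies = st, associations = as_, attempts = at),
            class = "transrep_db")
}

#' @export
print.transrep_db <- function(x, ...) {
  cat(sprintf("transrep replication database: %d studies, %d associations, %d attempts\n",
              nrow(x$studies), nrow(x$associations), nrow(x$attempts)))
  invisible(x)
}

#' Write a replication-database table set to TSV files
#'
#' @param db a \code{transrep_db} (or any list with \code{studies},
#'   \code{associations}, \code{attempts} data.frames).
#' @param dir output directory, created if needed.
#' @param comments optional extra header comment lines.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_tables <- function(db, dir, comments = output_comments()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(studies = file.path(dir, "studies.tsv"),
             associations = file.path(dir, "associations.tsv"),
             attempts = file.path(dir, "attempts.tsv"))
  write_tsv(db$studies, paths[["studies"]], comments)
  write_tsv(db$associations, paths[["associations"]], comments)
  write_tsv(db$attempts, paths[["attempts"]], comments)
  invisible(paths)
}

#' Curate discovered associations
#'
#' Applies the discovery-side inclusion rules for disease-associated SNPs:
#' \enumerate{
#'   \item drop SNPs associated only in sex-specific analyses;
#'   \item drop SNPs whose discovery p-value misses the genome-wide
#'     threshold appropriate for the discovery study: \code{5e-7} for
#'     directly genotyped scans, tightened to \code{5e-8} when the study
#'     used imputed SNPs;
#'   \item drop SNPs in the MHC region (default chr6:25-35 Mb);
#'   \item per disease and chromosome, cluster the remaining SNPs by
#'     transitive chaining at strictly less than \code{prune_gap_bp}
#'     (default 200 kb) and keep only the SNP with the lowest p-value in
#'     each cluster (ties: smaller position). Cluster membership is recorded
#'     in \code{region_id}.
#' }
#'
#' @param associations associations data.frame (see \code{\link{load_tables}}).
#' @param studies studies data.frame; supplies \code{uses_imputation} per
#'   discovery study.
#' @param p_genotyped,p_imputed genome-wide significance thresholds
#'   (strict \code{<}).
#' @param mhc list with \code{chrom}, \code{start_bp}, \code{end_bp}
#'   defining the excluded MHC window (inclusive).
#' @param prune_gap_bp region-pruning distance in bp (strict \code{<}).
#' @return list with \code{associations} (kept rows, \code{region_id}
#'   filled) and \code{excluded} (data.frame \code{snp_id}, \code{reason}).
#' @export
apply_discovery_filters <- function(associations, studies,
                                    p_genotyped = 5e-7, p_imputed = 5e-8,
                                    mhc = list(chrom = "6",
                                               start_bp = 25e6, end_bp = 35e6),
                                    prune_gap_bp = 2e5) {
  a <- associations
  excl <- data.frame(snp_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  drop <- function(idx, reason) {
    if (!length(idx)) return(invisible())
    excl <<- rbind(excl, data.frame(snp_id = a$snp_id[idx], reason = reason,
                                    stringsAsFactors = FALSE))
    a <<- a[-idx, , drop = FALSE]
    invisible()
  }

  drop(which(a$sex_specific %in% TRUE), "sex_specific")

  imput <- studies$uses_imputation[match(a$discovery_study_id, studies$study_id)]
  imput[is.na(imput)] <- FALSE
  thr <- ifelse(imput, p_imputed, p_genotyped)
  drop(which(!(a$p_discovery < thr)), "p_threshold")

  in_mhc <- a$chrom == as.character(mhc$chrom) &
    a$pos_bp >= mhc$start_bp & a$pos_bp <= mhc$end_bp
  drop(which(in_mhc), "mhc")

  # 200-kb transitive (single-linkage) pruning within disease x chromosome;
  # on a line this is chaining of consecutive sorted gaps.
  a$region_id <- NA_character_
  keep <- logical(nrow(a))
  key <- paste(a$disease, a$chrom, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(a$pos_bp[idx])]
    pos <- a$pos_bp[idx]
    new_cluster <- c(TRUE, diff(pos) >= prune_gap_bp)
    cluster <- cumsum(new_cluster)
    for (cl in unique(cluster)) {
      members <- idx[cluster == cl]
      a$region_id[members] <- sprintf("%s_chr%s_%03d",
                                      gsub("\\s+", "_", a$disease[members[1]]),
                                      a$chrom[members[1]], cl)
      p <- a$p_discovery[members]
      best <- members[order(p, a$pos_bp[members])][1]
      keep[best] <- TRUE
    }
  }
  drop_idx <- which(!keep)
  if (length(drop_idx)) {
    excl <- rbind(excl, data.frame(snp_id = a$snp_id[drop_idx],
                                   reason = "region_pruned",
                                   stringsAsFactors = FALSE))
    a <- a[-drop_idx, , drop = FALSE]
  }
  rownames(a) <- NULL
  list(associations = a, excluded = excl)
}

#' Reference an odds ratio to the discovery risk allele
#'
#' Orients a reported odds ratio to the allele that was the risk allele in
#' the discovery study. When the reporting allele differs, the OR is
#' inverted (an OR of 2 for one allele is an OR of 0.5 for the other) and
#' the \code{shift} flag is set. The operation is an involution: applying
#' the shift twice returns the original OR.
#'
#' @param or positive odds ratio(s) as reported.
#' @param reported_allele allele the reported OR refers to.
#' @param risk_allele discovery risk allele.
#' @return data.frame with \code{or} (oriented), \code{log_or},
#'   \code{shift} and \code{direction_same} (\code{NA} when OR is exactly 1,
#'   where direction is undefined).
#' @export
reference_risk_allele <- function(or, reported_allele, risk_allele) {
  if (any(!is.finite(or) | or <= 0)) stop("'or' must be > 0", call. = FALSE)
  n <- max(length(or), length(reported_allele), length(risk_allele))
  or <- rep_len(or, n)
  shift <- rep_len(as.character(reported_allele), n) !=
    rep_len(as.character(risk_allele), n)
  or_out <- ifelse(shift, 1 / or, or)
  log_or <- log(or_out)
  direction_same <- ifelse(or_out == 1, NA, log_or > 0)
  data.frame(or = or_out, log_or = log_or, shift = shift,
             direction_same = direction_same)
}

#' Select a deterministic subset of replication attempts
#'
#' Implements the attempt-filtering used to guard replicability estimates
#' against SNPs that accrued many attempts: keep all attempts, the largest
#' attempt per SNP (by total sample size), the most-powered attempt per SNP,
#' or the most-powered attempt per genomic region. Ties are broken by larger
#' total sample size, then lexicographic study id.
#'
#' @param attempts attempts data.frame.
#' @param mode one of \code{"all"}, \code{"largest_per_snp"},
#'   \code{"most_powered_per_snp"}, \code{"most_powered_per_region"}.
#' @param associations associations data.frame with \code{region_id};
#'   required for \code{most_powered_per_region}.
#' @return the selected subset of \code{attempts}.
#' @export
select_attempts <- function(attempts,
                            mode = c("all", "largest_per_snp",
                                     "most_powered_per_snp",
                                     "most_powered_per_region"),
                            associations = NULL) {
  mode <- match.arg(mode)
  if (mode == "all") return(attempts)
  total_n <- attempts$n_cases + attempts$n_controls
  if (mode == "largest_per_snp") {
    key <- attempts$snp_id
    primary <- total_n
  } else {
    if (is.null(attempts$power) || anyNA(attempts$power)) {
      stop("mode '", mode, "' requires a filled 'power' column", call. = FALSE)
    }
    primary <- attempts$power
    if (mode == "most_powered_per_snp") {
      key <- attempts$snp_id
    } else {
      if (is.null(associations) || is.null(associations$region_id)) {
        stop("mode 'most_powered_per_region' requires associations with region_id",
             call. = FALSE)
      }
      key <- associations$region_id[match(attempts$snp_id, associations$snp_id)]
      if (anyNA(key)) stop("attempt snp_id missing from associations", call. = FALSE)
    }
  }
  ord <- order(key, -primary, -total_n, attempts$replication_study_id)
  sorted <- attempts[ord, , drop = FALSE]
  sel <- sorted[!duplicated(key[ord]), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Derive the replication-success flag
#'
#' A replication attempt is successful when the same risk allele as in the
#' discovery study reaches the significance threshold: the
#' discovery-referenced replication OR exceeds 1 and
#' \code{p_replication < alpha}.
#'
#' @param attempts attempts data.frame (\code{or_replication} referenced to
#'   the discovery risk allele).
#' @param alpha replication significance threshold.
#' @return \code{attempts} with the \code{success} column (re)computed.
#' @export
flag_success <- function(attempts, alpha = 0.05) {
  check_fraction(alpha, "alpha")
  attempts$success <- !is.na(attempts$p_replication) &
    !is.na(attempts$or_replication) &
    attempts$or_replication > 1 & attempts$p_replication < alpha
  attempts
}
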