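# Phased haplotype panel container and VCF / sidecar I/O.

#' Construct a phased haplotype panel
#'
#' A panel stores phased binary alleles for one population as a matrix with
#' one row per haplotype (two consecutive rows per diploid individual) and
#' one column per SNP, plus SNP coordinates. Entries are 0/1 (\code{NA} for
#' missing); SNP positions must be strictly increasing.
#'
#' @param alleles numeric/integer matrix, 2 * n_individuals rows, one
#'   column per SNP.
#' @param snp data.frame with \code{snp_id}, \code{chrom}, \code{pos_bp}
#'   (and optionally \code{ref_allele}, \code{alt_allele}).
#' @param sample_ids character vector of individual ids
#'   (length \code{nrow(alleles)/2}).
#' @param population population label.
#' @return object of class \code{hap_panel}.
#' @export
hap_panel <- function(alleles, snp, sample_ids, population) {
  alleles <- as.matrix(alleles)
  if (nrow(alleles) %% 2 != 0) {
    stop("haplotype count must be even (diploid individuals)", call. = FALSE)
  }
  if (length(sample_ids) != nrow(alleles) / 2) {
    stop("need one sample id per diploid individual", call. = FALSE)
  }
  if (ncol(alleles) != nrow(snp)) {
    stop("allele matrix and SNP table disagree on SNP count", call. = FALSE)
  }
  vals <- alleles[!is.na(alleles)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("allele entries must be 0, 1 or NA", call. = FALSE)
  }
  if (is.unsorted(snp$pos_bp, strictly = TRUE)) {
    stop("SNP positions must be strictly increasing", call. = FALSE)
  }
  structure(list(alleles = alleles, snp = as.data.frame(snp),
                 sample_ids = as.character(sample_ids),
                 population = population),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel '%s': %d individuals (%d haplotypes) x %d SNPs\n",
              x$population, length(x$sample_ids), nrow(x$alleles),
              ncol(x$alleles)))
  invisible(x)
}

n_individuals <- function(panel) length(panel$sample_ids)

# Per-SNP sample allele frequency (of the "1" allele) over haplotypes.
allele_freq <- function(panel) colMeans(panel$alleles, na.rm = TRUE)

#' Per-SNP expected heterozygosity
#'
#' \eqn{2p(1-p)} from the sample allele frequency of each SNP.
#'
#' @param panel a \code{\link{hap_panel}}.
#' @return numeric vector, one value per SNP.
#' @export
heterozygosity <- function(panel) {
  p <- allele_freq(panel)
  2 * p * (1 - p)
}

#' Write haplotype panels as a minimal phased VCF plus population sidecar
#'
#' Emits a VCFv4.2 file with phased \code{GT} fields (\code{|} separator)
#' for the individuals of one or two panels sharing a SNP map, and a
#' two-column sidecar file (\code{sample_id} TAB \code{population}).
#'
#' @param panels a single \code{\link{hap_panel}} or list of panels with
#'   identical SNP tables.
#' @param vcf_path output VCF path.
#' @param pops_path output sidecar path (default: \code{vcf_path} with a
#'   \code{.pops.tsv} suffix).
#' @return named vector of the two paths, invisibly.
#' @export
write_hap_vcf <- function(panels, vcf_path,
                          pops_path = paste0(vcf_path, ".pops.tsv")) {
  if (inherits(panels, "hap_panel")) panels <- list(panels)
  snp <- panels[[1]]$snp
  for (p in panels) {
    if (!identical(p$snp$snp_id, snp$snp_id)) {
      stop("panels must share the same SNP map", call. = FALSE)
    }
  }
  ref <- snp$ref_allele %||% rep("A", nrow(snp))
  alt <- snp$alt_allele %||% rep("G", nrow(snp))
  samples <- unlist(lapply(panels, function(p) p$sample_ids))
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids across panels", call. = FALSE)
  }
  gt_blocks <- lapply(panels, function(p) {
    a <- p$alleles
    ch <- matrix(as.character(a), nrow = nrow(a))
    ch[is.na(a)] <- "."
    hap1 <- ch[seq(1, nrow(a), by = 2), , drop = FALSE]
    hap2 <- ch[seq(2, nrow(a), by = 2), , drop = FALSE]
    # SNPs x individuals
    matrix(paste(t(hap1), t(hap2), sep = "|"), nrow = ncol(a))
  })
  gt <- do.call(cbind, gt_blocks)
  body <- cbind(as.character(snp$chrom), as.character(snp$pos_bp),
                snp$snp_id, ref, alt, ".", "PASS", ".", "GT", gt)
  con <- file(vcf_path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=transrep%s", transrep_version()),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  pops <- data.frame(
    sample_id = samples,
    population = unlist(lapply(panels, function(p)
      rep(p$population, n_individuals(p)))))
  utils::write.table(pops, pops_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf_path, pops = pops_path))
}

#' Read phased haplotype panels from a VCF and population sidecar
#'
#' Parses a phased VCF (via \pkg{vcfR}) and splits the samples into one
#' \code{\link{hap_panel}} per population according to the sidecar file.
#' Unphased genotypes (\code{/} separator) are an error.
#'
#' @param vcf_path VCF file with phased GT fields.
#' @param pops_path sidecar TSV (\code{sample_id} TAB \code{population}).
#' @return named list of \code{\link{hap_panel}} objects, one per
#'   population, in sidecar order.
#' @export
read_hap_panels <- function(vcf_path, pops_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snp <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                    pos_bp = as.integer(fix$POS),
                    ref_allele = fix$REF, alt_allele = fix$ALT)
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotypes found; phased '|' GT required", call. = FALSE)
  }
  pops <- utils::read.delim(pops_path, colClasses = "character")
  missing_s <- setdiff(pops$sample_id, colnames(gt))
  if (length(missing_s)) {
    stop("sidecar samples absent from VCF: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  parse_pop <- function(ids, pop) {
    sub <- gt[, ids, drop = FALSE]
    n_snp <- nrow(sub)
    hap <- matrix(NA_real_, nrow = 2 * length(ids), ncol = n_snp)
    for (i in seq_along(ids)) {
      parts <- strsplit(sub[, i], "|", fixed = TRUE)
      h1 <- vapply(parts, `[`, character(1), 1)
      h2 <- vapply(parts, `[`, character(1), 2)
      hap[2 * i - 1, ] <- suppressWarnings(as.numeric(h1))
      hap[2 * i, ] <- suppressWarnings(as.numeric(h2))
    }
    hap_panel(hap, snp, ids, pop)
  }
  out <- lapply(split(pops$sample_id, pops$population)[unique(pops$population)],
                function(ids) NULL)
  for (pop in unique(pops$population)) {
    out[[pop]] <- parse_pop(pops$sample_id[pops$population == pop], pop)
  }
  out
}
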