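# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used throughout the package: ties round away from zero
#' (so 11.25 -> 11.3 at one decimal), unlike \code{round()}'s round-half-even.
#' Raw, unrounded values are always kept alongside displayed ones.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic sub-stream seed derivation; stays below 2^31-1.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 1e6) * 1009 + 7919 * as.numeric(offset)
  as.integer(s %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strict numeric parsing for TSV columns: refuses locale dialects such as
# comma decimals instead of silently coercing them to NA.
strict_numeric <- function(x, column, na_string = ".") {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  miss <- is.na(x) | x == na_string | x == ""
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
  bad <- which(!miss & !ok)
  if (length(bad)) {
    stop(sprintf("column '%s': non-numeric value '%s' at row %d",
                 column, x[bad[1]], bad[1]), call. = FALSE)
  }
  out[!miss] <- as.numeric(x[!miss])
  out
}

strict_logical <- function(x, column, na_string = ".") {
  x <- as.character(x)
  out <- rep(NA, length(x))
  miss <- is.na(x) | x == na_string | x == ""
  up <- toupper(x)
  true_set <- c("TRUE", "T", "1", "Y", "YES")
  false_set <- c("FALSE", "F", "0", "N", "NO")
  bad <- which(!miss & !(up %in% c(true_set, false_set)))
  if (length(bad)) {
    stop(sprintf("column '%s': non-logical value '%s' at row %d",
                 column, x[bad[1]], bad[1]), call. = FALSE)
  }
  out[!miss] <- up[!miss] %in% true_set
  out
}

strict_integer <- function(x, column, na_string = ".") {
  v <- strict_numeric(x, column, na_string)
  bad <- which(!is.na(v) & v != round(v))
  if (length(bad)) {
    stop(sprintf("column '%s': non-integer value at row %d", column, bad[1]),
         call. = FALSE)
  }
  as.integer(round(v))
}

# TSV writer: "." for missing, optional "# " comment header lines.
write_tsv <- function(df, path, comments = character()) {
  out <- df
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v)) {
      v <- vapply(v, function(x) format(x, digits = 15, trim = TRUE,
                                        scientific = NA), character(1))
    }
    v <- as.character(v)
    v[is.na(df[[j]])] <- "."
    out[[j]] <- v
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, colClasses = "character", comment.char = "#",
                    check.names = FALSE, na.strings = NULL,
                    stringsAsFactors = FALSE)
}

# Stable short hash of an R object (used to stamp output tables).
config_hash <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  substr(unname(tools::md5sum(f)), 1, 12)
}

transrep_version <- function() {
  as.character(utils::packageVersion("transrep"))
}

output_comments <- function(config = NULL) {
  c(sprintf("transrep %s", transrep_version()),
    if (!is.null(config)) sprintf("config_hash=%s", config_hash(config)))
}

check_fraction <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (any(!is.finite(x) | !lo_ok | !hi_ok)) {
    stop(sprintf("'%s' must lie in %s0,1%s", name,
                 if (open_left) "(" else "[", if (open_right) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  bad <- !is.finite(x) | x != round(x) | (if (positive) x <= 0 else x < 0)
  if (any(bad)) {
    stop(sprintf("'%s' must be %s integer(s)", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(as.integer(round(x)))
}
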