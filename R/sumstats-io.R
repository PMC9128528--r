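# Reading, validating and writing GWAS summary statistics, harmonized
# instrument tables, and pairwise-LD references. All tabular formats are
# plain TSV with a header row.

SUMSTAT_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")

HARMONIZED_COLS <- c("snp", "ea", "oa", "eaf", "beta_exp", "se_exp", "p_exp",
                     "beta_out", "se_out", "p_out", "flags")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Validate a table of GWAS summary statistics
#'
#' Every row is either accepted or rejected with a machine-readable reason;
#' the two sets always partition the input. Variants must be biallelic SNVs
#' (single-base A/C/G/T alleles); indels and multi-base alleles are rejected
#' because strand and palindrome logic downstream is defined only for SNVs.
#'
#' @param df data.frame with columns `snp, chr, pos, ea, oa, eaf, beta, se, p, n`.
#' @return list with `records` (validated rows, alleles upper-cased) and
#'   `rejected` (data.frame with `row`, `snp`, `reason`).
#' @details Required per-row conditions: alleles are single characters in
#'   A/C/G/T and differ from one another; `0 < eaf < 1`; `se > 0`;
#'   `0 < p <= 1`; `n > 0`. Duplicated `snp` identifiers among accepted rows
#'   are an error (summary statistics for one trait must be unique per SNP).
#' @export
validate_sumstats <- function(df) {
  missing_cols <- setdiff(SUMSTAT_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, SUMSTAT_COLS, drop = FALSE]
  df$snp <- as.character(df$snp)
  df$chr <- as.character(df$chr)
  df$ea <- toupper(as.character(df$ea))
  df$oa <- toupper(as.character(df$oa))
  for (col in c("pos", "eaf", "beta", "se", "p", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  n <- nrow(df)
  reasons <- vector("list", n)
  note <- function(i, why) reasons[[i]] <<- c(reasons[[i]], why)
  for (i in seq_len(n)) {
    if (is.na(df$snp[i]) || !nzchar(df$snp[i])) note(i, "missing snp id")
    if (!(df$ea[i] %in% VALID_ALLELES) || !(df$oa[i] %in% VALID_ALLELES)) {
      note(i, "not a biallelic SNV")
    } else if (df$ea[i] == df$oa[i]) {
      note(i, "identical alleles")
    }
    if (is.na(df$pos[i]) || df$pos[i] < 1) note(i, "invalid position")
    if (is.na(df$eaf[i]) || df$eaf[i] <= 0 || df$eaf[i] >= 1) note(i, "eaf out of range")
    if (is.na(df$beta[i]) || !is.finite(df$beta[i])) note(i, "missing beta")
    if (is.na(df$se[i]) || df$se[i] <= 0) note(i, "se not positive")
    if (is.na(df$p[i]) || df$p[i] <= 0 || df$p[i] > 1) note(i, "pvalue out of range")
    if (is.na(df$n[i]) || df$n[i] <= 0) note(i, "n not positive")
  }

  bad <- vapply(reasons, function(r) length(r) > 0, logical(1))
  rejected <- data.frame(
    row = which(bad),
    snp = df$snp[bad],
    reason = vapply(reasons[bad], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE
  )
  records <- df[!bad, , drop = FALSE]
  dup <- unique(records$snp[duplicated(records$snp)])
  if (length(dup) > 0) {
    stop("duplicate snp id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  records$pos <- as.integer(round(records$pos))
  records$n <- as.integer(round(records$n))
  rownames(records) <- NULL
  list(records = records, rejected = rejected)
}

#' Read GWAS summary statistics from a TSV file
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect optional named character vector mapping the canonical column
#'   names (`snp, chr, pos, ea, oa, eaf, beta, se, p, n`) to the headers used
#'   in the file, e.g. `c(snp = "rsid", p = "pval")`. Unmapped names are
#'   assumed canonical.
#' @return as [validate_sumstats()]: list with `records` and `rejected`.
#' @export
read_sumstats <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), SUMSTAT_COLS)
    if (length(bad) > 0) stop("unknown dialect key(s): ", paste(bad, collapse = ", "),
                              call. = FALSE)
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw)) {
        stop("missing required column(s): ", src, " (mapped to ", canon, ")",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  validate_sumstats(raw)
}

#' Write summary statistics to TSV
#'
#' @param records data.frame of validated records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  utils::write.table(records[, SUMSTAT_COLS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a pairwise-LD reference
#'
#' Stores r-squared values between SNP pairs with symmetric closure; any pair
#' not listed is treated as unlinked (r2 = 0, conservative for clumping on a
#' sparse reference) and self-pairs are always 1.
#'
#' @param pairs data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @param positions optional data.frame with columns `snp`, `chr`, `pos`.
#' @return an object of class `ld_ref`.
#' @export
ld_reference <- function(pairs = NULL, positions = NULL) {
  env <- new.env(parent = emptyenv())
  snps <- character(0)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
    r2 <- as.numeric(pairs$r2)
    if (any(is.na(r2) | r2 < 0 | r2 > 1)) {
      stop("r2 values must lie in [0, 1]", call. = FALSE)
    }
    a <- as.character(pairs$snp_a)
    b <- as.character(pairs$snp_b)
    for (i in seq_along(a)) {
      if (a[i] == b[i]) next  # self-pairs forced to 1 by lookup
      key <- if (a[i] < b[i]) paste(a[i], b[i], sep = "\r") else paste(b[i], a[i], sep = "\r")
      assign(key, r2[i], envir = env)
    }
    snps <- unique(c(a, b))
  }
  structure(list(env = env, snps = snps, positions = positions), class = "ld_ref")
}

#' Look up pairwise r-squared in an LD reference
#'
#' @param ld an `ld_ref` object.
#' @param a single SNP id.
#' @param b character vector of SNP ids.
#' @return numeric vector of r2 values; 1 for self pairs, 0 for unlisted pairs.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_ref"), length(a) == 1)
  vapply(b, function(bi) {
    if (bi == a) return(1)
    key <- if (a < bi) paste(a, bi, sep = "\r") else paste(bi, a, sep = "\r")
    if (exists(key, envir = ld$env, inherits = FALSE)) {
      get(key, envir = ld$env)
    } else 0
  }, numeric(1), USE.NAMES = FALSE)
}

#' @export
print.ld_ref <- function(x, ...) {
  cat("LD reference:", length(x$snps), "SNPs,",
      length(ls(x$env)), "stored pairs\n")
  invisible(x)
}

#' Read a pairwise-LD table
#'
#' @param path TSV with columns `snp_a`, `snp_b`, `r2`.
#' @return an `ld_ref` object. An empty file yields an empty reference in
#'   which every query returns 0.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("snp_a", "snp_b", "r2"), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ld_reference(raw)
}

#' Write an LD reference to TSV
#'
#' @param ld an `ld_ref` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  keys <- ls(ld$env)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    snp_a = vapply(parts, `[`, character(1), 1),
    snp_b = vapply(parts, `[`, character(1), 2),
    r2 = vapply(keys, function(k) get(k, envir = ld$env), numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$snp_a, out$snp_b), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a harmonized instrument table to TSV
#'
#' Columns: `snp, ea, oa, eaf, beta_exp, se_exp, p_exp, beta_out, se_out,
#' p_out, flags` (`eaf` is the exposure-study effect-allele frequency; flags
#' is a comma-separated subset of `flipped`, `palindromic`, `proxy`).
#'
#' @param ivs harmonized instrument data.frame (from [harmonize_tables()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(ivs, path) {
  out <- data.frame(
    snp = ivs$snp, ea = ivs$ea, oa = ivs$oa, eaf = ivs$eaf_exp,
    beta_exp = ivs$beta_exp, se_exp = ivs$se_exp, p_exp = ivs$p_exp,
    beta_out = ivs$beta_out, se_out = ivs$se_out, p_out = ivs$p_out,
    flags = ivs$flags, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a harmonized instrument table from TSV
#'
#' @param path TSV in the layout written by [write_harmonized()].
#' @return harmonized instrument data.frame with internal column names
#'   (`eaf_exp` for the `eaf` column).
#' @export
read_harmonized <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(flags = "character"))
  missing_cols <- setdiff(HARMONIZED_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(raw$se_exp <= 0) || any(raw$se_out <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  data.frame(
    snp = as.character(raw$snp), ea = toupper(raw$ea), oa = toupper(raw$oa),
    eaf_exp = raw$eaf, beta_exp = raw$beta_exp, se_exp = raw$se_exp,
    p_exp = raw$p_exp, beta_out = raw$beta_out, se_out = raw$se_out,
    p_out = raw$p_out,
    flags = ifelse(is.na(raw$flags), "", as.character(raw$flags)),
    stringsAsFactors = FALSE
  )
}
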