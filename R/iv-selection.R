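# Instrument-selection funnel: significance filtering, greedy LD clumping,
# proxy substitution, exclusion on secondary traits, and allele harmonization
# of exposure-outcome record pairs.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Instrument-selection configuration
#'
#' Thresholds for the instrument-selection funnel. Defaults follow common
#' two-sample MR practice for large GWAS: genome-wide significance 5e-8 for
#' exposure association, clumping at r2 < 0.001 within a 10 kb window keeping
#' the lowest p-value per locus, exclusion of instruments showing suggestive
#' (p < 1e-5) association with the outcome or a confounder, proxy search at
#' r2 > 0.8, and frequency alignment of palindromic SNPs only when the minor
#' allele frequency is below 0.3 in both studies.
#'
#' @param p_exposure exposure-association significance cutoff.
#' @param clump_r2 r-squared at or above which two nearby SNPs are considered
#'   dependent during clumping.
#' @param clump_kb clumping window, kilobases; distances are inclusive on both
#'   ends and positions are 1-based.
#' @param p_outcome_exclude instruments with outcome association below this
#'   p-value are removed (direct-pleiotropy guard).
#' @param p_confounder_exclude as above, for confounder tables.
#' @param proxy_r2_min minimum r-squared (strict) for proxy substitution.
#' @param palindrome_maf_max palindromic SNPs are frequency-aligned only when
#'   MAF is below this in both studies; otherwise dropped as ambiguous.
#' @return a list of class `selection_config`.
#' @export
selection_config <- function(p_exposure = 5e-8,
                             clump_r2 = 0.001,
                             clump_kb = 10,
                             p_outcome_exclude = 1e-5,
                             p_confounder_exclude = 1e-5,
                             proxy_r2_min = 0.8,
                             palindrome_maf_max = 0.3) {
  cfg <- list(p_exposure = p_exposure, clump_r2 = clump_r2, clump_kb = clump_kb,
              p_outcome_exclude = p_outcome_exclude,
              p_confounder_exclude = p_confounder_exclude,
              proxy_r2_min = proxy_r2_min,
              palindrome_maf_max = palindrome_maf_max)
  thr <- unlist(cfg[c("p_exposure", "clump_r2", "p_outcome_exclude",
                      "p_confounder_exclude", "proxy_r2_min",
                      "palindrome_maf_max")])
  if (any(thr <= 0 | thr >= 1)) stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (clump_kb <= 0) stop("clump_kb must be positive", call. = FALSE)
  class(cfg) <- "selection_config"
  cfg
}

#' Filter records to those significantly associated with the exposure
#'
#' @param records validated summary-statistic data.frame.
#' @param cfg a [selection_config()].
#' @return the records with `p < cfg$p_exposure`, original order preserved.
#' @export
select_significant <- function(records, cfg) {
  records[records$p < cfg$p_exposure, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Repeatedly retains the unprocessed record with the lowest p-value (ties
#' broken by SNP id) and discards every unprocessed record on the same
#' chromosome within `clump_kb` whose r-squared with the retained SNP is at
#' least `clump_r2`. The retained set is mutually independent under the
#' (r2, window) rule.
#'
#' @param records significance-filtered summary-statistic data.frame.
#' @param ld an `ld_ref` object; unlisted pairs count as unlinked.
#' @param cfg a [selection_config()].
#' @return the retained records, ordered by ascending p-value.
#' @export
clump_snps <- function(records, ld, cfg) {
  if (nrow(records) == 0) return(records)
  ord <- order(records$p, records$snp)
  records <- records[ord, , drop = FALSE]
  n <- nrow(records)
  window_bp <- cfg$clump_kb * 1000
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & records$chr == records$chr[i] &
                    abs(records$pos - records$pos[i]) <= window_bp)
    if (length(cand) > 0) {
      r2 <- ld_r2(ld, records$snp[i], records$snp[cand])
      alive[cand[r2 >= cfg$clump_r2]] <- FALSE
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find a proxy for an instrument missing from the outcome study
#'
#' Among candidate records, returns the one with maximal r-squared to the
#' target, provided it exceeds `proxy_r2_min` (strictly); ties are broken by
#' lower p-value, then SNP id. The candidate's own exposure association is
#' required — the target's association is never transplanted onto the proxy.
#'
#' @param target SNP id absent from the outcome table.
#' @param available data.frame of candidate exposure records (those present
#'   in the outcome table).
#' @param ld an `ld_ref` object.
#' @param cfg a [selection_config()].
#' @return the selected one-row data.frame, or `NULL` when no candidate
#'   qualifies.
#' @export
find_proxy <- function(target, available, ld, cfg) {
  if (nrow(available) == 0) return(NULL)
  r2 <- ld_r2(ld, target, available$snp)
  ok <- r2 > cfg$proxy_r2_min & available$snp != target
  if (!any(ok)) return(NULL)
  cand <- available[ok, , drop = FALSE]
  r2 <- r2[ok]
  ord <- order(-r2, cand$p, cand$snp)
  out <- cand[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude instruments associated with a secondary trait
#'
#' An instrument is removed iff it appears in `trait_stats` with a p-value
#' below `p_cut`; instruments absent from the trait table are kept. Used both
#' for direct outcome pleiotropy and for confounder traits.
#'
#' @param ivs data.frame of candidate instruments.
#' @param trait_stats summary statistics for the secondary trait.
#' @param p_cut exclusion p-value threshold.
#' @return list with `kept` and `removed` data.frames; they partition `ivs`.
#' @export
exclude_by_trait <- function(ivs, trait_stats, p_cut) {
  idx <- match(ivs$snp, trait_stats$snp)
  p_trait <- trait_stats$p[idx]
  remove <- !is.na(idx) & p_trait < p_cut
  list(kept = ivs[!remove, , drop = FALSE],
       removed = ivs[remove, , drop = FALSE])
}

is_palindromic_pair <- function(a, b) COMPLEMENT[[a]] == b

#' Harmonize one exposure-outcome record pair onto a shared effect allele
#'
#' Aligns the outcome association to the exposure's effect allele, covering
#' the four situations that arise with biallelic SNVs: identical alleles
#' (pass-through), swapped alleles (negate the outcome beta and complement
#' its frequency), opposite-strand reporting (strand-flip the outcome alleles
#' first), and palindromic A/T or C/G variants, which are alignable only via
#' allele frequency and only when the minor allele frequency is below
#' `cfg$palindrome_maf_max` in both studies. Non-concordant allele sets and
#' ambiguous palindromes are dropped with a reason, never silently.
#'
#' @param exp one-row exposure record.
#' @param out one-row outcome record for the same SNP.
#' @param cfg a [selection_config()].
#' @return list with either `iv` (one-row harmonized data.frame, `reason =
#'   NULL`) or `iv = NULL` and a character `reason`
#'   (`"ambiguous palindrome"` or `"non-concordant"`).
#' @export
harmonize_pair <- function(exp, out, cfg) {
  stopifnot(exp$snp == out$snp)
  e_ea <- exp$ea; e_oa <- exp$oa
  o_ea <- out$ea; o_oa <- out$oa
  beta_out <- out$beta; eaf_out <- out$eaf
  flags <- ""
  dropped <- function(reason) list(iv = NULL, reason = reason)

  if (is_palindromic_pair(e_ea, e_oa)) {
    # strand flips are unresolvable from alleles: both strands show the same
    # pair, so alignment must come from allele frequency
    if (!setequal(c(o_ea, o_oa), c(e_ea, e_oa))) return(dropped("non-concordant"))
    flags <- add_flag(flags, "palindromic")
    if (o_ea == e_oa) {  # label swap first
      beta_out <- -beta_out
      eaf_out <- 1 - eaf_out
      flags <- add_flag(flags, "flipped")
    }
    maf_exp <- min(exp$eaf, 1 - exp$eaf)
    maf_out <- min(eaf_out, 1 - eaf_out)
    if (maf_exp >= cfg$palindrome_maf_max || maf_out >= cfg$palindrome_maf_max) {
      return(dropped("ambiguous palindrome"))
    }
    if ((exp$eaf < 0.5) != (eaf_out < 0.5)) {
      # frequencies disagree on which allele is minor: the outcome study
      # reported the opposite strand, so its labelled effect allele is
      # actually the other allele
      beta_out <- -beta_out
      eaf_out <- 1 - eaf_out
      flags <- add_flag(flags, "flipped")
    }
  } else if (o_ea == e_ea && o_oa == e_oa) {
    # already aligned
  } else if (o_ea == e_oa && o_oa == e_ea) {
    beta_out <- -beta_out
    eaf_out <- 1 - eaf_out
    flags <- add_flag(flags, "flipped")
  } else {
    oc_ea <- COMPLEMENT[[o_ea]]; oc_oa <- COMPLEMENT[[o_oa]]
    if (oc_ea == e_ea && oc_oa == e_oa) {
      # opposite strand, same orientation: no numeric change
    } else if (oc_ea == e_oa && oc_oa == e_ea) {
      beta_out <- -beta_out
      eaf_out <- 1 - eaf_out
      flags <- add_flag(flags, "flipped")
    } else {
      return(dropped("non-concordant"))
    }
  }

  iv <- data.frame(
    snp = exp$snp, ea = e_ea, oa = e_oa,
    eaf_exp = exp$eaf, beta_exp = exp$beta, se_exp = exp$se, p_exp = exp$p,
    eaf_out = eaf_out, beta_out = beta_out, se_out = out$se, p_out = out$p,
    n_exp = exp$n, n_out = out$n, flags = flags,
    stringsAsFactors = FALSE
  )
  list(iv = iv, reason = NULL)
}

#' Harmonize matching rows of an exposure and an outcome table
#'
#' Applies [harmonize_pair()] to every SNP present in both tables.
#'
#' @param exp_df exposure summary statistics.
#' @param out_df outcome summary statistics.
#' @param cfg a [selection_config()].
#' @param proxy_snps optional character vector of SNP ids to flag as proxies.
#' @return list with `ivs` (harmonized data.frame) and `dropped` (data.frame
#'   `snp`, `reason`; SNPs absent from the outcome table appear with reason
#'   `"missing from outcome"`).
#' @export
harmonize_tables <- function(exp_df, out_df, cfg, proxy_snps = character(0)) {
  ivs <- list()
  drop_snp <- character(0)
  drop_reason <- character(0)
  out_idx <- match(exp_df$snp, out_df$snp)
  for (i in seq_len(nrow(exp_df))) {
    j <- out_idx[i]
    if (is.na(j)) {
      drop_snp <- c(drop_snp, exp_df$snp[i])
      drop_reason <- c(drop_reason, "missing from outcome")
      next
    }
    h <- harmonize_pair(exp_df[i, , drop = FALSE], out_df[j, , drop = FALSE], cfg)
    if (is.null(h$iv)) {
      drop_snp <- c(drop_snp, exp_df$snp[i])
      drop_reason <- c(drop_reason, h$reason)
    } else {
      if (h$iv$snp %in% proxy_snps) h$iv$flags <- add_flag(h$iv$flags, "proxy")
      ivs[[length(ivs) + 1]] <- h$iv
    }
  }
  iv_df <- if (length(ivs) > 0) do.call(rbind, ivs) else
    data.frame(snp = character(0), ea = character(0), oa = character(0),
               eaf_exp = numeric(0), beta_exp = numeric(0), se_exp = numeric(0),
               p_exp = numeric(0), eaf_out = numeric(0), beta_out = numeric(0),
               se_out = numeric(0), p_out = numeric(0), n_exp = integer(0),
               n_out = integer(0), flags = character(0),
               stringsAsFactors = FALSE)
  rownames(iv_df) <- NULL
  list(ivs = iv_df,
       dropped = data.frame(snp = drop_snp, reason = drop_reason,
                            stringsAsFactors = FALSE))
}
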