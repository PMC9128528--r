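# Study orchestration: the per-trait instrument funnel, method selection by
# instrument count, the estimator and diagnostic suite, multiple-testing
# correction, the headline decision rule, bidirectional analysis with MHC
# exclusion, and forest-table export.

#' Choose the estimators to run for a given instrument count
#'
#' With a single instrument only the Wald ratio is defined; with two, IVW
#' and the cML estimator; from three instruments the full suite runs
#' (IVW, weighted median, MR-Egger, cML), and the simulation-based outlier
#' test additionally requires four.
#'
#' @param n_iv number of harmonized instruments.
#' @return character vector of method names (possibly empty).
#' @export
select_methods <- function(n_iv) {
  if (n_iv <= 0) return(character(0))
  if (n_iv == 1) return("wald")
  if (n_iv == 2) return(c("ivw", "cml"))
  out <- c("ivw", "weighted_median", "egger", "cml")
  if (n_iv >= 4) out <- c(out, "presso")
  out
}

# the per-trait funnel + analysis; returns a trait_report
analyze_trait <- function(trait, exp_df, out_df, confounders, ld, cfg,
                          bonferroni_alpha, mhc_region = NULL,
                          n_boot = 1000, n_sim = 1000, seed = 42,
                          n_eff = NULL) {
  stages <- c(input = nrow(exp_df))

  sig <- select_significant(exp_df, cfg)
  stages["significant"] <- nrow(sig)

  mhc_excluded <- 0L
  if (!is.null(mhc_region)) {
    inside <- sig$chr == as.character(mhc_region$chrom) &
      sig$pos >= mhc_region$start & sig$pos <= mhc_region$end
    mhc_excluded <- sum(inside)
    sig <- sig[!inside, , drop = FALSE]
    stages["non_mhc"] <- nrow(sig)
  }

  cl <- clump_snps(sig, ld, cfg)
  stages["clumped"] <- nrow(cl)

  # proxy substitution for clumped instruments missing from the outcome
  present <- cl$snp %in% out_df$snp
  available <- exp_df[exp_df$snp %in% out_df$snp &
                        !(exp_df$snp %in% cl$snp), , drop = FALSE]
  proxy_snps <- character(0)
  extra <- list()
  for (miss in cl$snp[!present]) {
    pr <- find_proxy(miss, available, ld, cfg)
    if (!is.null(pr)) {
      extra[[length(extra) + 1]] <- pr
      proxy_snps <- c(proxy_snps, pr$snp)
      available <- available[available$snp != pr$snp, , drop = FALSE]
    }
  }
  ivset <- rbind(cl[present, , drop = FALSE], do.call(rbind, extra))
  stages["in_outcome"] <- nrow(ivset)

  ex_out <- exclude_by_trait(ivset, out_df, cfg$p_outcome_exclude)
  ivset <- ex_out$kept
  stages["outcome_pleiotropy_filtered"] <- nrow(ivset)

  for (cf in confounders) {
    ex_cf <- exclude_by_trait(ivset, cf, cfg$p_confounder_exclude)
    ivset <- ex_cf$kept
  }
  stages["confounder_filtered"] <- nrow(ivset)

  harm <- harmonize_tables(ivset, out_df, cfg, proxy_snps = proxy_snps)
  ivs <- harm$ivs
  stages["harmonized"] <- nrow(ivs)

  n_iv <- nrow(ivs)
  methods <- select_methods(n_iv)

  estimates <- list()
  heterogeneity <- NULL
  egger_intercept <- NULL
  presso <- NULL
  loo <- NULL
  strength <- NULL

  if ("wald" %in% methods) {
    estimates$wald <- mr_wald_ratio(ivs)
  }
  if ("ivw" %in% methods) {
    estimates$ivw_mre <- mr_ivw(ivs, model = "random")
    estimates$ivw_fixed <- mr_ivw(ivs, model = "fixed")
    heterogeneity <- cochran_q(ivs)
  }
  if ("weighted_median" %in% methods) {
    estimates$weighted_median <- mr_weighted_median(ivs, n_boot = n_boot,
                                                    seed = seed)
  }
  if ("egger" %in% methods) {
    eg <- mr_egger(ivs)
    estimates$egger_slope <- eg$slope
    egger_intercept <- eg$intercept
  }
  if ("cml" %in% methods) {
    cml <- mr_cml(ivs, n_eff = n_eff, seed = seed)
    estimates$cml_bic <- cml$bic_est
    estimates$cml_ma <- cml$ma_est
  }
  if ("presso" %in% methods) {
    presso <- mr_presso(ivs, n_sim = n_sim, seed = seed)
    if (!is.null(presso$corrected)) estimates$presso_corrected <- presso$corrected
  }
  if (n_iv >= 3) loo <- leave_one_out(ivs)
  if (n_iv >= 1) strength <- instrument_strength(ivs)

  est_df <- if (length(estimates) > 0) {
    out <- do.call(rbind, estimates)
    rownames(out) <- NULL
    out
  } else NULL

  # headline estimate: IVW (multiplicative random effects), or the Wald
  # ratio when only one instrument survives
  headline <- estimates$ivw_mre %||% estimates$wald

  contradiction <- FALSE
  if (!is.null(headline)) {
    sens <- estimates[intersect(names(estimates),
                                c("weighted_median", "egger_slope",
                                  "cml_bic", "cml_ma", "presso_corrected"))]
    for (s in sens) {
      if (s$pvalue < 0.05 && sign(s$beta) != sign(headline$beta)) {
        contradiction <- TRUE
      }
    }
    if (!is.null(egger_intercept) && egger_intercept$pvalue < 0.05) {
      contradiction <- TRUE
    }
  }

  verdict <- if (n_iv == 0) {
    "insufficient"
  } else if (headline$pvalue < bonferroni_alpha && !contradiction) {
    "robust"
  } else if (headline$pvalue < 0.05) {
    "suggestive"
  } else {
    "null"
  }

  structure(list(
    trait = trait,
    stage_counts = stages,
    mhc_excluded = mhc_excluded,
    dropped = harm$dropped,
    estimates = est_df,
    headline = headline,
    heterogeneity = heterogeneity,
    egger_intercept = egger_intercept,
    presso = presso,
    loo = loo,
    strength = strength,
    ivs = ivs,
    bonferroni_alpha = bonferroni_alpha,
    contradiction = contradiction,
    verdict = verdict
  ), class = "trait_report")
}

#' @export
print.trait_report <- function(x, ...) {
  cat(sprintf("Trait: %s  [verdict: %s]\n", x$trait, x$verdict))
  cat("  funnel:", paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts),
                         collapse = " -> "), "\n")
  if (!is.null(x$headline)) {
    cat(sprintf("  headline (%s): OR %.3f (%.3f-%.3f), p = %.3g, %d IVs\n",
                x$headline$method, x$headline$or, x$headline$or_ci_low,
                x$headline$or_ci_high, x$headline$pvalue, x$headline$n_snp))
  }
  invisible(x)
}

#' Forward MR over a panel of exposure traits
#'
#' For each exposure: significance filter, LD clumping, proxy substitution
#' for instruments missing from the outcome, exclusion of instruments with
#' suggestive outcome or confounder association, allele harmonization, then
#' the estimator suite chosen by instrument count plus heterogeneity,
#' pleiotropy, outlier, influence, and strength diagnostics. The Bonferroni
#' level is 0.05 divided by the number of exposures in the run. A trait's
#' verdict is `"robust"` when the headline (IVW multiplicative random
#' effects, or Wald ratio with one instrument) passes Bonferroni with no
#' contradiction, `"suggestive"` at nominal significance, `"null"`
#' otherwise, and `"insufficient"` when no instrument survives; a
#' contradiction is any sensitivity estimator nominally significant with the
#' opposite sign, or a significant MR-Egger intercept.
#'
#' @param exposures named list of exposure summary-statistic data.frames.
#' @param outcome outcome summary-statistic data.frame.
#' @param confounders list of confounder summary-statistic data.frames.
#' @param ld an `ld_ref`.
#' @param cfg a [selection_config()].
#' @param n_boot,n_sim,seed settings for the bootstrap and simulation-based
#'   components.
#' @param n_eff optional effective sample size for the cML BIC penalty.
#' @return named list of `trait_report` objects.
#' @export
run_forward <- function(exposures, outcome, confounders = list(), ld,
                        cfg = selection_config(), n_boot = 1000, n_sim = 1000,
                        seed = 42, n_eff = NULL) {
  stopifnot(is.list(exposures), length(exposures) > 0)
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    stop("exposures must be a named list", call. = FALSE)
  }
  alpha <- 0.05 / length(exposures)
  reports <- lapply(names(exposures), function(tr) {
    analyze_trait(tr, exposures[[tr]], outcome, confounders, ld, cfg,
                  bonferroni_alpha = alpha, n_boot = n_boot, n_sim = n_sim,
                  seed = seed, n_eff = n_eff)
  })
  names(reports) <- names(exposures)
  reports
}

#' Reverse-direction MR with MHC exclusion
#'
#' Runs the identical funnel with the disease as exposure, excluding
#' instruments inside the major histocompatibility complex region before
#' clumping (its long-range LD and pervasive pleiotropy make MHC variants
#' unreliable instruments). The report records how many were excluded.
#'
#' @param outcome_as_exposure disease summary statistics, used as exposure.
#' @param target_trait summary statistics of the trait now analyzed as
#'   outcome.
#' @param mhc_region list with `chrom`, `start`, `end`; default
#'   chr6:25,000,000-35,000,000.
#' @param ld an `ld_ref`.
#' @param cfg a [selection_config()].
#' @param confounders,n_boot,n_sim,seed,n_eff,bonferroni_alpha as in
#'   [run_forward()]; the Bonferroni level defaults to 0.05 (single trait).
#' @return a `trait_report` with an `mhc_excluded` count.
#' @export
run_reverse <- function(outcome_as_exposure, target_trait,
                        mhc_region = list(chrom = "6", start = 25e6, end = 35e6),
                        ld, cfg = selection_config(), confounders = list(),
                        n_boot = 1000, n_sim = 1000, seed = 42, n_eff = NULL,
                        bonferroni_alpha = 0.05) {
  stopifnot(all(c("chrom", "start", "end") %in% names(mhc_region)),
            mhc_region$start <= mhc_region$end)
  analyze_trait("reverse", outcome_as_exposure, target_trait, confounders,
                ld, cfg, bonferroni_alpha = bonferroni_alpha,
                mhc_region = mhc_region, n_boot = n_boot, n_sim = n_sim,
                seed = seed, n_eff = n_eff)
}

#' Forest-plot table from trait reports
#'
#' One row per (trait, method): odds ratio, 95% CI bounds, p-value and
#' instrument count, plus the log-scale columns they are derived from.
#'
#' @param reports list of `trait_report` objects.
#' @return data.frame.
#' @export
forest_data <- function(reports) {
  if (inherits(reports, "trait_report")) reports <- list(reports)
  rows <- list()
  for (rep in reports) {
    if (is.null(rep$estimates)) next
    est <- rep$estimates
    rows[[length(rows) + 1]] <- data.frame(
      trait = rep$trait, method = est$method,
      beta = est$beta, se = est$se,
      or = est$or, or_ci_low = est$or_ci_low, or_ci_high = est$or_ci_high,
      pvalue = est$pvalue, n_snp = est$n_snp,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(trait = character(0), method = character(0),
                      beta = numeric(0), se = numeric(0), or = numeric(0),
                      or_ci_low = numeric(0), or_ci_high = numeric(0),
                      pvalue = numeric(0), n_snp = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
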