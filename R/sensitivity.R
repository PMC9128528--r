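# Heterogeneity, outlier, and influence diagnostics for a harmonized
# instrument set: Cochran's Q, the simulation-based residual-sum outlier
# test (MR-PRESSO), leave-one-out, and funnel/scatter table export.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (ratio_j - pooled)^2` over the per-SNP Wald ratios with
#' inverse-variance weights `w_j = (beta_exp_j / se_out_j)^2`, referred to a
#' chi-square with k-1 degrees of freedom. By default `pooled` is the
#' fixed-effect IVW estimate, which minimizes Q.
#'
#' @param ivs harmonized instrument data.frame with at least two rows.
#' @param pooled_beta pooled log-OR; defaults to the fixed-effect IVW beta.
#' @return list of class `heterogeneity` with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(ivs, pooled_beta = NULL) {
  k <- nrow(ivs)
  if (k < 2) stop_insufficient(2, k)
  ratio <- ivs$beta_out / ivs$beta_exp
  w <- (ivs$beta_exp / ivs$se_out)^2
  if (is.null(pooled_beta)) pooled_beta <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - pooled_beta)^2)
  structure(list(q = q, df = k - 1L,
                 pvalue = stats::pchisq(q, k - 1, lower.tail = FALSE)),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n", x$q, x$df, x$pvalue))
  invisible(x)
}

# leave-one-out fixed-effect IVW slopes from weighted totals
loo_betas <- function(x, y, w) {
  sxy <- sum(w * x * y)
  sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

#' Pleiotropy residual sum and outlier test (MR-PRESSO style)
#'
#' Global test: the observed residual sum of squares is computed with each
#' SNP predicted from the fixed-effect IVW fit that excludes it; the null
#' distribution comes from `n_sim` parametric simulations drawing each SNP's
#' exposure and outcome associations from their normal sampling distributions
#' under the leave-one-out fitted model. Per-SNP outliers are declared when a
#' SNP's observed weighted squared residual exceeds its simulated
#' distribution at `outlier_alpha` after Bonferroni correction over the k
#' instruments. When outliers are found, an outlier-removed IVW estimate is
#' returned together with a distortion test comparing the observed
#' full-vs-corrected shift against shifts from removing random subsets of the
#' same size.
#'
#' @param ivs harmonized instrument data.frame with at least four rows.
#' @param n_sim simulation replicates (at least 100).
#' @param seed RNG seed; the whole result is reproducible bitwise given
#'   (`seed`, `n_sim`).
#' @param outlier_alpha per-family outlier significance level before the
#'   Bonferroni correction; 0 disables outlier calls.
#' @return object of class `mr_presso`: `global_rss`, `global_pvalue`,
#'   `per_snp_pvalue` (named), `outliers`, `distortion_pvalue` (NULL when no
#'   outliers), `corrected` ([mr_estimate()] row or NULL), `n_sim`, `seed`.
#' @export
mr_presso <- function(ivs, n_sim = 1000, seed = 42, outlier_alpha = 0.05) {
  k <- nrow(ivs)
  if (k < 4) stop_insufficient(4, k)
  if (n_sim < 100) stop("n_sim must be at least 100", call. = FALSE)
  x <- ivs$beta_exp; y <- ivs$beta_out
  sx <- ivs$se_exp; sy <- ivs$se_out
  w <- 1 / sy^2

  b_loo <- loo_betas(x, y, w)
  res_obs <- y - b_loo * x
  rsq_obs <- w * res_obs^2
  rss_obs <- sum(rsq_obs)

  sim <- with_seed(seed, {
    xs <- matrix(stats::rnorm(n_sim * k, mean = rep(x, each = n_sim),
                              sd = rep(sx, each = n_sim)), nrow = n_sim)
    ys <- matrix(stats::rnorm(n_sim * k, mean = rep(b_loo * x, each = n_sim),
                              sd = rep(sy, each = n_sim)), nrow = n_sim)
    wm <- matrix(rep(w, each = n_sim), nrow = n_sim)
    wxy <- wm * xs * ys
    wx2 <- wm * xs^2
    b_loo_s <- (rowSums(wxy) - wxy) / (rowSums(wx2) - wx2)
    rsq_s <- wm * (ys - b_loo_s * xs)^2
    list(rsq = rsq_s, rss = rowSums(rsq_s))
  })

  # global p is the plain empirical exceedance; per-SNP p-values keep the
  # +1 smoothing so a Bonferroni outlier call is never made on a bare zero
  global_p <- mean(sim$rss >= rss_obs)
  per_snp <- (1 + colSums(sim$rsq >= rep(rsq_obs, each = n_sim))) / (n_sim + 1)
  names(per_snp) <- ivs$snp
  outliers <- if (outlier_alpha > 0) {
    ivs$snp[per_snp < outlier_alpha / k]
  } else character(0)

  corrected <- NULL
  distortion_p <- NULL
  if (length(outliers) > 0) {
    keep <- !(ivs$snp %in% outliers)
    corrected <- if (sum(keep) >= 2) {
      est <- mr_ivw(ivs[keep, , drop = FALSE], model = "random")
      est$method <- "presso_corrected"
      est
    } else if (sum(keep) == 1) {
      est <- mr_wald_ratio(ivs[keep, , drop = FALSE])
      est$method <- "presso_corrected"
      est
    } else NULL
    if (!is.null(corrected)) {
      b_full <- sum(w * x * y) / sum(w * x^2)
      d_obs <- (b_full - corrected$beta) / abs(corrected$beta)
      n_out <- length(outliers)
      d_null <- with_seed(seed + 1L, {
        vapply(seq_len(n_sim), function(i) {
          drop <- sample.int(k, n_out)
          b_sub <- sum((w * x * y)[-drop]) / sum((w * x^2)[-drop])
          (b_full - b_sub) / abs(b_sub)
        }, numeric(1))
      })
      distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
    }
  }

  structure(list(global_rss = rss_obs, global_pvalue = global_p,
                 per_snp_pvalue = per_snp, outliers = outliers,
                 distortion_pvalue = distortion_p, corrected = corrected,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("PRESSO global RSS = %.4f, p = %.3g (%d simulations)\n",
              x$global_rss, x$global_pvalue, x$n_sim))
  if (length(x$outliers) > 0) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf("  distortion p = %.3g\n", x$distortion_pvalue))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect by multiplicative random-effects IVW with
#' each instrument excluded in turn, to reveal single instruments that drive
#' the pooled estimate.
#'
#' @param ivs harmonized instrument data.frame with at least three rows.
#' @return list of class `mr_loo` with `rows` (data.frame: `left_out` plus
#'   the estimate columns) and `full` (the all-instrument estimate).
#' @export
leave_one_out <- function(ivs) {
  k <- nrow(ivs)
  if (k < 3) stop_insufficient(3, k)
  rows <- do.call(rbind, lapply(seq_len(k), function(j) {
    est <- mr_ivw(ivs[-j, , drop = FALSE], model = "random")
    cbind(data.frame(left_out = ivs$snp[j], stringsAsFactors = FALSE), est)
  }))
  rownames(rows) <- NULL
  structure(list(rows = rows, full = mr_ivw(ivs, model = "random")),
            class = "mr_loo")
}

#' @export
print.mr_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out over %d instruments; full beta = %.4f\n",
              nrow(x$rows), x$full$beta))
  rng <- range(x$rows$beta)
  cat(sprintf("  LOO beta range: [%.4f, %.4f]\n", rng[1], rng[2]))
  invisible(x)
}

#' Numeric data behind funnel and scatter plots
#'
#' @param ivs harmonized instrument data.frame.
#' @param fits data.frame of estimate rows (e.g. stacked [mr_estimate()]
#'   output); an optional `intercept` column supplies the MR-Egger intercept
#'   for its fit line, otherwise lines pass through the origin.
#' @return list with `funnel` (per-SNP ratio and precision), `scatter`
#'   (per-SNP associations with SE bars) and `lines` (one row per fit).
#' @export
funnel_scatter_data <- function(ivs, fits = NULL) {
  ratio <- ivs$beta_out / ivs$beta_exp
  se_ratio <- ivs$se_out / abs(ivs$beta_exp)
  funnel <- data.frame(snp = ivs$snp, ratio = ratio,
                       precision = 1 / se_ratio, stringsAsFactors = FALSE)
  scatter <- data.frame(snp = ivs$snp,
                        beta_exp = ivs$beta_exp, se_exp = ivs$se_exp,
                        beta_out = ivs$beta_out, se_out = ivs$se_out,
                        stringsAsFactors = FALSE)
  lines <- NULL
  if (!is.null(fits) && nrow(fits) > 0) {
    lines <- data.frame(method = fits$method,
                        intercept = if ("intercept" %in% names(fits))
                          ifelse(is.na(fits$intercept), 0, fits$intercept) else 0,
                        slope = fits$beta, stringsAsFactors = FALSE)
  }
  list(funnel = funnel, scatter = scatter, lines = lines)
}
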