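# Causal-effect estimators on harmonized instruments. All take the
# harmonized instrument data.frame (columns beta_exp, se_exp, beta_out,
# se_out, ...) and return the common mr_estimate() row layout, log-OR of
# outcome per SD of exposure.

#' Wald ratio estimate from a single instrument
#'
#' The ratio of the outcome to the exposure association, with a first-order
#' delta-method standard error `se_out / |beta_exp|` that ignores exposure
#' uncertainty — the same weighting convention as the IVW estimator, so a
#' single-instrument Wald ratio is the one-SNP limit of IVW. A second-order
#' option additionally propagates the exposure standard error.
#'
#' @param iv one-row harmonized instrument data.frame.
#' @param second_order if `TRUE`, use the second-order delta-method SE
#'   `sqrt(se_out^2/beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`.
#' @return an [mr_estimate()] row with method `"wald"`.
#' @export
mr_wald_ratio <- function(iv, second_order = FALSE) {
  if (nrow(iv) != 1) stop("wald ratio takes exactly one instrument", call. = FALSE)
  if (iv$beta_exp == 0) stop("undefined ratio: beta_exp is zero", call. = FALSE)
  beta <- iv$beta_out / iv$beta_exp
  se <- if (second_order) {
    sqrt(iv$se_out^2 / iv$beta_exp^2 +
           iv$beta_out^2 * iv$se_exp^2 / iv$beta_exp^4)
  } else {
    iv$se_out / abs(iv$beta_exp)
  }
  mr_estimate("wald", beta, se, 1L)
}

#' Inverse-variance weighted estimate
#'
#' Weighted least squares of `beta_out` on `beta_exp` through the origin with
#' weights `1/se_out^2` — equivalently, the inverse-variance meta-analysis of
#' the per-SNP Wald ratios. Under the multiplicative random-effects model
#' (the default) the standard error is inflated by
#' `sqrt(max(1, Q/(k-1)))`, where Q is Cochran's heterogeneity statistic of
#' the fit; the fixed-effect model applies no inflation.
#'
#' @param ivs harmonized instrument data.frame with at least two rows.
#' @param model `"random"` (multiplicative random effects) or `"fixed"`.
#' @return an [mr_estimate()] row with method `"ivw_mre"` or `"ivw_fixed"`,
#'   carrying attributes `q` (Cochran's Q) and `q_df`.
#' @export
mr_ivw <- function(ivs, model = c("random", "fixed")) {
  model <- match.arg(model)
  k <- nrow(ivs)
  if (k < 2) stop_insufficient(2, k, "use mr_wald_ratio() for a single instrument")
  x <- ivs$beta_exp; y <- ivs$beta_out; w <- 1 / ivs$se_out^2
  sxx <- sum(w * x^2)
  beta <- sum(w * x * y) / sxx
  se <- sqrt(1 / sxx)
  q <- sum(w * (y - beta * x)^2)
  if (model == "random") se <- se * sqrt(max(1, q / (k - 1)))
  est <- mr_estimate(if (model == "random") "ivw_mre" else "ivw_fixed",
                     beta, se, k)
  attr(est, "q") <- q
  attr(est, "q_df") <- k - 1L
  est
}

# linearly interpolated 50% weighted percentile of b with weights w
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  j <- max(which(s < 0.5))
  b[j] + (b[j + 1] - b[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted median estimate
#'
#' The inverse-variance weighted 50% percentile of the per-SNP Wald ratios
#' (linearly interpolated), consistent when instruments carrying at least
#' half the weight are valid. The standard error comes from a parametric
#' bootstrap: exposure and outcome associations are redrawn from their normal
#' sampling distributions and the weighted median recomputed.
#'
#' @param ivs harmonized instrument data.frame with at least three rows.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap (restored afterwards).
#' @return an [mr_estimate()] row with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(ivs, n_boot = 1000, seed = 42) {
  k <- nrow(ivs)
  if (k < 3) stop_insufficient(3, k)
  ratio <- ivs$beta_out / ivs$beta_exp
  w <- (ivs$beta_exp / ivs$se_out)^2
  beta <- weighted_median_point(ratio, w)
  se <- with_seed(seed, {
    reps <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      xb <- stats::rnorm(k, ivs$beta_exp, ivs$se_exp)
      yb <- stats::rnorm(k, ivs$beta_out, ivs$se_out)
      reps[i] <- weighted_median_point(yb / xb, (xb / ivs$se_out)^2)
    }
    stats::sd(reps)
  })
  mr_estimate("weighted_median", beta, se, k)
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_out` on `beta_exp` with an intercept,
#' weights `1/se_out^2`, after orienting every instrument to a positive
#' exposure effect (both betas negated where needed). The slope is the
#' pleiotropy-adjusted causal estimate under the InSIDE assumption; a nonzero
#' intercept indicates directional pleiotropy. Standard errors are inflated
#' by the multiplicative residual scale `sqrt(max(1, Q_e/(k-2)))`; p-values
#' are two-sided normal by default (`use_t = TRUE` switches both tests to the
#' t distribution with k-2 degrees of freedom, a dialect used by some
#' implementations).
#'
#' @param ivs harmonized instrument data.frame with at least three rows.
#' @param use_t use t rather than normal reference distribution.
#' @return list with `slope` (an [mr_estimate()] row, method
#'   `"egger_slope"`), `intercept` (list `value`, `se`, `pvalue`) and `q`
#'   (residual heterogeneity statistic, k-2 df).
#' @export
mr_egger <- function(ivs, use_t = FALSE) {
  k <- nrow(ivs)
  if (k < 3) stop_insufficient(3, k)
  s <- ifelse(ivs$beta_exp < 0, -1, 1)
  x <- s * ivs$beta_exp; y <- s * ivs$beta_out
  w <- 1 / ivs$se_out^2
  sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  d <- sw * swx2 - swx^2
  slope <- (sw * swxy - swx * swy) / d
  inter <- (swx2 * swy - swx * swxy) / d
  q <- sum(w * (y - inter - slope * x)^2)
  infl <- sqrt(max(1, q / (k - 2)))
  se_slope <- sqrt(sw / d) * infl
  se_inter <- sqrt(swx2 / d) * infl
  pfun <- if (use_t) {
    function(z) 2 * stats::pt(-abs(z), df = k - 2)
  } else {
    function(z) 2 * stats::pnorm(-abs(z))
  }
  est <- mr_estimate("egger_slope", slope, se_slope, k,
                     pvalue = pfun(slope / se_slope))
  list(slope = est,
       intercept = list(value = inter, se = se_inter,
                        pvalue = pfun(inter / se_inter)),
       q = q)
}

# profile objective of the constrained summary-data likelihood: with the
# per-SNP exposure effects profiled out, a valid SNP contributes
# (beta_out - theta beta_exp)^2 / (se_out^2 + theta^2 se_exp^2) and an
# invalid SNP (free pleiotropy) contributes 0
cml_profile_obj <- function(theta, x, y, sx2, sy2, valid) {
  sum((y[valid] - theta * x[valid])^2 / (sy2[valid] + theta^2 * sx2[valid]))
}

# one constrained-ML fit for a fixed number K of invalid instruments:
# iterative coordinate update between theta, the per-SNP exposure effects,
# and the choice of the K SNPs given free pleiotropy
cml_fit_k <- function(theta0, K, x, y, sx2, sy2, max_iter, tol) {
  k <- length(x)
  theta <- theta0
  invalid <- integer(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    t_j <- (y - theta * x)^2 / (sy2 + theta^2 * sx2)
    new_invalid <- if (K > 0) sort(order(t_j, decreasing = TRUE)[seq_len(K)]) else integer(0)
    valid <- setdiff(seq_len(k), new_invalid)
    gam <- (x[valid] / sx2[valid] + theta * y[valid] / sy2[valid]) /
      (1 / sx2[valid] + theta^2 / sy2[valid])
    theta_new <- sum(gam * y[valid] / sy2[valid]) / sum(gam^2 / sy2[valid])
    if (identical(new_invalid, invalid) && abs(theta_new - theta) < tol) {
      theta <- theta_new
      invalid <- new_invalid
      converged <- TRUE
      break
    }
    theta <- theta_new
    invalid <- new_invalid
  }
  valid <- setdiff(seq_len(k), invalid)
  obj <- cml_profile_obj(theta, x, y, sx2, sy2, valid)
  list(theta = theta, invalid = invalid, obj = obj, converged = converged)
}

#' Constrained maximum likelihood with BIC model selection and averaging
#'
#' For each candidate count K of invalid instruments, maximizes the
#' bivariate-normal summary-data likelihood of the exposure and outcome
#' associations over the causal effect, the per-SNP exposure effects, and
#' per-SNP pleiotropy constrained to at most K nonzero entries. The fit uses
#' an iterative coordinate update: given the causal effect, the K SNPs with
#' the largest squared standardized residual receive free pleiotropy, the
#' rest have their exposure effects updated in closed form, and the causal
#' effect is re-estimated by weighted regression on the valid set; multiple
#' seeded restarts guard against local optima. `BIC(K) = -2 loglik +
#' K log(n_eff)`; the BIC-minimizing K gives the selected model, and model
#' averaging weights each K by `exp(-BIC/2)` (normalized), combining
#' estimates with the usual mixture variance.
#'
#' @param ivs harmonized instrument data.frame with at least two rows.
#' @param n_eff effective sample size for the BIC penalty; defaults to the
#'   minimum of the exposure and outcome sample sizes carried on `ivs`
#'   (columns `n_exp`, `n_out`).
#' @param k_max largest candidate number of invalid instruments; at most
#'   `n_snp - 2` (default), so at least two instruments stay valid.
#' @param n_restart random restarts per K in addition to the IVW start.
#' @param seed RNG seed for the restarts.
#' @param max_iter,tol convergence control of the coordinate updates.
#' @return an object of class `mr_cml`: list with `per_k` (data.frame of
#'   `k_invalid`, `beta`, `se`, `bic`, `converged`, plus list-column
#'   `invalid` of SNP ids), `selected_k`, `bic_est` and `ma_est` (both
#'   [mr_estimate()] rows, methods `"cml_bic"` and `"cml_ma"`), `ma_weights`,
#'   and `invalid_selected` (SNP ids at the selected K).
#' @export
mr_cml <- function(ivs, n_eff = NULL, k_max = NULL, n_restart = 3, seed = 42,
                   max_iter = 200, tol = 1e-10) {
  k <- nrow(ivs)
  if (k < 2) stop_insufficient(2, k)
  if (is.null(n_eff)) {
    if (!all(c("n_exp", "n_out") %in% names(ivs))) {
      stop("n_eff not given and instrument table carries no sample sizes",
           call. = FALSE)
    }
    n_eff <- min(ivs$n_exp, ivs$n_out)
  }
  if (is.null(k_max)) k_max <- k - 2
  if (k_max > k - 2) stop("k_max must be at most n_snp - 2", call. = FALSE)
  k_max <- max(0, k_max)
  x <- ivs$beta_exp; y <- ivs$beta_out
  sx2 <- ivs$se_exp^2; sy2 <- ivs$se_out^2

  theta_ivw <- sum(x * y / sy2) / sum(x^2 / sy2)
  starts <- with_seed(seed, {
    spread <- stats::sd(y / x)
    if (!is.finite(spread) || spread == 0) spread <- abs(theta_ivw) + 1
    c(theta_ivw, stats::rnorm(n_restart, theta_ivw, spread))
  })

  per <- vector("list", k_max + 1)
  for (K in 0:k_max) {
    best <- NULL
    for (th0 in starts) {
      fit <- cml_fit_k(th0, K, x, y, sx2, sy2, max_iter, tol)
      if (is.null(best) || fit$obj < best$obj - 1e-12 ||
          (abs(fit$obj - best$obj) <= 1e-12 && fit$converged && !best$converged)) {
        best <- fit
      }
    }
    # curvature of the profile deviance gives the observed information
    h <- max(1e-6, abs(best$theta) * 1e-4)
    valid <- setdiff(seq_len(k), best$invalid)
    f0 <- best$obj
    fp <- cml_profile_obj(best$theta + h, x, y, sx2, sy2, valid)
    fm <- cml_profile_obj(best$theta - h, x, y, sx2, sy2, valid)
    f2 <- (fp - 2 * f0 + fm) / h^2
    se <- if (is.finite(f2) && f2 > 0) sqrt(2 / f2) else NA_real_
    per[[K + 1]] <- list(k_invalid = K, beta = best$theta, se = se,
                         bic = f0 + K * log(n_eff),
                         converged = best$converged && is.finite(se),
                         invalid = ivs$snp[best$invalid])
  }

  per_k <- data.frame(
    k_invalid = vapply(per, `[[`, integer(1), "k_invalid"),
    beta = vapply(per, `[[`, numeric(1), "beta"),
    se = vapply(per, `[[`, numeric(1), "se"),
    bic = vapply(per, `[[`, numeric(1), "bic"),
    converged = vapply(per, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  per_k$invalid <- I(lapply(per, `[[`, "invalid"))

  usable <- which(per_k$converged & is.finite(per_k$bic))
  if (length(usable) == 0) usable <- seq_len(nrow(per_k))
  sel_row <- usable[which.min(per_k$bic[usable])]
  selected_k <- per_k$k_invalid[sel_row]

  wts <- rep(0, nrow(per_k))
  wts[usable] <- exp(-(per_k$bic[usable] - min(per_k$bic[usable])) / 2)
  wts <- wts / sum(wts)
  ma_beta <- sum(wts * per_k$beta, na.rm = TRUE)
  ma_se <- sqrt(sum(wts * (ifelse(is.na(per_k$se), 0, per_k$se)^2 +
                             (per_k$beta - ma_beta)^2)))

  structure(list(
    per_k = per_k,
    selected_k = selected_k,
    invalid_selected = per_k$invalid[[sel_row]],
    bic_est = mr_estimate("cml_bic", per_k$beta[sel_row], per_k$se[sel_row], k),
    ma_est = mr_estimate("cml_ma", ma_beta, ma_se, k),
    ma_weights = wts,
    n_eff = n_eff,
    all_converged = all(per_k$converged)
  ), class = "mr_cml")
}

#' @export
print.mr_cml <- function(x, ...) {
  cat("cML with BIC selection and model averaging\n")
  cat(sprintf("  selected K (invalid instruments): %d of %d\n",
              x$selected_k, x$bic_est$n_snp))
  cat(sprintf("  cML-BIC: beta = %.4f (se %.4f)\n", x$bic_est$beta, x$bic_est$se))
  cat(sprintf("  cML-MA:  beta = %.4f (se %.4f), p = %.3g\n",
              x$ma_est$beta, x$ma_est$se, x$ma_est$pvalue))
  if (!x$all_converged) cat("  warning: some per-K fits did not converge\n")
  invisible(x)
}
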