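# Instrument-strength metrics: proportion of variance explained, the
# F-statistic, and an analytic power approximation for a binary outcome.

#' Proportion of exposure variance explained by a variant
#'
#' `PVE = 2 * EAF * (1 - EAF) * beta^2` for a per-SD effect `beta`, the
#' variance contributed by an additively coded biallelic variant on the
#' standardized exposure scale. Symmetric in `eaf` and `1 - eaf`.
#'
#' @param eaf effect-allele frequency in (0, 1); vectorized.
#' @param beta per-SD effect on the exposure; vectorized.
#' @return numeric vector of PVE values.
#' @export
pve <- function(eaf, beta) {
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie in (0, 1)", call. = FALSE)
  2 * eaf * (1 - eaf) * beta^2
}

#' F-statistic for an instrument set
#'
#' `F = [PVE * (n - 1 - k)] / [(1 - PVE) * k]` with `n` the exposure-study
#' sample size and `k` the number of variants in the instrument model.
#'
#' @param total_pve summed PVE of the instruments, in `[0, 1)`.
#' @param n exposure-study sample size; must exceed `k + 1`.
#' @param k number of instruments, at least 1.
#' @return the F-statistic.
#' @export
f_statistic <- function(total_pve, n, k) {
  if (total_pve < 0 || total_pve >= 1) stop("total_pve must lie in [0, 1)", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (n <= k + 1) stop("n must exceed k + 1", call. = FALSE)
  (total_pve * (n - 1 - k)) / ((1 - total_pve) * k)
}

#' Approximate power for MR with a binary outcome
#'
#' Normal approximation used by standard MR power calculators:
#' `power = Phi( sqrt(n * PVE * cf * (1 - cf)) * |log OR| - z_{1 - alpha/2} )`
#' with `n` the outcome-study size and `cf` its case fraction. At OR = 1 this
#' is the one-tail floor `Phi(-z_{1-alpha/2})` (about 0.025 at alpha = 0.05).
#' Monotone nondecreasing in `n`, PVE, and `|log OR|`.
#'
#' @param total_pve instrument PVE on the exposure, in `[0, 1)`.
#' @param n outcome-study sample size.
#' @param case_fraction fraction of cases in the outcome study, in (0, 1).
#' @param or_hypothesis odds ratio to detect (per SD of exposure).
#' @param alpha two-sided type-I error rate, in (0, 1).
#' @return estimated power in (0, 1).
#' @export
power_binary <- function(total_pve, n, case_fraction, or_hypothesis,
                         alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (total_pve < 0 || total_pve >= 1) stop("total_pve must lie in [0, 1)", call. = FALSE)
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop("case_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (n <= 0 || or_hypothesis <= 0) stop("n and or_hypothesis must be positive", call. = FALSE)
  ncp <- sqrt(n * total_pve * case_fraction * (1 - case_fraction)) *
    abs(log(or_hypothesis))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Strength summary for a harmonized instrument set
#'
#' Per-SNP and total PVE, the joint F-statistic, and the per-SNP
#' F-statistics (each with k = 1). Where per-SNP exposure sample sizes vary,
#' the minimum is used (and reported).
#'
#' @param ivs harmonized instrument data.frame.
#' @param n exposure sample size; defaults to `min(ivs$n_exp)`.
#' @return list of class `iv_strength` with `per_snp_pve` (named), `total_pve`,
#'   `f_joint`, `f_per_snp` (named), `n`, `k`.
#' @export
instrument_strength <- function(ivs, n = NULL) {
  if (is.null(n)) {
    if (!"n_exp" %in% names(ivs)) {
      stop("n not given and instrument table carries no exposure sample size",
           call. = FALSE)
    }
    n <- min(ivs$n_exp)
  }
  per <- pve(ivs$eaf_exp, ivs$beta_exp)
  names(per) <- ivs$snp
  k <- nrow(ivs)
  total <- sum(per)
  structure(list(
    per_snp_pve = per,
    total_pve = total,
    f_joint = f_statistic(total, n, k),
    f_per_snp = stats::setNames(
      vapply(per, function(p) f_statistic(p, n, 1), numeric(1)), ivs$snp),
    n = n, k = k
  ), class = "iv_strength")
}

#' @export
print.iv_strength <- function(x, ...) {
  cat(sprintf("%d instruments, total PVE = %.4f, joint F = %.1f (n = %d)\n",
              x$k, x$total_pve, x$f_joint, x$n))
  invisible(x)
}
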