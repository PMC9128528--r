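# Synthetic two-sample GWAS summary statistics with known ground truth.
# The generator instantiates exactly the structural model the estimators
# assume: per-SNP true exposure effects gamma_j, a causal effect theta on
# the outcome, optional direct (pleiotropic) effects alpha_j, and
# independent sampling noise in the exposure and outcome studies with
# MAF- and sample-size-driven standard errors.

#' Study-size presets for the synthetic generator
#'
#' Named presets carrying the scale of three kinds of study: a very large
#' blood-cell-trait GWAS meta-analysis (`bcx`, n = 563,085 individuals), a
#' small founder-population immune-cell phenotyping GWAS (`sardinian`,
#' n = 3,757), and a large case-control disease GWAS (`imsgc`, 47,429 cases
#' and 68,374 controls).
#'
#' @param name one of `"bcx"`, `"sardinian"`, `"imsgc"`.
#' @return a list with `n` (quantitative traits) or `cases` and `controls`
#'   (binary outcome).
#' @export
synth_preset <- function(name = c("bcx", "sardinian", "imsgc")) {
  switch(match.arg(name),
         bcx = list(n = 563085L),
         sardinian = list(n = 3757L),
         imsgc = list(cases = 47429L, controls = 68374L))
}

#' Configuration for the synthetic summary-statistics generator
#'
#' Defaults emulate the large-GWAS setting: a quantitative exposure measured
#' in 563,085 individuals, a binary outcome with 47,429 cases and 68,374
#' controls, per-SNP exposure effects with spread `gamma_sd = 0.02` per SD
#' (large enough for genome-wide-significant instruments at this exposure
#' scale), minor allele frequencies uniform on (0.05, 0.5), and about 15% of
#' variants palindromic, as in typical SNP panels.
#'
#' @param n_snp number of variants.
#' @param n_exposure exposure-study sample size.
#' @param outcome_cases,outcome_controls case-control sizes of the binary
#'   outcome study; the outcome noise scale uses the effective size
#'   `4 / (1/cases + 1/controls)`.
#' @param n_outcome optional quantitative-outcome sample size; overrides the
#'   case-control effective size when given.
#' @param true_theta causal effect, log-OR of outcome per SD of exposure.
#' @param gamma_sd spread of per-SNP true exposure effects (per SD).
#' @param pleiotropy_model `"none"`, `"balanced"` (direct effects centred on
#'   zero), `"directional"` (direct effects with a common sign relative to
#'   the exposure-increasing allele), or `"correlated"` (direct effects
#'   proportional to the exposure effect plus noise, violating InSIDE).
#' @param prop_invalid fraction of variants given a nonzero direct effect.
#' @param alpha_mean mean direct effect (directional), or the
#'   proportionality constant on `gamma` (correlated).
#' @param alpha_sd spread of direct effects.
#' @param maf_range minor-allele-frequency range, bounds in (0, 0.5].
#' @param palindromic_fraction fraction of variants given A/T or C/G alleles.
#' @param ld_block_sizes integer vector of LD block sizes (recycled over the
#'   panel); `NULL` means every SNP is its own block (no LD).
#' @param within_block_r2 r-squared assigned to every within-block pair.
#' @param eaf_noise_sd between-study jitter on the reported allele frequency.
#' @param seed RNG seed; generation is bitwise reproducible.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_snp = 30,
                         n_exposure = 563085,
                         outcome_cases = 47429,
                         outcome_controls = 68374,
                         n_outcome = NULL,
                         true_theta = 0,
                         gamma_sd = 0.02,
                         pleiotropy_model = c("none", "balanced", "directional", "correlated"),
                         prop_invalid = 0,
                         alpha_mean = 0,
                         alpha_sd = 0,
                         maf_range = c(0.05, 0.5),
                         palindromic_fraction = 0.15,
                         ld_block_sizes = NULL,
                         within_block_r2 = 0,
                         eaf_noise_sd = 0.005,
                         seed = 1) {
  pleiotropy_model <- match.arg(pleiotropy_model)
  stopifnot(n_snp >= 1, n_exposure > 0,
            prop_invalid >= 0, prop_invalid <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            within_block_r2 >= 0, within_block_r2 <= 1)
  structure(as.list(environment()), class = "synth_config")
}

# block-diagonal LD layout: contiguous blocks 1 kb apart within, far apart
# between, cycling over chromosomes
synth_layout <- function(n_snp, block_sizes) {
  if (is.null(block_sizes)) block_sizes <- rep(1L, n_snp)
  blocks <- integer(0)
  b <- 1L
  while (length(blocks) < n_snp) {
    sz <- block_sizes[((b - 1L) %% length(block_sizes)) + 1L]
    blocks <- c(blocks, rep(b, sz))
    b <- b + 1L
  }
  blocks <- blocks[seq_len(n_snp)]
  chr <- as.character(((blocks - 1L) %% 22L) + 1L)
  pos <- integer(n_snp)
  for (bb in unique(blocks)) {
    idx <- which(blocks == bb)
    start <- 1e6 + ((bb - 1L) %/% 22L) * 1e7
    pos[idx] <- as.integer(start + (seq_along(idx) - 1L) * 1000L)
  }
  list(blocks = blocks, chr = chr, pos = pos)
}

#' Generate synthetic two-sample GWAS summary statistics
#'
#' Draws minor allele frequencies, true per-SNP exposure effects, and direct
#' (pleiotropic) effects per the configured model, then observes them with
#' independent exposure- and outcome-study noise: `beta_exp_j ~ N(gamma_j,
#' se_exp_j^2)` and `beta_out_j ~ N(theta * gamma_j + alpha_j, se_out_j^2)`
#' with `se = 1 / sqrt(2 * maf * (1 - maf) * n)` on the standardized scale
#' (the binary outcome uses the case-control effective size). Alleles are
#' assigned with the configured palindromic fraction, both studies report
#' the same strand and effect allele, and the LD reference is block-diagonal.
#'
#' @param config a [synth_config()].
#' @return list with `exposure` and `outcome` (summary-statistic data.frames),
#'   `ld` (an `ld_ref`), and `truth` (list: `theta`, `gamma`, `alpha`,
#'   `invalid_set`, `palindromic_set`, `maf`, `blocks`, `warnings`).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  n <- cfg$n_snp
  warnings <- character(0)
  if (cfg$gamma_sd == 0 && cfg$true_theta != 0) {
    warnings <- c(warnings, "gamma_sd = 0 with nonzero true_theta: instruments carry no signal")
  }

  with_seed(cfg$seed, {
    snp <- sprintf("rs%06d", seq_len(n))
    layout <- synth_layout(n, cfg$ld_block_sizes)
    maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
    n_out_eff <- if (!is.null(cfg$n_outcome)) cfg$n_outcome else
      4 / (1 / cfg$outcome_cases + 1 / cfg$outcome_controls)
    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure)
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * n_out_eff)

    gamma <- stats::rnorm(n, 0, cfg$gamma_sd)
    alpha <- rep(0, n)
    n_invalid <- round(cfg$prop_invalid * n)
    invalid <- if (n_invalid > 0 && cfg$pleiotropy_model != "none") {
      sort(sample.int(n, n_invalid))
    } else integer(0)
    if (length(invalid) > 0) {
      m <- length(invalid)
      alpha[invalid] <- switch(
        cfg$pleiotropy_model,
        balanced = stats::rnorm(m, 0, cfg$alpha_sd),
        # directional effects are defined relative to the exposure-increasing
        # allele; with arbitrary effect-allele coding that means the direct
        # effect carries the sign of gamma
        directional = sign(gamma[invalid]) *
          stats::rnorm(m, cfg$alpha_mean, cfg$alpha_sd),
        correlated = cfg$alpha_mean * gamma[invalid] +
          stats::rnorm(m, 0, cfg$alpha_sd)
      )
    }

    beta_exp <- stats::rnorm(n, gamma, se_exp)
    beta_out <- stats::rnorm(n, cfg$true_theta * gamma + alpha, se_out)
    p_exp <- pmax(2 * stats::pnorm(-abs(beta_exp / se_exp)), 1e-320)
    p_out <- pmax(2 * stats::pnorm(-abs(beta_out / se_out)), 1e-320)

    n_pal <- round(cfg$palindromic_fraction * n)
    pal_idx <- if (n_pal > 0) sort(sample.int(n, n_pal)) else integer(0)
    ea <- character(n); oa <- character(n)
    pal_pairs <- list(c("A", "T"), c("C", "G"))
    other_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    pick <- function(pairs) {
      pr <- pairs[[sample.int(length(pairs), 1)]]
      if (stats::runif(1) < 0.5) pr else rev(pr)
    }
    for (i in seq_len(n)) {
      pr <- if (i %in% pal_idx) pick(pal_pairs) else pick(other_pairs)
      ea[i] <- pr[1]; oa[i] <- pr[2]
    }

    eaf_exp <- maf
    eaf_out <- pmin(pmax(maf + stats::rnorm(n, 0, cfg$eaf_noise_sd), 1e-3),
                    1 - 1e-3)

    exposure <- data.frame(
      snp = snp, chr = layout$chr, pos = layout$pos, ea = ea, oa = oa,
      eaf = eaf_exp, beta = beta_exp, se = se_exp, p = p_exp,
      n = as.integer(cfg$n_exposure), stringsAsFactors = FALSE
    )
    outcome <- data.frame(
      snp = snp, chr = layout$chr, pos = layout$pos, ea = ea, oa = oa,
      eaf = eaf_out, beta = beta_out, se = se_out, p = p_out,
      n = as.integer(round(n_out_eff)), stringsAsFactors = FALSE
    )

    pairs <- NULL
    if (cfg$within_block_r2 > 0) {
      pl <- list()
      for (bb in unique(layout$blocks)) {
        idx <- which(layout$blocks == bb)
        if (length(idx) < 2) next
        cmb <- utils::combn(idx, 2)
        pl[[length(pl) + 1]] <- data.frame(
          snp_a = snp[cmb[1, ]], snp_b = snp[cmb[2, ]],
          r2 = cfg$within_block_r2, stringsAsFactors = FALSE)
      }
      if (length(pl) > 0) pairs <- do.call(rbind, pl)
    }
    ld <- ld_reference(pairs, positions = data.frame(
      snp = snp, chr = layout$chr, pos = layout$pos, stringsAsFactors = FALSE))

    truth <- list(theta = cfg$true_theta,
                  gamma = stats::setNames(gamma, snp),
                  alpha = stats::setNames(alpha, snp),
                  invalid_set = snp[invalid],
                  palindromic_set = snp[pal_idx],
                  maf = stats::setNames(maf, snp),
                  blocks = stats::setNames(layout$blocks, snp),
                  n_outcome_effective = n_out_eff,
                  warnings = warnings)

    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
  })
}
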