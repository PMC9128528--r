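# Fixture builders and independent oracles used across the suite.

# a harmonized instrument table drawn directly from the structural model,
# bypassing the generator (for estimator-level tests)
make_ivs <- function(k, theta = 0.2, gamma_sd = 0.02, se_exp = 0.002,
                     se_out = 0.005, alpha = rep(0, k), seed = 1) {
  set.seed(seed)
  gamma <- rnorm(k, 0, gamma_sd)
  data.frame(
    snp = sprintf("rs%03d", seq_len(k)),
    ea = "A", oa = "G",
    eaf_exp = runif(k, 0.1, 0.5),
    beta_exp = rnorm(k, gamma, se_exp),
    se_exp = rep(se_exp, k),
    p_exp = rep(1e-10, k),
    eaf_out = runif(k, 0.1, 0.5),
    beta_out = rnorm(k, theta * gamma + alpha, se_out),
    se_out = rep(se_out, k),
    p_out = rep(0.5, k),
    n_exp = 500000L, n_out = 100000L,
    flags = "",
    stringsAsFactors = FALSE
  )
}

# weighted least squares through the origin, via lm()
oracle_ivw <- function(ivs) {
  fit <- lm(beta_out ~ 0 + beta_exp, data = ivs, weights = 1 / ivs$se_out^2)
  unname(coef(fit)[1])
}

# weighted least squares with intercept on positively oriented instruments
oracle_egger <- function(ivs) {
  s <- ifelse(ivs$beta_exp < 0, -1, 1)
  x <- s * ivs$beta_exp
  y <- s * ivs$beta_out
  fit <- lm(y ~ x, weights = 1 / ivs$se_out^2)
  unname(coef(fit))  # intercept, slope
}

# cumulative-weight search for the interpolated weighted median, written as
# an explicit loop independent of the package's vectorized implementation
oracle_weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  s <- numeric(length(b))
  acc <- 0
  for (i in seq_along(b)) {
    s[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  j <- 1
  while (s[j + 1] < 0.5) j <- j + 1
  if (s[j] == 0.5) return(b[j])
  b[j] + (b[j + 1] - b[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

# exhaustive pairwise independence check for a clumping result: retained set
# must be conflict-free, and every discarded SNP must conflict with a
# retained SNP of lower p (tie-broken by id)
check_clump <- function(input, kept, ld, cfg) {
  conflicts <- function(a, b) {
    a$chr == b$chr && abs(a$pos - b$pos) <= cfg$clump_kb * 1000 &&
      ld_r2(ld, a$snp, b$snp) >= cfg$clump_r2
  }
  for (i in seq_len(nrow(kept))) {
    for (j in seq_len(nrow(kept))) {
      if (i < j && conflicts(kept[i, ], kept[j, ])) {
        return("retained pair in conflict")
      }
    }
  }
  dropped <- input[!(input$snp %in% kept$snp), , drop = FALSE]
  for (i in seq_len(nrow(dropped))) {
    dominated <- FALSE
    for (j in seq_len(nrow(kept))) {
      k <- kept[j, ]
      d <- dropped[i, ]
      better <- k$p < d$p || (k$p == d$p && k$snp < d$snp)
      if (better && conflicts(d, k)) dominated <- TRUE
    }
    if (!dominated) return(paste("dropped SNP not dominated:", dropped$snp[i]))
  }
  TRUE
}

# random summary-statistic table for IO / filter tests
random_sumstats <- function(n, seed = 1) {
  set.seed(seed)
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "C"), c("A", "T"), c("C", "G"))
  al <- pairs[sample.int(length(pairs), n, replace = TRUE)]
  data.frame(
    snp = sprintf("rs%05d", seq_len(n)),
    chr = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e8, n),
    ea = vapply(al, `[`, character(1), 1),
    oa = vapply(al, `[`, character(1), 2),
    eaf = runif(n, 0.01, 0.99),
    beta = rnorm(n, 0, 0.05),
    se = runif(n, 0.001, 0.01),
    p = runif(n),
    n = sample(1000:500000, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
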