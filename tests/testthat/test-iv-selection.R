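cfg_default <- selection_config()

test_that("significance filtering keeps exactly the sub-threshold records in order", {
  df <- random_sumstats(4, seed = 1)
  df$p <- c(1e-9, 1e-7, 0.5, 4.9e-8)
  kept <- select_significant(df, cfg_default)
  expect_equal(kept$snp, df$snp[c(1, 4)])

  df$p <- rep(1, 4)
  expect_equal(nrow(select_significant(df, cfg_default)), 0)

  big <- random_sumstats(1000, seed = 2)
  big$p <- 10^runif(1000, -12, 0)
  kept <- select_significant(big, cfg_default)
  brute <- big[sapply(seq_len(nrow(big)), function(i) big$p[i] < 5e-8), ]
  expect_equal(kept$snp, brute$snp)
})

test_that("clumping keeps the lowest-p SNP per locus and respects the window", {
  two <- random_sumstats(2, seed = 3)
  two$chr <- "1"; two$pos <- c(100000, 105000)
  two$p <- c(1e-10, 1e-9)
  ld <- ld_reference(data.frame(snp_a = two$snp[1], snp_b = two$snp[2], r2 = 0.9))
  kept <- clump_snps(two, ld, cfg_default)
  expect_equal(kept$snp, two$snp[1])

  two$pos <- c(100000, 100000 + 500000)  # outside the 10 kb window
  expect_equal(sort(clump_snps(two, ld, cfg_default)$snp), sort(two$snp))
})

test_that("clumped sets satisfy the exhaustive independence and dominance checks", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50
    df <- random_sumstats(n, seed = seed + 100)
    blocks <- rep(1:5, each = 10)
    df$chr <- as.character(blocks)
    df$pos <- 1e6 + (seq_len(n) %% 10) * 1500  # some pairs in, some out of window
    df$p <- 10^runif(n, -12, -8)
    pl <- list()
    for (b in 1:5) {
      idx <- which(blocks == b)
      cmb <- combn(idx, 2)
      pl[[b]] <- data.frame(snp_a = df$snp[cmb[1, ]], snp_b = df$snp[cmb[2, ]],
                            r2 = runif(ncol(cmb))^0.3, stringsAsFactors = FALSE)
    }
    ld <- ld_reference(do.call(rbind, pl))
    kept <- clump_snps(df, ld, cfg_default)
    expect_true(isTRUE(check_clump(df, kept, ld, cfg_default)),
                info = paste("seed", seed))
  }
})

test_that("proxy search returns the max-r2 qualifying candidate with tie rules", {
  cand <- random_sumstats(3, seed = 4)
  ld <- ld_reference(data.frame(snp_a = "target",
                                snp_b = cand$snp,
                                r2 = c(0.85, 0.95, 0.5)))
  got <- find_proxy("target", cand, ld, cfg_default)
  expect_equal(got$snp, cand$snp[2])

  ld_low <- ld_reference(data.frame(snp_a = "target", snp_b = cand$snp,
                                    r2 = c(0.7, 0.6, 0.5)))
  expect_null(find_proxy("target", cand, ld_low, cfg_default))

  # brute-force argmax with ties broken by p then id, 20 random candidates
  set.seed(5)
  cand <- random_sumstats(20, seed = 6)
  r2 <- sample(c(0.7, 0.85, 0.9, 0.95), 20, replace = TRUE)
  cand$p <- sample(c(1e-9, 1e-8), 20, replace = TRUE)
  ld <- ld_reference(data.frame(snp_a = "target", snp_b = cand$snp, r2 = r2))
  got <- find_proxy("target", cand, ld, cfg_default)
  ok <- r2 > cfg_default$proxy_r2_min
  pool <- cand[ok, ]; r2p <- r2[ok]
  pool <- pool[order(-r2p, pool$p, pool$snp), ]
  expect_equal(got$snp, pool$snp[1])
})

test_that("trait-based exclusion removes listed sub-threshold SNPs and keeps the rest", {
  ivs <- random_sumstats(6, seed = 7)
  trait <- random_sumstats(4, seed = 8)
  trait$snp <- ivs$snp[1:4]
  trait$p <- c(1e-6, 1e-4, 2e-5, 1e-7)
  res <- exclude_by_trait(ivs, trait, 1e-5)
  expect_equal(sort(res$removed$snp), sort(ivs$snp[c(1, 4)]))
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(ivs))
  # SNPs absent from the trait table are always kept
  expect_true(all(ivs$snp[5:6] %in% res$kept$snp))

  # sequential filters over two confounder tables match one-by-one brute force
  ivs <- random_sumstats(200, seed = 9)
  c1 <- random_sumstats(150, seed = 10); c1$snp <- ivs$snp[1:150]
  c2 <- random_sumstats(100, seed = 11); c2$snp <- ivs$snp[51:150]
  c1$p <- 10^runif(150, -8, 0); c2$p <- 10^runif(100, -8, 0)
  step1 <- exclude_by_trait(ivs, c1, 1e-5)
  step2 <- exclude_by_trait(step1$kept, c2, 1e-5)
  brute <- ivs$snp[!(ivs$snp %in% c1$snp[c1$p < 1e-5]) &
                     !(ivs$snp %in% c2$snp[c2$p < 1e-5])]
  expect_equal(step2$kept$snp, brute)
})

make_pair <- function(e_ea, e_oa, o_ea, o_oa, eaf_exp = 0.2, eaf_out = 0.2,
                      beta_out = 0.05) {
  exp <- data.frame(snp = "rs1", chr = "1", pos = 1000L, ea = e_ea, oa = e_oa,
                    eaf = eaf_exp, beta = 0.1, se = 0.01, p = 1e-9, n = 1000L,
                    stringsAsFactors = FALSE)
  out <- data.frame(snp = "rs1", chr = "1", pos = 1000L, ea = o_ea, oa = o_oa,
                    eaf = eaf_out, beta = beta_out, se = 0.02, p = 0.01,
                    n = 2000L, stringsAsFactors = FALSE)
  list(exp = exp, out = out)
}

test_that("harmonization covers aligned, swapped, strand-flipped and bad pairs", {
  # identical alleles pass through untouched
  p <- make_pair("A", "G", "A", "G")
  h <- harmonize_pair(p$exp, p$out, cfg_default)
  expect_equal(h$iv$beta_out, 0.05)
  expect_equal(h$iv$flags, "")

  # swapped alleles: sign negated, frequency complemented, flagged
  p <- make_pair("A", "G", "G", "A", eaf_out = 0.8)
  h <- harmonize_pair(p$exp, p$out, cfg_default)
  expect_equal(h$iv$beta_out, -0.05)
  expect_equal(h$iv$eaf_out, 0.2)
  expect_match(h$iv$flags, "flipped")

  # opposite strand, same orientation: numbers unchanged
  p <- make_pair("A", "G", "T", "C")
  h <- harmonize_pair(p$exp, p$out, cfg_default)
  expect_equal(h$iv$beta_out, 0.05)

  # opposite strand and swapped: negated
  p <- make_pair("A", "G", "C", "T")
  h <- harmonize_pair(p$exp, p$out, cfg_default)
  expect_equal(h$iv$beta_out, -0.05)

  # non-concordant allele sets are dropped with a reason
  p <- make_pair("A", "G", "A", "C")
  h <- harmonize_pair(p$exp, p$out, cfg_default)
  expect_null(h$iv)
  expect_equal(h$reason, "non-concordant")
})

test_that("palindromic SNPs are frequency-aligned only below the MAF threshold", {
  # MAF 0.45 in the outcome: ambiguous at the 0.3 threshold
  p <- make_pair("A", "T", "A", "T", eaf_exp = 0.2, eaf_out = 0.45)
  h <- harmonize_pair(p$exp, p$out, cfg_default)
  expect_null(h$iv)
  expect_equal(h$reason, "ambiguous palindrome")

  # concordant frequencies below threshold: kept as reported
  p <- make_pair("C", "G", "C", "G", eaf_exp = 0.2, eaf_out = 0.25)
  h <- harmonize_pair(p$exp, p$out, cfg_default)
  expect_equal(h$iv$beta_out, 0.05)
  expect_true(grepl("palindromic", h$iv$flags))

  # discordant frequencies: the outcome study reported the other strand
  p <- make_pair("C", "G", "C", "G", eaf_exp = 0.2, eaf_out = 0.75)
  h <- harmonize_pair(p$exp, p$out, cfg_default)
  expect_equal(h$iv$beta_out, -0.05)
  expect_equal(h$iv$eaf_out, 0.25)
  expect_true(grepl("flipped", h$iv$flags))
})

test_that("harmonization is idempotent and the swap transform is an involution", {
  p <- make_pair("A", "G", "A", "G")
  h1 <- harmonize_pair(p$exp, p$out, cfg_default)
  # feed the harmonized outcome back as an aligned record
  out2 <- p$out
  out2$beta <- h1$iv$beta_out; out2$eaf <- h1$iv$eaf_out
  h2 <- harmonize_pair(p$exp, out2, cfg_default)
  expect_equal(h2$iv$beta_out, h1$iv$beta_out)
  expect_equal(h2$iv$eaf_out, h1$iv$eaf_out)

  # double swap restores the original
  swap <- function(out) {
    tmp <- out$ea; out$ea <- out$oa; out$oa <- tmp
    out$beta <- -out$beta; out$eaf <- 1 - out$eaf
    out
  }
  p <- make_pair("A", "G", "A", "G", eaf_out = 0.3)
  once <- swap(p$out)
  twice <- swap(once)
  expect_equal(twice$beta, p$out$beta)
  expect_equal(twice$eaf, p$out$eaf)
  h_orig <- harmonize_pair(p$exp, p$out, cfg_default)
  h_twice <- harmonize_pair(p$exp, twice, cfg_default)
  expect_equal(h_twice$iv$beta_out, h_orig$iv$beta_out)
})

test_that("table harmonization conserves counts across kept and dropped", {
  d <- synth_generate(synth_config(n_snp = 60, true_theta = 0.1,
                                   maf_range = c(0.05, 0.5),
                                   palindromic_fraction = 0.3, seed = 13))
  h <- harmonize_tables(d$exposure, d$outcome, cfg_default)
  expect_equal(nrow(h$ivs) + nrow(h$dropped), 60)
  expect_true(all(h$dropped$reason %in%
                    c("ambiguous palindrome", "non-concordant",
                      "missing from outcome")))
})
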