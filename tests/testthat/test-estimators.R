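test_that("the Wald ratio matches the delta method and its edge cases", {
  iv <- make_ivs(1, seed = 1)
  iv$beta_exp <- 0.1; iv$beta_out <- 0; iv$se_out <- 0.02
  est <- mr_wald_ratio(iv)
  expect_equal(est$beta, 0)
  expect_equal(est$or, 1)
  expect_equal(est$se, 0.2)

  iv$beta_exp <- 0
  expect_error(mr_wald_ratio(iv), "undefined ratio")

  # numeric first-order delta-method oracle: gradient of by/bx at the
  # estimates, exposure uncertainty ignored to match the IVW weighting
  set.seed(2)
  for (i in 1:200) {
    iv <- make_ivs(1, seed = i + 10)
    iv$beta_exp <- rnorm(1, 0.1, 0.05)
    if (abs(iv$beta_exp) < 1e-4) next
    est <- mr_wald_ratio(iv)
    h <- 1e-6
    g_by <- ((iv$beta_out + h) / iv$beta_exp - iv$beta_out / iv$beta_exp) / h
    se_oracle <- sqrt(g_by^2 * iv$se_out^2)
    expect_equal(est$beta, iv$beta_out / iv$beta_exp, tolerance = 1e-12)
    expect_equal(est$se, se_oracle, tolerance = 1e-5)
  }
})

test_that("IVW equals weighted least squares through the origin", {
  # homogeneous pair: estimate is the common ratio, Q = 0, no inflation
  iv <- make_ivs(2, seed = 3)
  iv$beta_exp <- c(0.1, 0.2)
  iv$beta_out <- 1.5 * iv$beta_exp
  fixed <- mr_ivw(iv, model = "fixed")
  random <- mr_ivw(iv, model = "random")
  expect_equal(fixed$beta, 1.5, tolerance = 1e-12)
  expect_equal(attr(fixed, "q"), 0, tolerance = 1e-20)
  expect_equal(fixed$se, random$se)

  for (seed in 1:50) {
    ivs <- make_ivs(sample(3:40, 1), theta = runif(1, -0.5, 0.5), seed = seed)
    est <- mr_ivw(ivs, model = "fixed")
    expect_equal(est$beta, oracle_ivw(ivs), tolerance = 1e-10)
  }

  expect_error(mr_ivw(make_ivs(1)), "insufficient instruments.*wald")
})

test_that("the weighted median interpolates the cumulative-weight percentile", {
  # constant ratios: the estimate is that constant whatever the weights
  ivs <- make_ivs(5, seed = 4)
  ivs$beta_out <- 0.7 * ivs$beta_exp
  est <- mr_weighted_median(ivs, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.7, tolerance = 1e-12)

  # frozen case: ratios {1, 2, 10} with equal weights -> 2 (cumulative
  # midweights {1/6, 1/2, 5/6} cross 0.5 exactly at the second ratio)
  ivs3 <- make_ivs(3, seed = 5)
  ivs3$beta_exp <- rep(0.1, 3)
  ivs3$se_out <- rep(0.01, 3)
  ivs3$beta_out <- c(1, 2, 10) * 0.1
  est <- mr_weighted_median(ivs3, n_boot = 100, seed = 1)
  expect_equal(est$beta, 2, tolerance = 1e-12)
  expect_equal(oracle_weighted_median(c(1, 2, 10), rep(1, 3)), 2)

  # random instances against the loop-based oracle
  for (seed in 1:30) {
    ivs <- make_ivs(sample(3:25, 1), seed = seed + 50)
    ratio <- ivs$beta_out / ivs$beta_exp
    w <- (ivs$beta_exp / ivs$se_out)^2
    est <- mr_weighted_median(ivs, n_boot = 100, seed = 1)
    expect_equal(est$beta, oracle_weighted_median(ratio, w), tolerance = 1e-10)
  }

  expect_error(mr_weighted_median(make_ivs(2)), "insufficient")
})

test_that("MR-Egger equals the weighted normal equations with intercept", {
  # collinear points through the origin: intercept exactly 0
  ivs <- make_ivs(3, seed = 6)
  ivs$beta_exp <- c(0.1, 0.2, 0.3)
  ivs$beta_out <- 0.4 * ivs$beta_exp
  eg <- mr_egger(ivs)
  expect_equal(eg$intercept$value, 0, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.4, tolerance = 1e-12)

  for (seed in 1:50) {
    ivs <- make_ivs(sample(3:40, 1), theta = runif(1, -0.5, 0.5), seed = seed + 80)
    eg <- mr_egger(ivs)
    ref <- oracle_egger(ivs)
    expect_equal(eg$intercept$value, ref[1], tolerance = 1e-10)
    expect_equal(eg$slope$beta, ref[2], tolerance = 1e-10)
  }

  expect_error(mr_egger(make_ivs(2)), "insufficient")
})

test_that("Egger recovers a planted directional pleiotropy intercept", {
  set.seed(7)
  n_rep <- 200
  ints <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    k <- 30
    gamma <- abs(rnorm(k, 0, 0.02))  # oriented positive
    se_out <- rep(0.005, k)
    ivs <- make_ivs(k, seed = r + 200)
    ivs$beta_exp <- gamma
    ivs$se_out <- se_out
    ivs$beta_out <- rnorm(k, 0.2 * gamma + 0.05, se_out)
    ints[r] <- mr_egger(ivs)$intercept$value
  }
  mcse <- sd(ints) / sqrt(n_rep)
  expect_lt(abs(mean(ints) - 0.05), 4 * mcse + 1e-4)
})

test_that("cML with K = 0 matches a generic one-dimensional optimizer", {
  for (seed in 1:10) {
    ivs <- make_ivs(12, theta = 0.15, seed = seed + 300)
    res <- mr_cml(ivs, k_max = 0, seed = 1)
    f <- function(th) {
      sum((ivs$beta_out - th * ivs$beta_exp)^2 /
            (ivs$se_out^2 + th^2 * ivs$se_exp^2))
    }
    opt <- optimize(f, c(-5, 5), tol = 1e-12)
    expect_equal(res$bic_est$beta, opt$minimum, tolerance = 1e-6)
  }
})

test_that("cML selects no invalid instruments under a clean model and finds planted ones", {
  clean <- make_ivs(20, theta = 0.2, seed = 8)
  res <- mr_cml(clean, seed = 1)
  expect_equal(res$selected_k, 0)
  expect_lt(abs(res$ma_est$beta - 0.2), 4 * res$ma_est$se)

  alpha <- rep(0, 20)
  planted <- c(3, 9, 17)
  alpha[planted] <- 0.08
  dirty <- make_ivs(20, theta = 0.2, alpha = alpha, seed = 9)
  res <- mr_cml(dirty, seed = 1)
  expect_true(all(dirty$snp[planted] %in% res$invalid_selected))
  # model-averaged weights are a proper distribution
  expect_true(all(res$ma_weights >= 0))
  expect_equal(sum(res$ma_weights), 1, tolerance = 1e-12)
  # selected K minimizes BIC among converged fits
  conv <- res$per_k[res$per_k$converged, ]
  expect_equal(res$selected_k, conv$k_invalid[which.min(conv$bic)])

  expect_error(mr_cml(make_ivs(10), k_max = 9), "k_max")
})

test_that("ratio estimators are scale-equivariant and MRE never deflates the SE", {
  ivs <- make_ivs(15, theta = 0.25, seed = 10)
  for (c_scale in c(0.5, 2, 10)) {
    scaled <- ivs
    scaled$beta_exp <- ivs$beta_exp * c_scale
    scaled$se_exp <- ivs$se_exp * c_scale
    expect_equal(mr_ivw(scaled)$beta, mr_ivw(ivs)$beta / c_scale,
                 tolerance = 1e-10)
    expect_equal(mr_weighted_median(scaled, n_boot = 100, seed = 1)$beta,
                 mr_weighted_median(ivs, n_boot = 100, seed = 1)$beta / c_scale,
                 tolerance = 1e-10)
    one <- ivs[1, , drop = FALSE]
    one_s <- scaled[1, , drop = FALSE]
    expect_equal(mr_wald_ratio(one_s)$beta, mr_wald_ratio(one)$beta / c_scale,
                 tolerance = 1e-12)
  }

  for (seed in 1:20) {
    ivs <- make_ivs(sample(3:30, 1), seed = seed + 400)
    f <- mr_ivw(ivs, model = "fixed")
    r <- mr_ivw(ivs, model = "random")
    expect_gte(r$se, f$se)
    q <- attr(f, "q")
    if (q <= nrow(ivs) - 1) expect_equal(r$se, f$se)
  }
})

test_that("a single-instrument Wald ratio is the vanishing-weight limit of IVW", {
  iv <- make_ivs(1, seed = 11)
  wald <- mr_wald_ratio(iv)
  second <- make_ivs(1, seed = 12)
  second$se_out <- 1e4  # negligible weight
  pair <- rbind(iv, second)
  pair$snp <- c("a", "b")
  ivw <- mr_ivw(pair, model = "fixed")
  expect_equal(ivw$beta, wald$beta, tolerance = 1e-6)
  expect_equal(ivw$se, wald$se, tolerance = 1e-6)
})

test_that("estimate rows keep the log and odds-ratio scales consistent", {
  est <- mr_estimate("ivw_mre", 0.21, 0.07, 12L)
  z <- qnorm(0.975)
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$ci_low, est$beta - z * est$se)
  expect_equal(est$ci_high, est$beta + z * est$se)
  expect_true(est$ci_low <= est$beta && est$beta <= est$ci_high)
  expect_equal(est$or_ci_low, exp(est$ci_low))
})
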