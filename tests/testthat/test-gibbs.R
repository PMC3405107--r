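test_that("uncensored no-marker fit recovers least-squares fixed effects", {
  co <- make_test_cohort(150, seed = 10, cens_frac = 0)
  m <- model_spec(c("sex", "age_spline", "smoking", "bmi_spline"), name = "B-0")
  f <- fit_wgp(co, m, chain = quick_chain(4000, 1000, 2, seed = 3))
  d <- build_fixed_design(co, m)
  y <- co$outcomes$yl_lower
  ls <- lm.fit(d$X, y)
  post_sd <- apply(f$draws_beta_F, 2, sd)
  mcse <- post_sd / sqrt(nrow(f$draws_beta_F) / 10)  # generous ESS deflation
  expect_true(all(abs(f$posterior$beta_F - ls$coefficients) <
                    2 * (post_sd + mcse)))
  # fitted values agree closely with least squares
  expect_lt(mean(abs(f$posterior$fitted - d$X %*% ls$coefficients)), 1)
})

test_that("chains are bit-reproducible from the seed and respect bounds", {
  co <- make_test_cohort(80, seed = 11, cens_frac = 0.5)
  m <- model_spec(c("sex", "age_spline"), name = "A-0")
  f1 <- fit_wgp(co, m, chain = quick_chain(800, 200, 2, seed = 99))
  f2 <- fit_wgp(co, m, chain = quick_chain(800, 200, 2, seed = 99))
  expect_identical(f1$chain, f2$chain)
  expect_identical(f1$posterior$beta_F, f2$posterior$beta_F)
  f3 <- fit_wgp(co, m, chain = quick_chain(800, 200, 2, seed = 100))
  expect_false(identical(f1$chain$sigma2e, f3$chain$sigma2e))
  # censoring bounds never violated in any retained draw
  expect_equal(f1$bounds_violations, 0L)
})

test_that("censored intercept model is unbiased while the naive fit is biased low", {
  co <- make_tobit_cohort(n = 400, mu = 75, sdv = 10, cpoint = 75, seed = 21)
  f <- fit_wgp(co, intercept_model(), chain = quick_chain(3000, 800, 2, seed = 5))
  mu_sd <- sd(f$draws_beta_F[, 1])
  expect_lt(abs(f$posterior$beta_F[[1]] - 75), 2.5 * mu_sd)
  naive <- make_tobit_cohort(n = 400, mu = 75, sdv = 10, cpoint = 75,
                             seed = 21, ignore_censoring = TRUE)
  fn <- fit_wgp(naive, intercept_model(), chain = quick_chain(1500, 400, 2, seed = 5))
  expect_lt(fn$posterior$beta_F[[1]], f$posterior$beta_F[[1]] - 1)
})

test_that("marker model recovers simulated genetic signal", {
  cfg <- sim_config(n_founders = 250, n_families = 50, p = 300, h2 = 0.4,
                    causal_frac = 0.2, seed = 31)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  m <- model_spec(c("sex", "age_spline", "smoking", "bmi_spline"),
                  markers = seq_len(300), name = "B-300")
  f <- fit_wgp(co, m, chain = quick_chain(2500, 500, 4, seed = 7))
  ghat <- as.vector(sweep(co$genotypes, 2, f$marker_centers) %*% f$posterior$beta_M)
  expect_gt(cor(ghat, sim$truth$g[co$ids]), 0.2)
  expect_gt(cor(f$posterior$beta_M, sim$truth$beta), 0.1)
})

test_that("prediction reproduces fitted values, linearity and marker-set checks", {
  cfg <- sim_config(n_founders = 120, n_families = 20, p = 60, seed = 41)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  m <- model_spec(c("sex", "age_spline"), markers = seq_len(60), name = "A-60")
  f <- fit_wgp(co, m, chain = quick_chain(1200, 300, 3, seed = 2))
  # predicting the training cohort returns the design-based posterior mean,
  # which matches the chain's running posterior-mean fitted values
  pr <- predict(f, co)
  expect_lt(max(abs(pr - f$posterior$fitted)), 0.5)
  expect_equal(predict(f), f$posterior$fitted)
  # doubling one marker dosage shifts the prediction by beta_j
  co2 <- co
  j <- which.max(abs(f$posterior$beta_M))
  co2$genotypes[1, j] <- co2$genotypes[1, j] + 1
  pr2 <- predict(f, co2)
  expect_equal(pr2[1] - pr[1], unname(f$posterior$beta_M[j]), tolerance = 1e-8)
  expect_equal(pr2[-1], pr[-1])
  # marker-set mismatch is reported with the offending names
  co3 <- subset_markers(co, 1:50)
  expect_error(predict(f, co3), "snp")
})

test_that("deviance and DIC follow their definitions", {
  # hand-computed observed-data deviance at fixed (mu = 0, sigma = 1)
  out <- data.frame(id = c("a", "b", "c"), age_entry = -5,
                    status = "observed", yl_lower = c(-1, 0, 2),
                    yl_upper = c(-1, 0, 2))
  enc <- wgplife:::encode_outcomes(out)
  dev <- wgplife:::observed_deviance(rep(0, 3), 1, enc)
  expect_equal(dev, -2 * sum(dnorm(c(-1, 0, 2), log = TRUE)), tolerance = 1e-10)
  # right-censored bound far below the mean (survival prob > 1/2)
  # contributes less deviance than one far above
  outr <- data.frame(id = c("a", "b"), age_entry = 0, status = "right",
                     yl_lower = c(60, 100), yl_upper = Inf)
  encr <- wgplife:::encode_outcomes(outr)
  d_lo <- wgplife:::observed_deviance(c(80, 80), 25, wgplife:::encode_outcomes(outr[1, ]))
  d_hi <- wgplife:::observed_deviance(c(80, 80), 25, wgplife:::encode_outcomes(outr[2, ]))
  expect_lt(d_lo, d_hi)
  # degenerate chain: all draws identical => pD = 0, DIC = that deviance
  fake <- structure(list(
    chain = data.frame(deviance = rep(dev, 20), sigma2e = 1),
    posterior = list(fitted = rep(0, 3), sigma2e = 1),
    outcomes_enc = enc), class = "wgp_fit")
  d <- dic(fake)
  expect_equal(d$pD, 0)
  expect_equal(d$DIC, dev)
  fake$chain <- fake$chain[1:5, ]
  expect_error(dic(fake), "10 retained")
})

test_that("joint sampler passes a successive-conditional (Geweke-style) check", {
  # tiny proper-prior model: y = X beta + e, p = 2 markers, n = 6,
  # Park-Casella hierarchy on beta, scaled-inv-chi2 on sigma2.
  set.seed(77)
  n <- 6; p <- 2
  X <- matrix(rnorm(n * p), n, p)
  xtx <- colSums(X^2)
  df0 <- 6; S0 <- 4; s <- 3; delta <- 2
  M <- 30000
  forward <- function() {
    lam2 <- rgamma(1, s, rate = delta)
    tau2 <- rexp(p, rate = lam2 / 2)
    s2 <- S0 / rchisq(1, df0)
    beta <- rnorm(p, 0, sqrt(tau2 * s2))
    c(s2 = s2, lam2 = lam2, b2 = sum(beta^2))
  }
  fw <- t(replicate(M, forward()))
  # successive-conditional: redraw data, then one Gibbs cycle
  lam2 <- rgamma(1, s, rate = delta); tau2 <- rexp(p, rate = lam2 / 2)
  s2 <- S0 / rchisq(1, df0); beta <- rnorm(p, 0, sqrt(tau2 * s2))
  sc <- matrix(NA_real_, M, 3)
  for (i in seq_len(M)) {
    y <- as.vector(X %*% beta) + rnorm(n, 0, sqrt(s2))
    r <- y - as.vector(X %*% beta)
    wgplife:::.gibbs_coef_sweep(X, r, beta, xtx, tau2 * s2, s2)
    tau2 <- wgplife:::.update_tau2(beta, lam2, s2)
    lam2 <- wgplife:::.update_lambda2(tau2, s, delta)
    s2 <- wgplife:::.draw_scaled_inv_chisq(df0, S0, sum(r^2) + sum(beta^2 / tau2),
                                           n + p)
    sc[i, ] <- c(s2, lam2, sum(beta^2))
  }
  # compare means with autocorrelation-inflated standard errors
  for (k in 1:3) {
    se_fw <- sd(fw[, k]) / sqrt(M)
    bm <- colMeans(matrix(sc[seq_len(M - M %% 100), k], nrow = 100))
    se_sc <- sd(bm) / sqrt(length(bm))
    z <- (mean(fw[, k]) - mean(sc[, k])) / sqrt(se_fw^2 + se_sc^2)
    expect_lt(abs(z), 5)
  }
})
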