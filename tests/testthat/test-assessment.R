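test_that("information criteria at a point-mass posterior reduce to the
           deviance identities", {
  d <- sim_small(n = 60, seed = 5)
  pm <- point_mass_fit(c(-0.5, 1), c(0.5, 0.5), d)
  ic <- information_criteria(pm)
  dhat <- -2 * loglik_zmps(list(beta1 = c(-0.5, 1), beta2 = c(0.5, 0.5)), d)
  expect_equal(ic$DIC, dhat, tolerance = 1e-10)
  expect_equal(ic$pD, 0, tolerance = 1e-10)
  n <- sum(d$w); dd <- 4
  expect_equal(ic$EBIC - ic$EAIC, dd * (log(n) - 2), tolerance = 1e-10)
})

test_that("effective parameter count is near the true dimension for a
           well-identified fit", {
  spec <- zmps_scenario("deflation", 1, "logit")
  set.seed(71)
  dat <- simulate_zmps_data(spec, n = 400)
  fit <- zmps_fit(dat, mcmc = quick_cfg(n_iter = 4000, burnin = 800,
                                        thin = 4, seed = 72))
  ic <- information_criteria(fit)
  expect_gt(ic$pD, 1.5)
  expect_lt(ic$pD, 7)
})

test_that("CPO matches the brute-force double loop and its bounds", {
  d <- sim_small(n = 25, seed = 9)
  fit <- zmps_fit(d, mcmc = quick_cfg(n_iter = 800, thin = 4, seed = 10))
  res <- cpo_nlmpl(fit)
  # brute force: per-observation harmonic mean over draws
  M <- nrow(fit$draws)
  f <- matrix(NA_real_, length(d$y), M)
  for (t in seq_len(M)) {
    b <- fit$draws[t, ]
    mu <- exp(drop(d$X1 %*% b[1:2]))
    om <- d$omega_link$linkinv(drop(d$X2 %*% b[3:4]))
    f[, t] <- dzmps(d$y, mu, om)
  }
  cpo_brute <- 1 / rowMeans(1 / f)
  expect_equal(res$cpo, cpo_brute, tolerance = 1e-10)
  expect_equal(res$NLMPL, -sum(d$w * log(cpo_brute)), tolerance = 1e-8)
  expect_true(all(res$cpo <= apply(f, 1, max) + 1e-12))
  expect_true(all(res$cpo > 0 & res$cpo <= 1))
  # point-mass draws: CPO is the plug-in density
  pm <- point_mass_fit(c(-0.5, 1), c(0.5, 0.5), d)
  rpm <- cpo_nlmpl(pm)
  mu <- exp(drop(d$X1 %*% c(-0.5, 1)))
  om <- plogis(drop(d$X2 %*% c(0.5, 0.5)))
  expect_equal(rpm$cpo, dzmps(d$y, mu, om), tolerance = 1e-12)
  expect_equal(rpm$NLMPL,
               -loglik_zmps(list(beta1 = c(-0.5, 1), beta2 = c(0.5, 0.5)),
                            d), tolerance = 1e-8)
})

test_that("Bayesian p-value is calibrated on self-simulated data and
           extreme under gross misspecification", {
  d <- sim_small(n = 300, seed = 33)
  fit <- zmps_fit(d, mcmc = quick_cfg(n_iter = 3000, burnin = 600,
                                      thin = 3, seed = 34))
  pb <- bayes_pvalue(fit, seed = 35)
  expect_gt(pb$p_value, 0.05)
  expect_lt(pb$p_value, 0.95)
  # reproducibility at fixed seed
  pb2 <- bayes_pvalue(fit, seed = 35)
  expect_identical(pb$p_value, pb2$p_value)
  # plain Poisson fit to heavily zero-inflated overdispersed data fails in
  # a known direction
  set.seed(36)
  x <- runif(300)
  yzi <- as.integer(rzmps(300, mu = exp(1 + x), omega = 0.3))
  dzi <- zmps_data(yzi, X1 = x)
  pfit <- zmps_fit(dzi, family = "poisson",
                   mcmc = quick_cfg(n_iter = 2000, thin = 2, seed = 37))
  pbp <- bayes_pvalue(pfit, seed = 38)
  expect_true(pbp$p_value > 0.99 || pbp$p_value < 0.01)
})

test_that("randomized quantile residuals are normal under the fitted
           model", {
  d <- sim_small(n = 400, seed = 44)
  fit <- zmps_fit(d, mcmc = quick_cfg(n_iter = 3000, burnin = 600,
                                      thin = 3, seed = 45))
  r <- rqr(fit, seed = 46)
  expect_length(r, sum(d$w))
  expect_gt(ks.test(r, "pnorm")$p.value, 0.01)
  expect_identical(r, rqr(fit, seed = 46))
  # the randomization interval is always well ordered
  ft <- zmps_fitted(list(beta1 = posterior_mean(fit)[1:2],
                         beta2 = posterior_mean(fit)[3:4]), d)
  lo <- pzmps(d$y - 1, ft$mu, ft$omega)
  hi <- pzmps(d$y, ft$mu, ft$omega)
  expect_true(all(hi > lo))
})

test_that("influence divergences are zero at a point mass and detect a
           planted outlier", {
  d <- sim_small(n = 40, seed = 55)
  pm <- point_mass_fit(c(-0.5, 1), c(0.5, 0.5), d)
  infl <- influence_divergence(pm)
  expect_equal(infl$KL, rep(0, nrow(infl)), tolerance = 1e-10)
  expect_equal(infl$KL_calibration, rep(0.5, nrow(infl)),
               tolerance = 1e-6)
  expect_equal(infl$H_calibration, rep(0.5, nrow(infl)), tolerance = 1e-4)
  # calibration is monotone in the divergence
  kl <- c(0, 0.01, 0.1, 0.5, 2)
  cal <- 0.5 * (1 + sqrt(1 - exp(-2 * kl)))
  expect_true(all(diff(cal) > 0))
  # contaminate a clean dataset with one gross outlier
  set.seed(56)
  x <- runif(80)
  y <- as.integer(rzmps(80, exp(-0.5 + x), plogis(0.5 + 0.5 * x)))
  y[80] <- 25L
  dc <- zmps_data(y, X1 = x)
  fit <- zmps_fit(dc, mcmc = quick_cfg(n_iter = 2000, thin = 2, seed = 57))
  inf2 <- influence_divergence(fit)
  expect_equal(which.max(inf2$KL_calibration), 80L)
  expect_equal(which.max(inf2$H_calibration), 80L)
})

test_that("goodness-of-fit table pools, merges and normalizes", {
  d <- sim_small(n = 500, seed = 66)
  fit <- zmps_fit(d, mcmc = quick_cfg(n_iter = 2000, thin = 2, seed = 67))
  g <- grouped_gof(fit)
  expect_equal(sum(g$table$expected), sum(d$w), tolerance = 1e-6)
  expect_equal(sum(g$table$observed), sum(d$w))
  expect_gte(g$df, 1)
  expect_equal(g$df, nrow(g$table) - 1)
  # all trailing merged cells exceed the threshold except possibly the
  # first retained ones
  expect_true(all(g$table$expected[-seq_len(2)] > 0))
  # n0_hat for a hurdle fit is the summed fitted zero probability
  ft <- zmps_fitted(split_beta_test(fit), d)
  expect_equal(g$n0_hat, sum(d$w * (1 - ft$omega)), tolerance = 1e-8)
  # posterior-predictive expected frequencies also sum to n, and at a
  # point-mass posterior they coincide with the plug-in table
  pm <- point_mass_fit(split_beta_test(fit)$beta1,
                       split_beta_test(fit)$beta2, fit$data)
  gp <- grouped_gof(pm, expected = "predictive")
  expect_equal(sum(gp$table$expected), sum(d$w), tolerance = 1e-6)
  expect_equal(gp$chi2, grouped_gof(pm)$chi2, tolerance = 1e-8)
})
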