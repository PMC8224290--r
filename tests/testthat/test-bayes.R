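test_that("g-prior covariance follows the unit-information scaling", {
  expect_equal(g_prior(matrix(1, 7, 1))$cov, matrix(1, 1, 1))
  # orthogonal design with column norms sqrt(n) gives the identity
  n <- 16
  X <- cbind(rep(1, n), rep(c(1, -1), n / 2))
  expect_equal(g_prior(X)$cov, diag(2))
  # duplicated column: generalized inverse plus warning, still finite
  Xd <- cbind(1, runif(10), 0)
  Xd[, 3] <- Xd[, 2]
  expect_warning(pr <- g_prior(Xd), "generalized inverse")
  expect_true(all(is.finite(pr$cov)))
  expect_equal(pr$cov, t(pr$cov))
  # weighted (grouped) cross-product equals the expanded one
  Xg <- cbind(1, c(0.1, 0.5)); w <- c(3, 2)
  Xl <- Xg[rep(1:2, w), ]
  expect_equal(g_prior(Xg, weights = w)$cov, g_prior(Xl)$cov)
})

test_that("numeric Hessian is exact on quadratics and symmetric", {
  A <- matrix(c(3, 1, 1, 2), 2)
  f <- function(x) -0.5 * drop(crossprod(x, A %*% x)) + sum(x)
  H <- neg_hessian(f, c(0.3, -0.8))
  expect_equal(H, A, tolerance = 1e-6)
  g <- function(x) sum(sin(x)) - 0.1 * sum(x^4)
  Hg <- neg_hessian(g, c(0.4, 1.2, -0.5))
  expect_equal(Hg, t(Hg))
  # pure Gaussian prior with flat likelihood: H equals the precision
  pr <- g_prior(cbind(1, c(0.2, 0.9, 0.4)))
  lp <- function(b) log_posterior_block(b, function(bb) 0, pr)
  expect_equal(neg_hessian(lp, c(0.1, -0.2)), pr$prec, tolerance = 1e-4)
})

test_that("block log-posterior combines likelihood and prior", {
  d <- sim_small(n = 40, seed = 2)
  pr <- g_prior(d$X1, d$w)
  lt <- function(b) log_posterior_block(b, function(bb)
    loglik_positive(bb, d), pr)
  expect_equal(lt(c(0, 0)), loglik_positive(c(0, 0), d))
  b <- c(0.3, -0.2)
  expect_equal(lt(b),
               loglik_positive(b, d) -
                 0.5 * drop(crossprod(b, pr$prec %*% b)),
               tolerance = 1e-12)
  # finite-difference gradient vanishes at the located mode
  opt <- optim(c(0, 0), function(b) -lt(b), method = "BFGS")
  h <- 1e-5
  grad <- vapply(1:2, function(j) {
    e <- numeric(2); e[j] <- h
    (lt(opt$par + e) - lt(opt$par - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(grad)), 1e-3)
})

test_that("sampler recovers a conjugate normal posterior", {
  # Gaussian likelihood + Gaussian prior: posterior available in closed
  # form, so the MH kernel's invariant distribution can be checked
  set.seed(100)
  n <- 40; sigma <- 1.5
  x <- rnorm(n); yobs <- rnorm(n, 2 * x, sigma)
  prec_post <- sum(x^2) / sigma^2 + 1 / 4
  mean_post <- (sum(x * yobs) / sigma^2) / prec_post
  lt <- function(b) -0.5 * sum((yobs - b * x)^2) / sigma^2 - 0.5 * b^2 / 4
  for (mode in c("shrunken", "centered")) {
    cfg <- mh_config(n_iter = 20000, burnin = 2000, thin = 2, seed = 7,
                     proposal = mode, hessian_refresh = "cached",
                     nu = n / (n + 1))
    out <- mh_sample(lt, 0, cfg)
    m <- mean(out$draws); v <- var(drop(out$draws))
    expect_lt(abs(m - mean_post), 4 * sqrt(1 / prec_post / 500))
    expect_lt(abs(v - 1 / prec_post) / (1 / prec_post), 0.2)
    expect_true(out$accept > 0 && out$accept < 1)
  }
})

test_that("fits are bit-reproducible under a fixed seed", {
  d <- sim_small(n = 60, seed = 17)
  f1 <- zmps_fit(d, mcmc = quick_cfg(n_iter = 600, thin = 2, seed = 99))
  f2 <- zmps_fit(d, mcmc = quick_cfg(n_iter = 600, thin = 2, seed = 99))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$accept, f2$accept)
})

test_that("posterior mean and HPDI follow their definitions", {
  expect_equal(posterior_mean(matrix(c(1, 1, 5, 5), 2)), c(1, 5))
  expect_equal(posterior_mean(rbind(c(0, 2), c(4, 6))), c(2, 4))
  set.seed(3)
  dr <- matrix(rnorm(3000), ncol = 3)
  expect_equal(posterior_mean(dr), colMeans(dr))
  # shortest window over sorted draws
  expect_equal(unname(hpdi(1:100, 0.95)), c(1, 95))
  # symmetric sample: close to the equal-tail interval
  xs <- rnorm(20000)
  expect_equal(unname(hpdi(xs, 0.9)), unname(quantile(xs, c(0.05, 0.95))),
               tolerance = 0.05)
  # skewed sample: strictly shorter than equal tails
  xe <- rexp(20000)
  et <- unname(diff(quantile(xe, c(0.025, 0.975))))
  expect_lt(diff(hpdi(xe, 0.95)), et)
})

test_that("diagnostics behave on iid and autocorrelated chains", {
  set.seed(42)
  M <- 4000
  iid <- matrix(rnorm(2 * M), ncol = 2)
  dg <- mcmc_diagnostics(iid)
  expect_true(all(abs(dg$geweke_z) < 3))
  expect_true(all(dg$rhat < 1.01))
  expect_true(all(dg$ess > 0.8 * M))
  # AR(1) with rho = 0.5 has ESS about M/3
  rho <- 0.5
  ar <- as.numeric(arima.sim(list(ar = rho), n = M))
  e <- mcmc_diagnostics(matrix(ar))$ess
  expect_lt(abs(e - M * (1 - rho) / (1 + rho)) / (M / 3), 0.35)
  # agreement with an established estimator on the same chain
  if (requireNamespace("coda", quietly = TRUE)) {
    e2 <- unname(coda::effectiveSize(ar))
    expect_lt(abs(e - e2) / e2, 0.35)
  }
  # constant chain and short chain edge cases
  expect_true(is.na(mcmc_diagnostics(matrix(rnorm(50)))$ess))
})

test_that("posterior predictive pmf collapses correctly and normalizes", {
  d <- sim_small(n = 50, seed = 23)
  beta1 <- c(-0.2, 0.6); beta2 <- c(0.4, 0.3)
  pm <- point_mass_fit(beta1, beta2, d)
  x1 <- c(1, 0.5); x2 <- c(1, 0.5)
  mu <- exp(sum(x1 * beta1)); om <- plogis(sum(x2 * beta2))
  expect_equal(posterior_predictive_pmf(pm, 0:6, x1, x2),
               dzmps(0:6, mu, om), tolerance = 1e-12)
  # spread draws: normalization and the zero shortcut
  fit <- zmps_fit(d, mcmc = quick_cfg(n_iter = 1000, thin = 2, seed = 4))
  pv <- posterior_predictive_pmf(fit, 0:80, x1, x2)
  expect_lt(abs(sum(pv) - 1), 1e-6)
  om_t <- plogis(fit$draws[, 3] + 0.5 * fit$draws[, 4])
  expect_equal(pv[1], mean(1 - om_t), tolerance = 1e-12)
})

test_that("parameter recovery on a simulated inflation design", {
  # inflation scenario 4 truth: beta1 = (1.5, -1.5), beta2 = (-1, 0.5)
  spec <- zmps_scenario("inflation", 4, "logit")
  set.seed(61)
  dat <- simulate_zmps_data(spec, n = 500)
  fit <- zmps_fit(dat, mcmc = mh_config(n_iter = 6000, burnin = 1200,
                                        thin = 4, seed = 62,
                                        hessian_refresh = "cached"))
  est <- posterior_mean(fit)
  sds <- apply(fit$draws, 2, sd)
  truth <- attr(dat, "truth")
  expect_true(all(abs(est - truth) < 3.5 * sds))
})
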