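## Zero-modified data simulator and the Monte Carlo harness evaluating the
## frequentist performance of the Bayesian point estimator and HPDIs.

## true coefficient values of the eight study scenarios: a single U(0,1)
## covariate shared by both components (X2 = X1), log link for mu
scenario_table <- function() {
  data.frame(
    case = rep(c("inflation", "deflation"), each = 4),
    scenario = rep(1:4, 2),
    b10 = c(1.5, 1.5, 1.5, 1.5, -1, -1, -1, -1),
    b11 = c(3, 3, -1.5, -1.5, 1, 1, -1.5, -1.5),
    b20 = c(-1, -1, -1, -1, 0.5, 1.5, 0.5, 1.5),
    b21 = c(-1, 0.5, -1, 0.5, 0.5, -1, 0.5, -1))
}

#' Simulation scenario specification
#'
#' The predefined zero-inflation and zero-deflation scenarios: true
#' coefficients for the two linear predictors `beta10 + beta11 x` (log
#' scale of `mu`) and `beta20 + beta21 x` (link scale of `omega`), with a
#' single Uniform(0,1) covariate shared by both components.  Inflation
#' scenarios keep the zero-modification parameter `p` below 1 across the
#' covariate range; deflation scenarios keep it at or above 1.
#'
#' @param case `"inflation"` or `"deflation"`.
#' @param scenario integer 1-4.
#' @param omega_link link of the binary component.
#' @param replicates default number of Monte Carlo replicates.
#' @return An object of class `zmps_scenario`.
#' @export
#' @examples
#' zmps_scenario("deflation", 1, "logit")
zmps_scenario <- function(case = c("inflation", "deflation"), scenario = 1,
                          omega_link = c("logit", "probit", "cloglog"),
                          replicates = 500) {
  case <- match.arg(case)
  omega_link <- match.arg(omega_link)
  stopifnot(scenario %in% 1:4)
  tab <- scenario_table()
  row <- tab[tab$case == case & tab$scenario == scenario, ]
  structure(list(case = case, scenario = scenario,
                 omega_link = omega_link,
                 beta1 = c(row$b10, row$b11), beta2 = c(row$b20, row$b21),
                 replicates = replicates),
            class = "zmps_scenario")
}

#' @export
print.zmps_scenario <- function(x, ...) {
  rng <- scenario_ranges(x)
  cat("<zmps_scenario>", x$case, "scenario", x$scenario,
      "(", x$omega_link, "link )\n")
  cat("  beta1 =", x$beta1, "; beta2 =", x$beta2, "\n")
  cat("  mu range:", paste(rng$mu_range, collapse = " - "),
      "; p range:", paste(rng$p_range, collapse = " - "), "\n")
  invisible(x)
}

#' Parameter ranges implied by a scenario
#'
#' Evaluates the linear predictors at the covariate endpoints `x = 0` and
#' `x = 1`: the `mu` range is `exp()` of the mean predictor and the `p`
#' range follows from `p = omega / P(Y > 0; mu)` at the matched
#' endpoints.  Ranges are returned ordered and rounded to two decimals,
#' the reporting convention of the study design.
#'
#' @param spec a [zmps_scenario()].
#' @return A list with `mu_range` and `p_range` (each length 2, sorted).
#' @export
scenario_ranges <- function(spec) {
  lk <- zmps_link(spec$omega_link)
  mu <- exp(spec$beta1[1] + spec$beta1[2] * c(0, 1))
  om <- lk$linkinv(spec$beta2[1] + spec$beta2[2] * c(0, 1))
  p <- p_from_omega(mu, om)
  list(mu_range = round(sort(mu), 2), p_range = round(sort(p), 2))
}

#' Simulate one zero-modified regression dataset
#'
#' Draws the covariate `x ~ U(0,1)` i.i.d., forms `mu_i` and `omega_i`
#' from the scenario's true coefficients and generates responses with the
#' sequential-search sampler [rzmps()].
#'
#' @param spec a [zmps_scenario()].
#' @param n sample size.
#' @param seed optional seed.
#' @param x optional fixed covariate vector (overrides random generation,
#'   for fixed-design studies).
#' @return A [zmps_data()] object with attribute `"truth"` holding the
#'   generating coefficients.
#' @export
simulate_zmps_data <- function(spec, n, seed = NULL, x = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x)) x <- stats::runif(n)
  lk <- zmps_link(spec$omega_link)
  mu <- exp(spec$beta1[1] + spec$beta1[2] * x)
  om <- lk$linkinv(spec$beta2[1] + spec$beta2[2] * x)
  y <- rzmps(n, mu, om)
  d <- zmps_data(as.integer(y), X1 = x, omega_link = lk)
  attr(d, "truth") <- c(spec$beta1, spec$beta2)
  d
}

#' Monte Carlo evaluation of the Bayesian estimators
#'
#' Repeatedly simulates datasets from a scenario, fits the hurdle model to
#' each, and summarizes the posterior-mean point estimator and the 95%
#' HPDIs by bias, mean squared error, variance (`MSE - bias^2`), mean
#' absolute percentage error, and the coverage (CP), below-noncoverage
#' (BNCP) and above-noncoverage (ANCP) probabilities.
#'
#' @param spec a [zmps_scenario()].
#' @param n sample size per replicate.
#' @param replicates number of Monte Carlo replicates (defaults to the
#'   scenario's `replicates`).
#' @param mcmc an [mh_config()] used for every replicate fit (its `seed`
#'   is ignored; per-replicate seeds derive from `seed`).
#' @param seed master seed; per-replicate seeds are drawn from it once.
#' @param level HPDI mass for the coverage measures.
#' @return An object of class `zmps_study`: a list with `performance`
#'   (data frame, one row per parameter), `estimates` (replicates x
#'   parameters matrix), `spec`, `n`, and `failed` (count of failed
#'   replicate fits, excluded from the summaries).
#' @export
run_study <- function(spec, n, replicates = NULL,
                      mcmc = mh_config(n_iter = 4000, burnin = 800,
                                       thin = 4,
                                       hessian_refresh = "cached"),
                      seed = 1, level = 0.95) {
  if (is.null(replicates)) replicates <- spec$replicates
  stopifnot(replicates >= 2)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  truth <- c(spec$beta1, spec$beta2)
  d <- length(truth)
  est <- matrix(NA_real_, replicates, d)
  lo <- hi <- matrix(NA_real_, replicates, d)
  failed <- 0L
  for (r in seq_len(replicates)) {
    mcmc$seed <- rep_seeds[r]
    res <- tryCatch({
      set.seed(rep_seeds[r])
      dat <- simulate_zmps_data(spec, n)
      fit <- zmps_fit(dat, family = "zmps", mcmc = mcmc)
      list(mean = posterior_mean(fit), hp = hpdi(fit$draws, level))
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    est[r, ] <- res$mean
    lo[r, ] <- res$hp[, 1]; hi[r, ] <- res$hp[, 2]
  }
  ok <- !is.na(est[, 1])
  perf <- performance_table(est[ok, , drop = FALSE], truth,
                            lo[ok, , drop = FALSE], hi[ok, , drop = FALSE])
  structure(list(performance = perf, estimates = est, spec = spec, n = n,
                 replicates = replicates, failed = failed, seed = seed),
            class = "zmps_study")
}

#' Estimator performance measures
#'
#' The plug-in Monte Carlo estimators of bias
#' `B = mean(est - truth)`, `MSE = mean((est - truth)^2)`,
#' `variance = MSE - B^2`, `MAPE = mean(|est - truth| / |truth|)` and the
#' interval-based CP/BNCP/ANCP (which sum to 1 by construction).
#'
#' @param estimates replicates x parameters matrix of point estimates.
#' @param truth true parameter vector.
#' @param lower,upper matrices of interval bounds (optional; coverage
#'   columns are `NA` without them).
#' @return Data frame with one row per parameter.
#' @export
performance_table <- function(estimates, truth, lower = NULL, upper = NULL) {
  estimates <- as.matrix(estimates)
  stopifnot(ncol(estimates) == length(truth))
  err <- sweep(estimates, 2, truth)
  bias <- colMeans(err)
  mse <- colMeans(err^2)
  out <- data.frame(
    parameter = names(truth) %||%
      c("beta10", "beta11", "beta20", "beta21")[seq_along(truth)],
    truth = truth, bias = bias, mse = mse,
    variance = mse - bias^2,
    mape = colMeans(abs(err) / rep(abs(truth), each = nrow(err))),
    row.names = NULL)
  if (!is.null(lower)) {
    truth_below <- sweep(lower, 2, truth, ">")  # interval entirely above
    truth_above <- sweep(upper, 2, truth, "<")  # interval entirely below
    out$cp <- colMeans(!truth_below & !truth_above)
    out$bncp <- colMeans(truth_below)
    out$ancp <- colMeans(truth_above)
  }
  out
}

#' @export
print.zmps_study <- function(x, ...) {
  cat("Monte Carlo study:", x$spec$case, "scenario", x$spec$scenario,
      "(", x$spec$omega_link, "), n =", x$n, ",",
      sum(!is.na(x$estimates[, 1])), "replicates",
      if (x$failed) paste0("(", x$failed, " failed)") else "", "\n")
  print(x$performance, digits = 3)
  invisible(x)
}
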