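## Model assessment: information criteria, conditional predictive
## ordinates, posterior predictive (Bayesian) p-value, randomized quantile
## residuals, case-deletion influence divergences, and the pooled
## goodness-of-fit chi-square on the outcome frequency table.

## per-draw per-row matrix of log f(y_i | beta_t) under the fitted model
## (single-subject densities; weights are applied by the callers)
loglik_matrix <- function(fit, draws = fit$draws) {
  data <- fit$data; fam <- fit$family
  M <- nrow(draws)
  b1 <- draws[, seq_len(fit$q1), drop = FALSE]
  mu <- exp(tcrossprod(data$X1, b1))            # rows x M
  if (!fam$hurdle) {
    lf <- fam$log_dens(rep(data$y, M), as.vector(mu))
    return(matrix(lf, ncol = M))
  }
  b2 <- draws[, fit$q1 + seq_len(fit$q2), drop = FALSE]
  om <- fit$data$omega_link$linkinv(tcrossprod(data$X2, b2))
  lf <- matrix(base::log(1 - om), ncol = M)
  pos <- data$pos
  if (any(pos)) {
    mup <- mu[pos, , drop = FALSE]
    lt <- fam$log_dens(rep(data$y[pos], M), as.vector(mup)) -
      fam$log_ppos(as.vector(mup))
    lf[pos, ] <- base::log(om[pos, , drop = FALSE]) + matrix(lt, ncol = M)
  }
  lf
}

## per-draw total log-likelihood (weighted)
loglik_per_draw <- function(fit) {
  drop(crossprod(fit$data$w, loglik_matrix(fit)))
}

#' Information criteria from posterior draws
#'
#' With deviance `D(beta) = -2 loglik`, computes Spiegelhalter's
#' `DIC = Dbar + pD` where `pD = Dbar - D(betahat)`, and the
#' expected-deviance criteria `EAIC = Dbar + 2 d` and
#' `EBIC = Dbar + d log n` with `d` regression parameters and `n`
#' subjects.
#'
#' @param fit a `zmps_fit` object.
#' @return A list with `DIC`, `EAIC`, `EBIC`, `pD`, `Dbar` and `Dhat`.
#' @export
information_criteria <- function(fit) {
  dev <- -2 * loglik_per_draw(fit)
  dbar <- mean(dev)
  dhat <- -2 * loglik_zmps(split_beta(fit), fit$data, fit$family)
  d <- fit$q1 + fit$q2
  n <- sum(fit$data$w)
  list(DIC = 2 * dbar - dhat, EAIC = dbar + 2 * d,
       EBIC = dbar + d * base::log(n), pD = dbar - dhat,
       Dbar = dbar, Dhat = dhat)
}

#' Conditional predictive ordinates and pseudo-marginal likelihood
#'
#' `CPO_i` is the harmonic mean of the per-draw densities
#' `f(y_i | beta^(t))`, the Monte Carlo estimate of the leave-one-out
#' predictive ordinate; the negative log pseudo-marginal likelihood is
#' `NLMPL = -sum_i w_i log CPO_i`.
#'
#' @param fit a `zmps_fit` object.
#' @return A list with `cpo` (one value per data row) and `NLMPL`.
#' @export
cpo_nlmpl <- function(fit) {
  lf <- loglik_matrix(fit)
  ## harmonic mean in log space: -log mean exp(-lf)
  lcpo <- apply(lf, 1, function(r) {
    mx <- max(-r)
    -(mx + base::log(mean(exp(-r - mx))))
  })
  list(cpo = exp(lcpo), NLMPL = -sum(fit$data$w * lcpo))
}

## draw n values from the fitted (possibly plain) family by inverse cdf
r_family <- function(n, mu, omega, fam) {
  if (fam$hurdle) return(r_hurdle(n, mu, omega, fam))
  u <- stats::runif(n)
  findInterval(u, 1 - fam$surv(0:200, rep(mu, 201)), left.open = TRUE)
}

r_hurdle <- function(n, mu, omega, fam) {
  u <- stats::runif(n)
  cdf <- 1 - omega * fam$surv(0:200, rep(mu, 201)) / exp(fam$log_ppos(mu))
  findInterval(u, cdf, left.open = TRUE)
}

#' Posterior predictive (Bayesian) p-value
#'
#' Chi-square discrepancy check: for each retained draw
#' `D(y; beta) = sum_i (y_i - lambda_i)^2 / varsigma_i^2` is compared
#' between the observed data and a replicate dataset simulated from the
#' fitted model at that draw; the p-value is the proportion of draws where
#' the replicate discrepancy is at least the observed one.  Values near 0
#' or 1 indicate misfit.
#'
#' @param fit a `zmps_fit` object.
#' @param n_draws number of (evenly thinned) draws used; default
#'   `min(M, 1000)`.
#' @param seed optional seed for the replicate simulation.
#' @return A list with `p_value`, `D_obs` and `D_rep` (per-draw
#'   discrepancies).
#' @export
bayes_pvalue <- function(fit, n_draws = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- nrow(fit$draws)
  if (is.null(n_draws)) n_draws <- min(M, 1000)
  use <- unique(round(seq(1, M, length.out = n_draws)))
  data <- fit$data
  ## group rows by covariate pattern: replicates are drawn per pattern
  key <- apply(cbind(data$X1, data$X2), 1, paste, collapse = "\r")
  pat <- match(key, unique(key))
  npat <- tabulate(pat)
  wsub <- vapply(seq_len(max(pat)), function(j)
    sum(data$w[pat == j]), numeric(1))
  first <- match(seq_len(max(pat)), pat)
  d_obs <- d_rep <- numeric(length(use))
  for (s in seq_along(use)) {
    beta <- split_beta(fit, fit$draws[use[s], ])
    ft <- zmps_fitted(beta, data, fit$family)
    d_obs[s] <- sum(data$w * (data$y - ft$lambda)^2 / ft$var)
    dr <- 0
    for (j in seq_len(max(pat))) {
      i <- first[j]
      yr <- r_family(wsub[j], ft$mu[i],
                     if (fit$family$hurdle) ft$omega[i] else NULL,
                     fit$family)
      dr <- dr + sum((yr - ft$lambda[i])^2) / ft$var[i]
    }
    d_rep[s] <- dr
  }
  list(p_value = mean(d_rep >= d_obs), D_obs = d_obs, D_rep = d_rep)
}

#' Randomized quantile residuals
#'
#' For each subject a uniform deviate is drawn on the interval
#' `(F(y_i - 1), F(y_i))` of the fitted cdf and mapped through the
#' standard normal quantile function.  Under a correctly specified model
#' the residuals are approximately i.i.d. standard normal.  Weighted
#' (grouped) rows are expanded to one residual per subject.
#'
#' @param fit a `zmps_fit` object.
#' @param beta coefficient vector at which the cdf is evaluated; default
#'   the posterior mean.
#' @param seed optional seed for the uniform randomization.
#' @return Numeric vector with one residual per subject.
#' @export
rqr <- function(fit, beta = posterior_mean(fit), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data <- fit$data; fam <- fit$family
  ft <- zmps_fitted(split_beta(fit, beta), data, fam)
  cdf_at <- function(q) {
    out <- numeric(length(q))
    ok <- q >= 0
    if (any(ok)) {
      if (fam$hurdle) {
        out[ok] <- 1 - ft$omega[ok] * fam$surv(q[ok], ft$mu[ok]) /
          exp(fam$log_ppos(ft$mu[ok]))
      } else {
        out[ok] <- 1 - fam$surv(q[ok], ft$mu[ok])
      }
    }
    out
  }
  lo <- cdf_at(data$y - 1)
  hi <- cdf_at(data$y)
  idx <- expand_index(data)
  u <- stats::runif(length(idx), lo[idx], hi[idx])
  stats::qnorm(u)
}

## Hellinger calibration: p >= 1/2 such that the Hellinger divergence
## between Bernoulli(1/2) and Bernoulli(p) equals the estimated divergence
calibrate_hellinger <- function(h) {
  a <- pmin(pmax(1 - h, sqrt(0.5)), 1)   # Bernoulli affinity
  0.5 * (1 + sqrt(pmax(1 - 4 * (a^2 - 0.5)^2, 0)))
}

#' Case-deletion influence diagnostics
#'
#' Kullback-Leibler and Hellinger divergences between the full posterior
#' and the posterior without observation `i`, estimated from the posterior
#' sample through the usual importance-weight identities:
#' `KL_i = log((1/M) sum_t 1/f_it) + (1/M) sum_t log f_it` and
#' `H_i = 1 - (1/M) sum_t sqrt(CPO_i / f_it)`, with
#' `f_it = f(y_i | beta^(t))`.  Divergences are mapped to the calibration
#' scale `[0.5, 1)`; `0.5*(1 + sqrt(1 - exp(-2 KL)))` for KL and the
#' Bernoulli-matching calibration for Hellinger.  Observations whose
#' calibration exceeds `threshold` are flagged.
#'
#' @param fit a `zmps_fit` object.
#' @param threshold calibration above which a row is flagged influential
#'   (reporting default 0.65).
#' @return Data frame with one row per data row: `y`, weight, `cpo`,
#'   `KL`, `KL_calibration`, `H`, `H_calibration`, `influential`.
#' @export
influence_divergence <- function(fit, threshold = 0.65) {
  lf <- loglik_matrix(fit)
  lcpo <- apply(lf, 1, function(r) {
    mx <- max(-r)
    -(mx + base::log(mean(exp(-r - mx))))
  })
  kl <- -lcpo + rowMeans(lf)
  ## CPO_i <= geometric mean of f_it, so kl >= 0 up to Monte Carlo noise
  if (any(kl < -1e-8))
    warning("negative KL estimate clamped to zero (Monte Carlo noise)")
  kl <- pmax(kl, 0)
  aff <- rowMeans(exp(0.5 * (lcpo - lf)))   # mean sqrt(CPO_i / f_it)
  hel <- pmax(1 - aff, 0)
  calk <- 0.5 * (1 + sqrt(pmax(1 - exp(-2 * kl), 0)))
  calh <- calibrate_hellinger(hel)
  data.frame(y = fit$data$y, weight = fit$data$w, cpo = exp(lcpo),
             KL = kl, KL_calibration = calk,
             H = hel, H_calibration = calh,
             influential = calk > threshold)
}

#' Pooled goodness-of-fit chi-square on the outcome frequency table
#'
#' Expected frequencies of each outcome value are sums of fitted
#' single-subject probabilities over all subjects (plug-in at the
#' posterior mean by default, or the posterior predictive mixture).  The
#' final cell is the upper tail at the largest observed outcome so the
#' expected counts sum to `n`; trailing cells with expected count at or
#' below `threshold` are merged into the adjacent lower cell, and
#' `chi^2 = sum (obs - exp)^2 / exp` with `df = cells - 1`.
#'
#' @param fit a `zmps_fit` object.
#' @param threshold merge cells with expected frequency at or below this
#'   value (default 5).
#' @param expected `"plugin"` (default) evaluates probabilities at the
#'   posterior mean; `"predictive"` averages them over the posterior
#'   draws via [posterior_predictive_pmf()]-style block means.
#' @param beta coefficient vector for the plug-in evaluation.
#' @return A list with `chi2`, `df`, `p_value`, `table` (observed and
#'   expected by merged cell), `n0_hat` (expected zero count), and the
#'   model-based marginal moments `lambda_hat` and `var_hat` averaged over
#'   subjects.
#' @export
grouped_gof <- function(fit, threshold = 5,
                        expected = c("plugin", "predictive"),
                        beta = posterior_mean(fit)) {
  expected <- match.arg(expected)
  data <- fit$data; fam <- fit$family
  n <- sum(data$w)
  vmax <- max(data$y)
  obs <- vapply(0:vmax, function(v) sum(data$w[data$y == v]), numeric(1))
  ft <- zmps_fitted(split_beta(fit, beta), data, fam)
  cell_prob <- function(v) {
    if (fam$hurdle) {
      if (v == 0) 1 - ft$omega
      else ft$omega * exp(fam$log_dens(v, ft$mu) - fam$log_ppos(ft$mu))
    } else exp(fam$log_dens(v, ft$mu))
  }
  if (expected == "plugin") {
    ex <- vapply(0:(vmax - 1), function(v) sum(data$w * cell_prob(v)),
                 numeric(1))
  } else {
    ex <- vapply(0:(vmax - 1), function(v) {
      pv <- vapply(seq_len(length(data$y)), function(i)
        posterior_predictive_pmf(fit, v, x1 = data$X1[i, ],
                                 x2 = data$X2[i, ]), numeric(1))
      sum(data$w * pv)
    }, numeric(1))
  }
  ex <- c(ex, n - sum(ex))   # upper tail cell
  labels <- c(as.character(0:(vmax - 1)), paste0(">=", vmax))
  while (length(ex) > 2 && ex[length(ex)] <= threshold) {
    k <- length(ex)
    ex[k - 1] <- ex[k - 1] + ex[k]; obs[k - 1] <- obs[k - 1] + obs[k]
    labels[k - 1] <- paste0(">=", k - 2)
    ex <- ex[-k]; obs <- obs[-k]; labels <- labels[-k]
  }
  if (length(ex) < 2) stop("fewer than 2 cells after merging")
  chi2 <- sum((obs - ex)^2 / ex)
  df <- length(ex) - 1
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       table = data.frame(cell = labels, observed = obs, expected = ex),
       n0_hat = if (fam$hurdle) sum(data$w * (1 - ft$omega))
                else sum(data$w * exp(fam$log_dens(0, ft$mu))),
       lambda_hat = sum(data$w * ft$lambda) / n,
       var_hat = sum(data$w * ft$var) / n)
}

#' Full assessment report for a fitted model
#'
#' Bundles [information_criteria()], [cpo_nlmpl()], [bayes_pvalue()],
#' [grouped_gof()], [influence_divergence()] and [rqr()].
#'
#' @param fit a `zmps_fit` object.
#' @param seed seed for the stochastic components (replicates and residual
#'   randomization).
#' @param gof_threshold cell-merging threshold for the chi-square table.
#' @return An object of class `zmps_assessment`.
#' @export
assess <- function(fit, seed = NULL, gof_threshold = 5) {
  ic <- information_criteria(fit)
  cp <- cpo_nlmpl(fit)
  pb <- bayes_pvalue(fit, seed = seed)
  gof <- grouped_gof(fit, threshold = gof_threshold)
  structure(list(
    criteria = c(DIC = ic$DIC, EAIC = ic$EAIC, EBIC = ic$EBIC,
                 NLMPL = cp$NLMPL, pB = pb$p_value),
    ic = ic, cpo = cp$cpo, gof = gof,
    influence = influence_divergence(fit),
    rqr = rqr(fit, seed = seed),
    family = fit$family$name), class = "zmps_assessment")
}

#' @export
print.zmps_assessment <- function(x, ...) {
  cat("Model assessment (", x$family, " family)\n", sep = "")
  print(round(x$criteria, 3))
  cat(sprintf("chi2 = %.3f on %d df (p = %.3f); n0_hat = %.1f; ",
              x$gof$chi2, x$gof$df, x$gof$p_value, x$gof$n0_hat))
  cat(sprintf("lambda_hat = %.3f; var_hat = %.3f\n",
              x$gof$lambda_hat, x$gof$var_hat))
  ninf <- sum(x$influence$influential)
  cat(ninf, "observation row(s) flagged influential\n")
  invisible(x)
}
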