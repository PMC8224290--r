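## Bayesian engine: g-prior construction, numeric Hessians, and the block
## Metropolis-Hastings sampler with shrunken Hessian-based proposals.

#' Zellner-style g-prior for a coefficient block
#'
#' The prior is `beta_k ~ N(0, n * (Xk' Xk)^-1)`, the unit-information
#' scaling of the Fisher-information correlation structure.  For weighted
#' (grouped) data the cross-product is taken over the expanded design, i.e.
#' `Xk' W Xk`, which is identical to the long-format cross-product.  When
#' the cross-product is singular a Moore-Penrose generalized inverse is
#' used and a warning is emitted.
#'
#' @param X design matrix of the block.
#' @param weights case weights (frequency counts); default 1.
#' @param n prior variance factor; defaults to the number of subjects
#'   `sum(weights)`.
#' @return An object of class `g_prior` with elements `cov`, `prec`
#'   (the precision actually used in the posterior) and `n`.
#' @export
#' @examples
#' g_prior(matrix(1, nrow = 7))$cov   # 1x1 matrix: 7 * (7)^-1 = 1
g_prior <- function(X, weights = NULL, n = NULL) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (is.null(n)) n <- sum(weights)
  xtx <- crossprod(X * sqrt(weights))
  r <- qr(xtx)$rank
  if (r < ncol(xtx)) {
    warning("singular cross-product in g-prior; using generalized inverse")
    cov <- n * MASS::ginv(xtx)
    prec <- MASS::ginv(cov)
  } else {
    cov <- n * solve(xtx)
    prec <- xtx / n
  }
  cov <- (cov + t(cov)) / 2
  structure(list(cov = cov, prec = (prec + t(prec)) / 2, n = n),
            class = "g_prior")
}

#' Unnormalized log-posterior of one coefficient block
#'
#' Block log-likelihood plus the zero-mean Gaussian g-prior log-density
#' (without its normalizing constant).
#'
#' @param betak coefficient vector.
#' @param loglik function of `betak` returning the block log-likelihood.
#' @param prior a [g_prior()] object.
#' @return The unnormalized log-posterior value.
#' @export
log_posterior_block <- function(betak, loglik, prior) {
  ll <- loglik(betak)
  if (!is.finite(ll)) return(-Inf)
  ll - 0.5 * drop(crossprod(betak, prior$prec %*% betak))
}

#' Numeric negative Hessian
#'
#' Central finite differences with per-coordinate step
#' `step * max(1, |x_j|)`.
#'
#' @param f scalar function of a numeric vector.
#' @param x evaluation point.
#' @param step relative step size.
#' @return The matrix `-d^2 f / dx dx'`, symmetrized.
#' @export
neg_hessian <- function(f, x, step = 1e-5) {
  d <- length(x)
  hh <- step * pmax(1, abs(x))
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- hh[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh[i]^2
    if (i < d) for (j in (i + 1):d) {
      ej <- numeric(d); ej[j] <- hh[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hh[i] * hh[j])
    }
  }
  -(H + t(H)) / 2
}

## Cholesky of the inverse of H with escalating ridge if H is not positive
## definite; returns lower-triangular L with L L' = scale * H^-1 and the
## log-determinant of the proposal covariance
chol_inv_safe <- function(H, scale = 1) {
  d <- nrow(H)
  ridge <- 0
  repeat {
    ch <- tryCatch(chol(H + ridge * diag(d)), error = function(e) NULL)
    if (!is.null(ch)) break
    ridge <- if (ridge == 0) 1e-8 else ridge * 100
    if (ridge > 1e6) stop("Hessian could not be regularized")
  }
  ## H^-1 = R^-1 R^-T with R = ch (upper); chol of scale*H^-1
  Rinv <- backsolve(ch, diag(d))
  S <- scale * tcrossprod(Rinv)
  L <- t(chol((S + t(S)) / 2))
  list(L = L, logdet = 2 * sum(base::log(diag(L))))
}

## log N(x; m, Sigma) with Sigma = L L'
ldmvn <- function(x, m, L, logdet) {
  r <- forwardsolve(L, x - m)
  -0.5 * sum(r * r) - 0.5 * logdet - 0.5 * length(x) * base::log(2 * pi)
}

#' MCMC configuration
#'
#' @param n_iter total chain length `N`.
#' @param burnin number of initial iterations discarded; defaults to 20%
#'   of `n_iter`.
#' @param thin keep one draw out of every `thin`; default 10.
#' @param seed integer seed applied before sampling (optional).
#' @param init initial state: `"zero"` (default), `"map"` (start at the
#'   posterior mode), or a numeric vector.
#' @param proposal `"shrunken"` (default; candidate mean is
#'   `nu * beta^(t-1)` with `nu = n/(n+1)`, an asymmetric proposal whose
#'   forward and reverse densities enter the acceptance ratio) or
#'   `"centered"` (textbook random-walk, candidate mean `beta^(t-1)`).
#' @param hessian_refresh `"iteration"` (default; the proposal covariance
#'   `nu * H^-1` is re-evaluated at the shrunken current state every
#'   iteration) or `"cached"` (evaluated once at the posterior mode).
#' @param nu shrinkage factor; defaults to `n/(n+1)` at fit time.
#' @return A list of class `mh_config`.
#' @export
mh_config <- function(n_iter = 50000, burnin = NULL, thin = 10, seed = NULL,
                      init = c("zero", "map"),
                      proposal = c("shrunken", "centered"),
                      hessian_refresh = c("iteration", "cached"),
                      nu = NULL) {
  if (is.null(burnin)) burnin <- floor(0.2 * n_iter)
  stopifnot(n_iter > burnin, thin >= 1)
  if (!is.numeric(init)) init <- match.arg(init)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = seed, init = init,
                 proposal = match.arg(proposal),
                 hessian_refresh = match.arg(hessian_refresh), nu = nu),
            class = "mh_config")
}

#' Metropolis-Hastings sampling of one block
#'
#' Samples a single coefficient block from an unnormalized log-target
#' using multivariate normal proposals `N(nu * beta, nu * H^-1)` (or the
#' centered variant).  Because the shrunken proposal mean and the
#' state-dependent covariance make the kernel asymmetric, the acceptance
#' ratio includes the forward and reverse proposal densities except in the
#' one genuinely symmetric case (centered mean with cached covariance).
#'
#' @param log_target function returning the unnormalized log-posterior.
#' @param init numeric starting state.
#' @param config an [mh_config()]; `config$nu` must be set.
#' @return A list with `draws` (matrix of retained draws after burn-in and
#'   thinning), `accept` (acceptance rate), `map` (the located mode) and
#'   `config`.
#' @export
mh_sample <- function(log_target, init, config) {
  nu <- config$nu
  stopifnot(is.numeric(nu), nu > 0, nu < 1)
  d <- length(init)
  safe <- function(x) {
    v <- log_target(x)
    if (is.finite(v)) v else -1e10
  }
  opt <- stats::optim(init, safe, method = "BFGS",
                      control = list(fnscale = -1, maxit = 200))
  map <- opt$par
  refresh <- config$hessian_refresh == "iteration"
  shrunk <- config$proposal == "shrunken"
  correct <- shrunk || refresh
  prop_at <- function(x) chol_inv_safe(neg_hessian(log_target, x), nu)
  P_cached <- prop_at(map)
  b <- if (is.numeric(config$init)) config$init
       else if (identical(config$init, "map")) map else numeric(d)
  lpb <- log_target(b)
  if (!is.finite(lpb))
    stop("log-posterior not finite at the initial state")
  P_cur <- if (refresh) prop_at(nu * b) else P_cached
  n_keep <- (config$n_iter - config$burnin) %/% config$thin
  draws <- matrix(NA_real_, n_keep, d)
  acc <- 0L; kept <- 0L
  for (t in seq_len(config$n_iter)) {
    m_f <- if (shrunk) nu * b else b
    psi <- drop(m_f + P_cur$L %*% stats::rnorm(d))
    lppsi <- log_target(psi)
    if (is.finite(lppsi)) {
      la <- lppsi - lpb
      if (correct) {
        P_rev <- if (refresh) prop_at(nu * psi) else P_cached
        m_r <- if (shrunk) nu * psi else psi
        la <- la + ldmvn(b, m_r, P_rev$L, P_rev$logdet) -
          ldmvn(psi, m_f, P_cur$L, P_cur$logdet)
      }
      if (base::log(stats::runif(1)) < la) {
        b <- psi; lpb <- lppsi; acc <- acc + 1L
        if (refresh) P_cur <- P_rev
      } else if (!refresh) {
        ## covariance cached: nothing to restore
      }
    }
    if (t > config$burnin && (t - config$burnin) %% config$thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- b
    }
  }
  list(draws = draws, accept = acc / config$n_iter, map = map,
       config = config)
}

#' Posterior mean of retained draws
#'
#' @param draws a matrix of draws (or a `zmps_fit` object).
#' @return Named vector of column means, the minimum-mean-square-error
#'   Bayes point estimate.
#' @export
posterior_mean <- function(draws) {
  if (inherits(draws, "zmps_fit")) draws <- draws$draws
  colMeans(as.matrix(draws))
}

#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(level * M)` of the sorted draws.
#'
#' @param x numeric vector of draws, or a matrix (one interval per column).
#' @param level interval mass, in (0, 1).
#' @return For a vector, `c(lower, upper)`; for a matrix, a two-column
#'   matrix with one row per column of `x`.
#' @export
hpdi <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (is.matrix(x))
    return(t(apply(x, 2, hpdi, level = level)))
  xs <- sort(x)
  M <- length(xs)
  stopifnot(M >= 2)
  k <- ceiling(level * M)   # points inside the interval
  if (k >= M) return(c(lower = xs[1], upper = xs[M]))
  width <- xs[k:M] - xs[1:(M - k + 1)]
  i <- which.min(width)
  c(lower = xs[i], upper = xs[i + k - 1])
}

## ---------------------------------------------------------------------------
## Convergence diagnostics
## ---------------------------------------------------------------------------

## effective sample size via Geyer's initial monotone positive sequence
ess_chain <- function(x) {
  M <- length(x)
  if (M < 100) return(NA_real_)
  v <- stats::var(x)
  if (v == 0) return(M)
  ac <- stats::acf(x, lag.max = min(M - 1, 2000), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  npair <- (length(ac)) %/% 2
  G <- ac[2 * seq_len(npair) - 1] + ac[2 * seq_len(npair)]
  ## G[1] = rho0 + rho1; keep while positive, then enforce monotonicity
  pos <- which(G <= 0)
  if (length(pos)) G <- G[seq_len(pos[1] - 1)]
  if (length(G) > 1) G <- cummin(G)
  tau <- max(-1 + 2 * sum(G), 1e-8)
  min(M, M / tau)
}

## Geweke z-score: first frac1 vs last frac2 of the chain, standard errors
## from the per-window effective sample sizes
geweke_chain <- function(x, frac1 = 0.1, frac2 = 0.5) {
  M <- length(x)
  if (M < 100) return(NA_real_)
  a <- x[seq_len(floor(frac1 * M))]
  b <- x[(M - floor(frac2 * M) + 1):M]
  se2 <- function(w) stats::var(w) / max(ess_chain_safe(w), 1)
  (mean(a) - mean(b)) / sqrt(se2(a) + se2(b))
}

ess_chain_safe <- function(x) {
  e <- ess_chain(x)
  if (is.na(e)) length(x) else e
}

## split-chain potential scale reduction factor
rhat_chain <- function(x) {
  if (is.vector(x)) {
    M <- length(x) %/% 2
    x <- cbind(x[seq_len(M)], x[(M + 1):(2 * M)])
  }
  M <- nrow(x); K <- ncol(x)
  if (M < 50) return(NA_real_)
  means <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  if (W == 0) return(1)
  B <- M * stats::var(means)
  sqrt(((M - 1) / M * W + B / M) / W)
}

#' Convergence diagnostics for posterior draws
#'
#' Geweke z-scores (first 10% vs last 50% of the chain), split-chain
#' potential scale reduction factors, and effective sample sizes computed
#' with the initial-monotone-positive-sequence autocorrelation estimator.
#' Chains shorter than 100 retained draws return `NA` (diagnostic
#' unavailable).
#'
#' @param draws matrix of retained draws (or a `zmps_fit` object).
#' @return A data frame with one row per parameter and columns
#'   `geweke_z`, `rhat`, `ess`.
#' @export
mcmc_diagnostics <- function(draws) {
  if (inherits(draws, "zmps_fit")) draws <- draws$draws
  draws <- as.matrix(draws)
  data.frame(
    parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    geweke_z = apply(draws, 2, geweke_chain),
    rhat = apply(draws, 2, rhat_chain),
    ess = apply(draws, 2, ess_chain),
    row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
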