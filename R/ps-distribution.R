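#' zmpsreg: hurdle Poisson-Sujatha regression for zero-modified counts
#'
#' Probability functions, Bayesian g-prior inference, model assessment and
#' simulation tools for the zero-modified (hurdle) Poisson-Sujatha
#' regression model.  See [zmps_fit()] for the main model-fitting entry
#' point, [fit_aberration()] for the bundled cytogenetic dosimetry
#' application, and the package vignette for the underlying model.
#'
#' @keywords internal
"_PACKAGE"

## ---------------------------------------------------------------------------
## Poisson-Sujatha (PS) distribution under the mean parameterization.
##
## The PS distribution is the Poisson mixture whose mixing density is the
## Sujatha distribution theta^3/(theta^2+theta+2) * (1+x+x^2) * exp(-theta*x).
## Its mean is mu(theta) = (theta^2+2*theta+6) / (theta*(theta^2+theta+2)),
## a strictly decreasing bijection from theta>0 onto mu>0, so the model can
## be parameterized by the mean, with shape theta = h(mu) recovered as the
## unique positive root of the cubic
##     mu*t^3 + (mu-1)*t^2 + 2*(mu-1)*t - 6 = 0.
## ---------------------------------------------------------------------------

#' Mean of the Poisson-Sujatha distribution for a given shape
#'
#' @param theta positive shape parameter(s) of the Poisson-Sujatha
#'   distribution.
#' @return The distribution mean, `(theta^2 + 2*theta + 6) /
#'   (theta * (theta^2 + theta + 2))`, strictly decreasing in `theta`.
#' @seealso [ps_shape()] for the inverse map.
#' @export
#' @examples
#' ps_mean(1)    # 9/4
#' ps_mean(2)    # 14/16
ps_mean <- function(theta) {
  stopifnot(is.numeric(theta))
  if (any(!is.finite(theta) | theta <= 0))
    stop("'theta' must be positive and finite")
  (theta^2 + 2 * theta + 6) / (theta * (theta^2 + theta + 2))
}

#' Shape of the Poisson-Sujatha distribution for a given mean
#'
#' Inverts the mean map of [ps_mean()].  The default method solves the
#' cubic `mu*t^3 + (mu-1)*t^2 + 2*(mu-1)*t - 6 = 0` in closed form
#' (Cardano for the single-real-root branch, the trigonometric form for the
#' three-real-root branch) and polishes the root with a few Newton steps;
#' the radical printed in the literature is algebraically the same root but
#' is prone to cancellation when transcribed.  `method = "bisect"` is a
#' safeguarded `uniroot()` inversion of [ps_mean()], kept as the slow
#' reference.
#'
#' @param mu positive mean(s).
#' @param method `"analytic"` (default, vectorized) or `"bisect"`.
#' @return The shape `theta = h(mu)` with `ps_mean(h(mu)) == mu`.
#' @export
#' @examples
#' ps_shape(2.25)            # 1
#' ps_mean(ps_shape(0.131))  # round trip
ps_shape <- function(mu, method = c("analytic", "bisect")) {
  method <- match.arg(method)
  stopifnot(is.numeric(mu))
  if (any(!is.finite(mu) | mu <= 0))
    stop("'mu' must be positive and finite")
  if (method == "bisect") {
    return(vapply(mu, function(m) {
      f <- function(t) ps_mean(t) - m
      stats::uniroot(f, lower = 1e-10, upper = 1e10, tol = 1e-14)$root
    }, numeric(1)))
  }
  ## monic depressed cubic: t = z - a/3, z^3 + p z + q = 0
  a <- (mu - 1) / mu
  b <- 2 * (mu - 1) / mu
  cc <- -6 / mu
  p <- b - a^2 / 3
  q <- 2 * a^3 / 27 - a * b / 3 + cc
  disc <- (q / 2)^2 + (p / 3)^3
  t0 <- numeric(length(mu))
  one <- disc >= 0
  if (any(one)) {
    u <- -q[one] / 2 + sqrt(disc[one])
    v <- -q[one] / 2 - sqrt(disc[one])
    t0[one] <- sign(u) * abs(u)^(1 / 3) + sign(v) * abs(v)^(1 / 3) - a[one] / 3
  }
  if (any(!one)) {
    ## three real roots; exactly one is positive (one sign change in the
    ## cubic's coefficients), so scan the trigonometric roots for it
    pp <- p[!one]; qq <- q[!one]; aa <- a[!one]
    r <- 2 * sqrt(-pp / 3)
    phi <- acos(pmin(pmax(3 * qq / (pp * r), -1), 1))
    best <- rep(NA_real_, sum(!one))
    for (k in 0:2) {
      cand <- r * cos(phi / 3 - 2 * pi * k / 3) - aa / 3
      take <- is.na(best) & is.finite(cand) & cand > 0
      best[take] <- cand[take]
    }
    t0[!one] <- best
  }
  for (i in 1:3) {
    f <- mu * t0^3 + (mu - 1) * t0^2 + 2 * (mu - 1) * t0 - 6
    fp <- 3 * mu * t0^2 + 2 * (mu - 1) * t0 + 2 * (mu - 1)
    t0 <- t0 - f / fp
  }
  t0
}

#' Poisson-Sujatha probability mass function (mean parameterization)
#'
#' @param x vector of non-negative integer quantiles.
#' @param mu positive mean(s), recycled against `x`.
#' @param log logical; return log-probabilities?
#' @return `P(Y = x; mu)` for the Poisson-Sujatha distribution.
#' @export
#' @examples
#' dps(0:5, mu = 1)
#' sum(dps(0:200, mu = 2))  # 1
dps <- function(x, mu, log = FALSE) {
  check_counts(x)
  n <- max(length(x), length(mu))
  x <- rep_len(x, n); mu <- rep_len(mu, n)
  h <- ps_shape(mu)
  lp <- 3 * base::log(h) - base::log(h^2 + h + 2) +
    base::log(x^2 + x * (h + 4) + h^2 + 3 * h + 4) -
    (x + 3) * log1p(h)
  if (log) lp else exp(lp)
}

#' Variance of the Poisson-Sujatha distribution
#'
#' Computed from the Poisson-mixture moments of the Sujatha mixing density:
#' with `theta = h(mu)`, `E[X^2] = 2*(theta^2+3*theta+12) /
#' (theta^2*(theta^2+theta+2))` and `Var(Y) = mu + E[X^2] - mu^2`.  The
#' variance always exceeds the mean (the mixture is overdispersed for every
#' `mu`).
#'
#' @param mu positive mean(s).
#' @return The variance `sigma^2(mu)`.
#' @export
ps_var <- function(mu) {
  th <- ps_shape(mu)
  ex2 <- 2 * (th^2 + 3 * th + 12) / (th^2 * (th^2 + th + 2))
  mu + ex2 - mu^2
}

## log P(Y > 0; mu) through the cancellation-free polynomial identity
## (h^2+h+2)*(h+1)^3 - h^3*(h^2+3h+4) = h^4 + 4h^3 + 10h^2 + 7h + 2
log_ps_ppos <- function(mu, h = ps_shape(mu)) {
  base::log(h^4 + 4 * h^3 + 10 * h^2 + 7 * h + 2) -
    base::log(h^2 + h + 2) - 3 * log1p(h)
}

#' Zero probability of the Poisson-Sujatha distribution
#'
#' @param mu positive mean(s).
#' @return `P(Y = 0; mu)`.
#' @export
ps_p0 <- function(mu) dps(0, mu)

#' Zero-truncated Poisson-Sujatha probability mass function
#'
#' @param x vector of positive integer quantiles (the support is `y >= 1`).
#' @param mu positive mean(s) of the untruncated distribution.
#' @param log logical; return log-probabilities?
#' @return `P(Y = x | Y > 0; mu)`.
#' @export
dztps <- function(x, mu, log = FALSE) {
  check_counts(x)
  if (any(x < 1)) stop("zero-truncated support is y >= 1")
  n <- max(length(x), length(mu))
  x <- rep_len(x, n); mu <- rep_len(mu, n)
  h <- ps_shape(mu)
  lp <- 3 * base::log(h) - base::log(h^2 + h + 2) +
    base::log(x^2 + x * (h + 4) + h^2 + 3 * h + 4) -
    (x + 3) * log1p(h) - log_ps_ppos(mu, h)
  if (log) lp else exp(lp)
}

#' Hurdle (zero-modified) Poisson-Sujatha probability mass function
#'
#' The hurdle parameterization places probability `1 - omega` on zero and
#' distributes `omega` over the positive integers according to the
#' zero-truncated Poisson-Sujatha distribution with mean parameter `mu`.
#'
#' @param x vector of non-negative integer quantiles.
#' @param mu positive mean(s) of the baseline distribution.
#' @param omega probability of a positive outcome, in `[0, 1]`.
#' @param log logical; return log-probabilities?
#' @return `P(Y = x; mu, omega)`.
#' @export
#' @examples
#' dzmps(0:4, mu = 1, omega = 0.5)
dzmps <- function(x, mu, omega, log = FALSE) {
  check_counts(x)
  check_omega(omega)
  n <- max(length(x), length(mu), length(omega))
  x <- rep_len(x, n); mu <- rep_len(mu, n); omega <- rep_len(omega, n)
  lp <- numeric(n)
  z <- x == 0
  lp[z] <- base::log(1 - omega[z])
  if (any(!z))
    lp[!z] <- base::log(omega[!z]) + dztps(x[!z], mu[!z], log = TRUE)
  if (log) lp else exp(lp)
}

#' Hurdle Poisson-Sujatha cumulative distribution function
#'
#' Closed form via the Poisson-Sujatha survival function: with
#' `h = h(mu)` and `m = y + 1`,
#' `S(y) = [h^2*(m^2 + (h+4)*m + h^2+3h+4) + h*(2m+h+5) + 2] /
#' ((h^2+h+2)*(1+h)^(m+2))`, and
#' `F(y) = 1 - omega * S(y) / P(Y > 0; mu)`.  Negative `y` return 0 (the
#' convention required by randomized quantile residuals).
#'
#' @param q vector of integer quantiles (values below 0 allowed).
#' @param mu positive mean(s).
#' @param omega probability of a positive outcome, in `[0, 1]`.
#' @return `P(Y <= q; mu, omega)`.
#' @export
pzmps <- function(q, mu, omega) {
  check_omega(omega)
  n <- max(length(q), length(mu), length(omega))
  q <- rep_len(q, n); mu <- rep_len(mu, n); omega <- rep_len(omega, n)
  if (any(q != floor(q))) stop("'q' must be integer-valued")
  out <- numeric(n)
  neg <- q < 0
  if (any(!neg))
    out[!neg] <- 1 - omega[!neg] *
      ps_surv(q[!neg], mu[!neg]) / exp(log_ps_ppos(mu[!neg]))
  out
}

## P(Y > q; mu) for the untruncated PS distribution, q >= -1, from the
## closed-form geometric-polynomial tail sum (m = q + 1):
## S(q) = [h^2 (m^2+(h+4)m+h^2+3h+4) + h(2m+h+5) + 2] /
##        ((h^2+h+2)(1+h)^(m+2))
ps_surv <- function(q, mu) {
  stopifnot(all(q >= -1))
  h <- ps_shape(mu)
  m <- q + 1
  exp(base::log(h^2 * (m^2 + (h + 4) * m + h^2 + 3 * h + 4) +
                  h * (2 * m + h + 5) + 2) -
        base::log(h^2 + h + 2) - (m + 2) * log1p(h))
}

#' Convert between the hurdle and zero-modification parameterizations
#'
#' The zero-modification parameter `p` of the zero-modified
#' Poisson-Sujatha distribution relates to the hurdle probability `omega`
#' of a positive outcome through `omega = p * P(Y > 0; mu)`.  Values
#' `p < 1` correspond to zero inflation, `p > 1` to zero deflation and
#' `p = 1` to the unmodified baseline; the admissible range is
#' `[0, 1 / P(Y > 0; mu)]`.
#'
#' @param mu positive mean(s) of the baseline distribution.
#' @param omega probability of a positive outcome, in `[0, 1]`.
#' @param p zero-modification parameter.
#' @return `p_from_omega()` returns `p`; `omega_from_p()` returns `omega`.
#' @export
#' @examples
#' p_from_omega(1, plogis(1))          # > 1: zero deflation
#' omega_from_p(1, 1)                  # the unmodified PS zero mass
p_from_omega <- function(mu, omega) {
  check_omega(omega)
  omega / exp(log_ps_ppos(mu))
}

#' @rdname p_from_omega
#' @export
omega_from_p <- function(mu, p) {
  ppos <- exp(log_ps_ppos(mu))
  if (any(p < 0 | p > 1 / ppos + 1e-12))
    stop("'p' must lie in [0, 1/P(Y>0; mu)]")
  pmin(p * ppos, 1)
}

#' Sample from the hurdle Poisson-Sujatha distribution
#'
#' Sequential-search inversion of the cumulative probability vector: a
#' uniform deviate is compared against the running cumulative pmf until it
#' is exceeded.  The cumulative vector is computed once per unique
#' `(mu, omega)` pair and truncated where the remaining tail mass falls
#' below `1e-12`, so repeated draws at the same parameter values share the
#' search table.
#'
#' @param n number of draws.
#' @param mu positive mean(s), recycled to length `n`.
#' @param omega probability of a positive outcome, recycled to length `n`.
#' @return Integer vector of `n` draws.  The attribute `"iterations"`
#'   holds the total number of while-loop comparisons performed by the
#'   sequential search (one more than each generated value), the quantity
#'   whose expectation is [zmps_expected_iterations()].
#' @export
#' @examples
#' set.seed(1)
#' table(rzmps(1000, mu = 1, omega = 0.5))
rzmps <- function(n, mu, omega) {
  stopifnot(n >= 1)
  check_omega(omega)
  mu <- rep_len(mu, n); omega <- rep_len(omega, n)
  key <- paste(mu, omega)
  uk <- unique(key)
  y <- integer(n)
  if (length(uk) <= 50) {
    for (k in uk) {
      idx <- which(key == k)
      cdf <- zmps_cdf_table(mu[idx[1]], omega[idx[1]])
      u <- stats::runif(length(idx))
      ## findInterval on the cumulative vector is the sequential search's
      ## stopping index: y = #{cdf values strictly below u}
      y[idx] <- findInterval(u, cdf, left.open = TRUE)
    }
  } else {
    ## heterogeneous parameters: build the per-subject cumulative rows
    ## jointly, one outcome value at a time, until every row's tail mass
    ## is below 1e-12
    u <- stats::runif(n)
    cum <- 1 - omega            # F(0)
    yy <- integer(n)
    v <- 0L
    while (any(open <- u > cum) && v < 100000L) {
      v <- v + 1L
      cum[open] <- cum[open] +
        omega[open] * dztps(rep(v, sum(open)), mu[open])
      yy[open] <- v             # final for rows that just closed at v
    }
    y <- yy
  }
  structure(y, iterations = sum(y) + n)
}

## cumulative pmf of the hurdle distribution up to tail mass < 1e-12;
## geometric decay (1+h)^-y bounds the remainder
zmps_cdf_table <- function(mu, omega) {
  pmax <- 1 - 1e-12
  c0 <- 1 - omega
  if (omega == 0) return(1)
  cdf <- c0
  y <- 0
  repeat {
    y <- y + 1
    cdf <- c(cdf, cdf[length(cdf)] + dzmps(y, mu, omega))
    if (cdf[length(cdf)] >= pmax || y > 100000) break
  }
  cdf
}

#' Expected number of sequential-search comparisons
#'
#' For the sequential-search sampler the number of while-loop comparisons
#' needed to generate a value `y` is `y + 1`, so its expectation is
#' `lambda + 1` where `lambda = omega * mu / P(Y > 0; mu)` is the hurdle
#' distribution's mean.  Evaluated through the shape polynomial
#' `lambda = omega * mu * (h^2+h+2) * (h+1)^3 / (h^4+4h^3+10h^2+7h+2)`.
#'
#' @param mu positive mean(s) of the baseline distribution.
#' @param omega probability of a positive outcome.
#' @return `E[NI] = lambda + 1`.
#' @export
zmps_expected_iterations <- function(mu, omega) {
  check_omega(omega)
  h <- ps_shape(mu)
  omega * mu * (h^2 + h + 2) * (h + 1)^3 /
    (h^4 + 4 * h^3 + 10 * h^2 + 7 * h + 2) + 1
}

#' Moments of the hurdle Poisson-Sujatha distribution
#'
#' Mean `lambda = mu * p` and variance
#' `sigma^2 = p * (ps_var(mu) + (1 - p) * mu^2)` of the zero-modified
#' distribution, with `p = p_from_omega(mu, omega)`.
#'
#' @inheritParams dzmps
#' @return A list with components `mean` and `var`.
#' @export
zmps_moments <- function(mu, omega) {
  p <- p_from_omega(mu, omega)
  list(mean = mu * p, var = p * (ps_var(mu) + (1 - p) * mu^2))
}

check_counts <- function(x) {
  if (any(!is.finite(x) | x < 0 | x != floor(x)))
    stop("counts must be non-negative integers")
  invisible(x)
}

check_omega <- function(omega) {
  if (any(!is.finite(omega) | omega < 0 | omega > 1))
    stop("'omega' must lie in [0, 1]")
  invisible(omega)
}
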