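## Regression structure: design matrices, linear predictors, and the
## orthogonal decomposition of the hurdle log-likelihood into a
## positive-count block (beta1) and a binary block (beta2).

## linear predictors beyond this magnitude give mu outside [1e-13, 1e13];
## the likelihood returns -Inf there instead of overflowing, which simply
## rejects such proposals
ETA_BOUND <- 30

#' Construct a zero-modified regression dataset
#'
#' Bundles the response, the two design matrices and the binary-component
#' link.  Grouped frequency data are represented through `weights`
#' (number of subjects sharing a row); the log-likelihood of a weighted
#' dataset equals that of the expanded long format by construction.
#'
#' @param y vector of non-negative integer responses.
#' @param X1 design matrix of the mean component (include the intercept
#'   column).  A vector is treated as a single covariate and an intercept
#'   is prepended.
#' @param X2 design matrix of the binary component; defaults to `X1`.
#' @param weights positive case weights (frequency counts); default 1.
#' @param omega_link link for the binary component: `"logit"`,
#'   `"probit"` or `"cloglog"`.
#' @return An object of class `zmps_data`.
#' @export
#' @examples
#' d <- zmps_data(y = c(0, 0, 1, 3), X1 = c(0.1, 0.4, 0.6, 0.9))
zmps_data <- function(y, X1, X2 = X1, weights = NULL,
                      omega_link = c("logit", "probit", "cloglog")) {
  check_counts(y)
  omega_link <- if (inherits(omega_link, "zmps_link")) omega_link
                else zmps_link(match.arg(omega_link))
  as_design <- function(X) {
    if (is.null(dim(X))) X <- cbind(`(Intercept)` = 1, x = X)
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    X
  }
  X1 <- as_design(X1); X2 <- as_design(X2)
  n <- length(y)
  stopifnot(nrow(X1) == n, nrow(X2) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  rank_ok <- c(qr(X1)$rank == ncol(X1), qr(X2)$rank == ncol(X2))
  if (!all(rank_ok))
    warning("rank-deficient design matrix; ",
            "the g-prior will use a generalized inverse")
  structure(list(y = as.integer(y), X1 = X1, X2 = X2,
                 w = as.numeric(weights), omega_link = omega_link,
                 pos = y > 0, full_rank = rank_ok),
            class = "zmps_data")
}

#' @export
print.zmps_data <- function(x, ...) {
  cat("<zmps_data> n =", sum(x$w), "subjects in", length(x$y), "rows;",
      sum(x$w[!x$pos]), "zeros;",
      "q1+1 =", ncol(x$X1), ", q2+1 =", ncol(x$X2),
      ", omega link:", x$omega_link$name, "\n")
  invisible(x)
}

#' Collapse a dataset to its sufficient-statistic cells
#'
#' Rows with identical covariates and response are merged, summing their
#' weights.  The log-likelihood (and hence the whole posterior) is
#' unchanged, but MCMC on data with few distinct covariate patterns -- such
#' as dose-response designs -- becomes much cheaper.
#'
#' @param data a [zmps_data()] object.
#' @return A `zmps_data` object with one row per unique
#'   (covariates, response) cell.
#' @export
aggregate_zmps_data <- function(data) {
  key <- apply(cbind(data$y, data$X1, data$X2), 1, paste, collapse = "\r")
  idx <- !duplicated(key)
  w <- as.numeric(tapply(data$w, factor(key, levels = key[idx]), sum))
  zmps_data(data$y[idx], data$X1[idx, , drop = FALSE],
            data$X2[idx, , drop = FALSE], weights = w,
            omega_link = data$omega_link)
}

## expand weighted rows to one row per subject (for per-subject residuals)
expand_index <- function(data) rep(seq_along(data$y), times = data$w)

#' Log-likelihood of the positive-count block
#'
#' The hurdle log-likelihood separates into two orthogonal blocks; this is
#' the block depending only on `beta1`, the sum over positive outcomes of
#' the zero-truncated baseline log-pmf at `mu = exp(x1' beta1)`.
#'
#' @param beta1 coefficient vector of the mean component.
#' @param data a [zmps_data()] object.
#' @param family a [count_family()] (or its name); must be a hurdle family.
#' @return The block log-likelihood (0 for data without positive counts;
#'   `-Inf` where the linear predictor would overflow the mean scale).
#' @export
loglik_positive <- function(beta1, data, family = "zmps") {
  family <- as_family(family)
  pos <- data$pos
  if (!any(pos)) return(0)
  eta <- drop(data$X1[pos, , drop = FALSE] %*% beta1)
  if (any(!is.finite(eta)) || any(abs(eta) > ETA_BOUND)) return(-Inf)
  mu <- exp(eta)
  y <- data$y[pos]
  if (family$name == "zmps") {
    ## truncated log-pmf with the (h+1)^3 and (h^2+h+2) factors cancelled,
    ## one shape solve instead of two
    h <- ps_shape(mu)
    lt <- 3 * base::log(h) +
      base::log(y^2 + y * (h + 4) + h^2 + 3 * h + 4) -
      y * log1p(h) -
      base::log(h^4 + 4 * h^3 + 10 * h^2 + 7 * h + 2)
    return(sum(data$w[pos] * lt))
  }
  sum(data$w[pos] * (family$log_dens(y, mu) - family$log_ppos(mu)))
}

#' Log-likelihood of the binary (zero) block
#'
#' The block depending only on `beta2`: a Bernoulli log-likelihood for the
#' indicator of a positive outcome under the dataset's binary link,
#' evaluated in log space.
#'
#' @param beta2 coefficient vector of the binary component.
#' @param data a [zmps_data()] object.
#' @return The block log-likelihood.
#' @export
loglik_zero <- function(beta2, data) {
  eta <- drop(data$X2 %*% beta2)
  if (any(!is.finite(eta))) return(-Inf)
  lk <- data$omega_link$name
  if (lk == "logit") {
    lw <- stats::plogis(eta, log.p = TRUE)
    l1w <- stats::plogis(-eta, log.p = TRUE)
  } else if (lk == "probit") {
    lw <- stats::pnorm(eta, log.p = TRUE)
    l1w <- stats::pnorm(eta, lower.tail = FALSE, log.p = TRUE)
  } else {
    ee <- exp(pmin(eta, ETA_BOUND))
    l1w <- -ee
    lw <- base::log(-expm1(-pmax(ee, 1e-300)))
  }
  sum(data$w * ifelse(data$pos, lw, l1w))
}

#' Total log-likelihood of a zero-modified regression model
#'
#' For hurdle families this is `loglik_positive(beta1) +
#' loglik_zero(beta2)`, identical to summing the full zero-modified
#' log-pmf over all observations.  For plain families (`"ps"`,
#' `"poisson"`) it is the ordinary log-likelihood of the single mean
#' component and `beta$beta2` is ignored.
#'
#' @param beta a list with components `beta1` and (for hurdle families)
#'   `beta2`.
#' @param data a [zmps_data()] object.
#' @param family a [count_family()] or its name.
#' @return The log-likelihood value.
#' @export
loglik_zmps <- function(beta, data, family = "zmps") {
  family <- as_family(family)
  if (!family$hurdle) {
    eta <- drop(data$X1 %*% beta$beta1)
    if (any(!is.finite(eta)) || any(abs(eta) > ETA_BOUND)) return(-Inf)
    return(sum(data$w * family$log_dens(data$y, exp(eta))))
  }
  loglik_positive(beta$beta1, data, family) + loglik_zero(beta$beta2, data)
}

#' Fitted per-subject quantities of a hurdle fit
#'
#' Applies the links elementwise and derives the zero-modification
#' parameter `p = omega / P(Y > 0; mu)`, the marginal mean
#' `lambda = mu * p`, the marginal variance
#' `varsigma^2 = p * (sigma^2(mu) + (1 - p) * mu^2)` and the zero
#' probability `1 - omega`.
#'
#' @param beta a list with components `beta1`, `beta2`.
#' @param data a [zmps_data()] object.
#' @param family a hurdle [count_family()] or its name.
#' @return A data frame with columns `mu`, `omega`, `p`, `lambda`,
#'   `var` and `p0`, one row per data row.
#' @export
zmps_fitted <- function(beta, data, family = "zmps") {
  family <- as_family(family)
  mu <- exp(drop(data$X1 %*% beta$beta1))
  if (!family$hurdle) {
    return(data.frame(mu = mu, omega = NA_real_, p = NA_real_, lambda = mu,
                      var = family$var(mu), p0 = exp(family$log_dens(0, mu))))
  }
  omega <- data$omega_link$linkinv(drop(data$X2 %*% beta$beta2))
  p <- omega / exp(family$log_ppos(mu))
  sig2 <- family$var(mu)
  data.frame(mu = mu, omega = omega, p = p, lambda = mu * p,
             var = p * (sig2 + (1 - p) * mu^2), p0 = 1 - omega)
}
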