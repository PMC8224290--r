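## The embedded chromosomal aberration dataset: counts of dicentric and
## centric ring aberrations per cell in blood samples irradiated with 2.1
## MeV neutrons at five doses (72 h culture time).  The response is the
## number of aberrations per examined cell; the covariate is the absorbed
## dose in Gy.

aberration_freq <- function() {
  structure(
    rbind(c(2130, 59, 9, 2, 0, 0),
          c(1088, 84, 19, 6, 3, 0),
          c(875, 88, 30, 7, 0, 0),
          c(679, 88, 23, 8, 1, 1),
          c(480, 75, 27, 13, 5, 0)),
    dimnames = list(dose = c("0.1", "0.3", "0.5", "0.7", "1"),
                    y = 0:5))
}

#' Chromosomal aberration counts (cytogenetic dosimetry)
#'
#' Frequency table of the number of dicentric plus centric ring
#' aberrations per examined cell after in-vitro irradiation of blood
#' samples at doses 0.1-1.0 Gy (2200, 1200, 1000, 800 and 600 cells per
#' dose; 5800 cells in total, 5252 of them without aberrations).
#'
#' @param format `"grouped"` (default): one row per (dose, count) cell
#'   with its frequency; `"long"`: one row per examined cell (5800 rows).
#' @return A data frame with columns `dose`, `y` and (grouped format)
#'   `count`.
#' @export
#' @examples
#' sum(aberration_counts()$count)         # 5800
#' head(aberration_counts("long"))
aberration_counts <- function(format = c("grouped", "long")) {
  format <- match.arg(format)
  f <- aberration_freq()
  g <- expand.grid(y = 0:5, dose = as.numeric(rownames(f)))
  g$count <- as.vector(t(f))
  g <- g[g$count > 0, c("dose", "y", "count")]
  rownames(g) <- NULL
  if (format == "grouped") return(g)
  data.frame(dose = rep(g$dose, g$count), y = rep(g$y, g$count))
}

#' Descriptive summary of the aberration data
#'
#' Per-dose and pooled sample size, mean, standard deviation and
#' dispersion index (sample variance over mean) of the aberration counts.
#'
#' @return A data frame with one row per dose plus a pooled row.
#' @export
aberration_summary <- function() {
  g <- aberration_counts()
  stat <- function(sub) {
    n <- sum(sub$count)
    m <- sum(sub$y * sub$count) / n
    v <- (sum(sub$y^2 * sub$count) - n * m^2) / (n - 1)
    c(n = n, zeros = sum(sub$count[sub$y == 0]), mean = m, sd = sqrt(v),
      dispersion = v / m)
  }
  per <- t(vapply(split(g, g$dose), stat, numeric(5)))
  pooled <- stat(g)
  out <- data.frame(dose = c(rownames(per), "pooled"),
                    rbind(per, pooled), row.names = NULL)
  out
}

#' Fit a count regression to the aberration data
#'
#' Runs the full application pipeline: linear-dose predictors for both
#' components (`log mu = beta10 + beta11 dose`;
#' `g2(omega) = beta20 + beta21 dose`), g-prior block
#' Metropolis-Hastings sampling on the grouped sufficient statistics, and
#' the assessment layer (comparison criteria, Bayesian p-value,
#' chi-square goodness of fit, influence diagnostics, randomized quantile
#' residuals).
#'
#' @param family model family: `"zmps"` (default), `"zmp"`, `"ps"` or
#'   `"poisson"`.
#' @param omega_link binary-component link (default probit, the link used
#'   in the reference analysis of these data).
#' @param mcmc an [mh_config()]; the default chain is `N = 50000` with
#'   10000 burn-in and thinning 10 (`M = 4000` retained draws).
#' @param assessment also run the assessment layer? Default TRUE.
#' @param seed convenience override of `mcmc$seed`.
#' @return A list with `fit` (a `zmps_fit`) and, when requested,
#'   `assessment` (a `zmps_assessment`).
#' @export
#' @examples
#' \donttest{
#' app <- fit_aberration(mcmc = mh_config(n_iter = 5000, thin = 5, seed = 1,
#'                                        hessian_refresh = "cached"))
#' summary(app$fit)
#' }
fit_aberration <- function(family = "zmps",
                           omega_link = "probit",
                           mcmc = mh_config(n_iter = 50000, burnin = 10000,
                                            thin = 10),
                           assessment = TRUE, seed = NULL) {
  if (!is.null(seed)) mcmc$seed <- seed
  g <- aberration_counts()
  d <- zmps_data(g$y, X1 = g$dose, weights = g$count,
                 omega_link = omega_link)
  colnames(d$X1) <- colnames(d$X2) <- c("(Intercept)", "dose")
  fit <- zmps_fit(d, family = family, mcmc = mcmc)
  out <- list(fit = fit)
  if (assessment)
    out$assessment <- assess(fit, seed = mcmc$seed)
  out
}
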