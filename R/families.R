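## Pluggable count families.  The hurdle engine only needs the baseline
## pmf, the positive-outcome probability and the variance function, so the
## hurdle Poisson (ZMP) and the plain Poisson / Poisson-Sujatha regressions
## reuse the same likelihood and sampling machinery as the ZMPS model.

#' Count family for the regression engine
#'
#' @param name one of `"zmps"` (hurdle Poisson-Sujatha, the default),
#'   `"zmp"` (hurdle Poisson), `"ps"` (plain Poisson-Sujatha) or
#'   `"poisson"` (plain Poisson).  The two hurdle families model zeros
#'   through a separate binary component; the two plain families have a
#'   single log-linear mean component.
#' @return An object of class `count_family`: a list with `name`, logical
#'   `hurdle`, `log_dens(y, mu)` (baseline log-pmf), `log_ppos(mu)`
#'   (log P(Y>0; mu)) and `var(mu)`.
#' @export
#' @examples
#' fam <- count_family("zmp")
#' fam$log_ppos(1)   # log(1 - exp(-1))
count_family <- function(name = c("zmps", "zmp", "ps", "poisson")) {
  name <- match.arg(name)
  fam <- switch(name,
    zmps = list(
      hurdle = TRUE,
      log_dens = function(y, mu) dps(y, mu, log = TRUE),
      log_ppos = function(mu) log_ps_ppos(mu),
      surv = ps_surv,
      var = ps_var),
    zmp = list(
      hurdle = TRUE,
      log_dens = function(y, mu) stats::dpois(y, mu, log = TRUE),
      log_ppos = function(mu) base::log(-expm1(-mu)),
      surv = function(q, mu) stats::ppois(q, mu, lower.tail = FALSE),
      var = function(mu) mu),
    ps = list(
      hurdle = FALSE,
      log_dens = function(y, mu) dps(y, mu, log = TRUE),
      log_ppos = function(mu) log_ps_ppos(mu),
      surv = ps_surv,
      var = ps_var),
    poisson = list(
      hurdle = FALSE,
      log_dens = function(y, mu) stats::dpois(y, mu, log = TRUE),
      log_ppos = function(mu) base::log(-expm1(-mu)),
      surv = function(q, mu) stats::ppois(q, mu, lower.tail = FALSE),
      var = function(mu) mu))
  structure(c(list(name = name), fam), class = "count_family")
}

as_family <- function(x) {
  if (inherits(x, "count_family")) x else count_family(x)
}
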