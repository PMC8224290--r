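## Link functions for the two model components.  The mean component always
## uses the log link; the binary (hurdle) component may use logit, probit or
## complementary log-log.  Built on stats::make.link(), augmented with the
## second derivative of the inverse link needed by Hessian-based proposals.

#' Link function specification
#'
#' Wraps [stats::make.link()] and adds the second derivative of the
#' inverse link.  The inverse maps the whole real line strictly inside the
#' link's range (positive reals for `log`, the open unit interval for the
#' binary links), so fitted probabilities never hit 0 or 1 exactly for
#' finite linear predictors.
#'
#' @param name one of `"log"`, `"logit"`, `"probit"`, `"cloglog"`.
#' @return An object of class `zmps_link`: a list with `name`, `linkfun`,
#'   `linkinv`, `mu.eta` (first derivative of the inverse) and `d2mu.deta`
#'   (second derivative of the inverse).
#' @export
#' @examples
#' lk <- zmps_link("logit")
#' lk$linkinv(0)     # 0.5
#' lk$mu.eta(0)      # 0.25
zmps_link <- function(name = c("logit", "probit", "cloglog", "log")) {
  name <- match.arg(name)
  base <- stats::make.link(name)
  d2 <- switch(name,
    log = function(eta) exp(eta),
    logit = function(eta) {
      w <- stats::plogis(eta)
      w * (1 - w) * (1 - 2 * w)
    },
    probit = function(eta) -eta * stats::dnorm(eta),
    cloglog = function(eta) {
      ## d/deta exp(eta - exp(eta)) = exp(eta - exp(eta)) * (1 - exp(eta))
      exp(eta - exp(eta)) * (1 - exp(eta))
    })
  structure(list(name = name,
                 linkfun = base$linkfun,
                 linkinv = base$linkinv,
                 mu.eta = base$mu.eta,
                 d2mu.deta = d2),
            class = "zmps_link")
}

as_link <- function(x) {
  if (inherits(x, "zmps_link")) x else zmps_link(x)
}

#' @export
print.zmps_link <- function(x, ...) {
  cat("<zmps_link>", x$name, "\n")
  invisible(x)
}
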