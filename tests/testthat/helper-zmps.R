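# shared fixtures: short MCMC configurations and hand-built fit objects

quick_cfg <- function(n_iter = 2000, burnin = NULL, thin = 2, seed = 1,
                      refresh = "cached", ...) {
  mh_config(n_iter = n_iter, burnin = burnin, thin = thin, seed = seed,
            hessian_refresh = refresh, ...)
}

# a degenerate "posterior" concentrated on a single coefficient vector,
# wrapped as a zmps_fit so the assessment layer can consume it
point_mass_fit <- function(beta1, beta2, data, family = "zmps", M = 4) {
  family <- zmpsreg::count_family(family)
  draws <- matrix(rep(c(beta1, beta2), each = M), nrow = M)
  colnames(draws) <- c(paste0("beta1_", seq_along(beta1)),
                       if (length(beta2)) paste0("beta2_", seq_along(beta2)))
  structure(list(draws = draws, data = data, family = family,
                 q1 = length(beta1), q2 = length(beta2),
                 accept = c(beta1 = 1), map = c(beta1, beta2),
                 config = quick_cfg()),
            class = "zmps_fit")
}

# small hurdle dataset simulated at fixed coefficients
sim_small <- function(n = 150, seed = 42, beta1 = c(-0.5, 1),
                      beta2 = c(0.5, 0.5), link = "logit") {
  set.seed(seed)
  x <- runif(n)
  mu <- exp(beta1[1] + beta1[2] * x)
  om <- zmps_link(link)$linkinv(beta2[1] + beta2[2] * x)
  y <- as.integer(rzmps(n, mu, om))
  zmps_data(y, X1 = x, omega_link = link)
}

# independent inversion oracle for the shape map, written against the mean
# formula only
shape_by_uniroot <- function(mu) {
  vapply(mu, function(m) {
    f <- function(t) (t^2 + 2 * t + 6) / (t * (t^2 + t + 2)) - m
    uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-14)$root
  }, numeric(1))
}

# posterior-mean coefficient blocks of a fit
split_beta_test <- function(fit) {
  b <- posterior_mean(fit)
  list(beta1 = b[seq_len(fit$q1)], beta2 = b[fit$q1 + seq_len(fit$q2)])
}
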