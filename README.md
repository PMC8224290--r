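# zmpsreg

Bayesian hurdle Poisson–Sujatha regression for overdispersed count data
with zero modification (inflation **or** deflation at zero).

## The problem

Count responses in biostatistics and epidemiology — aberrant cells per
sample, disease notifications per district, accidents per driver — are
routinely overdispersed *and* show a zero frequency that a Poisson (or
even a negative binomial) model cannot match.  Hurdle models split the
two issues: a binary component decides whether an outcome is positive,
and a zero-truncated count distribution generates the positive values.
`zmpsreg` uses the Poisson–Sujatha (PS) distribution — the Poisson
mixture with Sujatha mixing density
θ³/(θ²+θ+2)·(1+x+x²)·e^(−θx) — as the count component.  The PS family is
overdispersed for every parameter value, so the hurdle PS model handles
both features with **no extra dispersion parameter**, making it a
parsimonious competitor to hurdle negative binomial regression.

The model, for subject *i* with covariate rows x₁ᵢ and x₂ᵢ:

    P(Yᵢ = y) = (1 − ωᵢ) δ_y + ωᵢ P*(Yᵢ = y; μᵢ),   y = 0, 1, 2, …

    log μᵢ = x₁ᵢᵀ β₁         (zero-truncated PS mean component)
    g₂(ωᵢ) = x₂ᵢᵀ β₂         (logit / probit / cloglog hurdle component)

with the zero-modification parameter p = ω / P(Y>0; μ): p < 1 is zero
inflation, p > 1 zero deflation.  Inference is fully Bayesian:
unit-information g-priors βₖ ~ N(0, n(XₖᵀXₖ)⁻¹) on the two orthogonal
coefficient blocks and a block Metropolis–Hastings sampler whose
multivariate normal proposal N(νβ^(t−1), νH⁻¹), ν = n/(n+1), is built
from the numeric Hessian of each block's log-posterior.

The package provides the exact PS/zero-truncated/hurdle probability
functions under the mean parameterization, the sampler, convergence
diagnostics (Geweke, split-R̂, ESS), model comparison (DIC, EAIC, EBIC,
negative log pseudo-marginal likelihood, Bayesian p-value), randomized
quantile residuals, case-deletion KL/Hellinger influence diagnostics
with calibration, a grouped χ² goodness-of-fit table, a zero-modified
data simulator with a catalogue of inflation/deflation study scenarios,
and an embedded cytogenetic dosimetry dataset (5800 irradiated blood
cells; dicentric + centric ring aberration counts by dose).

## Worked example

Simulate a zero-deflated dataset and refit it:

```r
library(zmpsreg)
set.seed(7)
x <- runif(300)
y <- rzmps(300, mu = exp(-1 + x), omega = plogis(0.5 + 0.5 * x))
d <- zmps_data(as.integer(y), X1 = x, omega_link = "logit")
fit <- zmps_fit(d, mcmc = mh_config(n_iter = 10000, burnin = 2000,
                                    thin = 5, seed = 42))
summary(fit)
#>           parameter   mean median    sd ess hpd_lower hpd_upper
#> 1 beta1_(Intercept) -0.727 -0.725 0.254 813    -1.236    -0.272
#> 2           beta1_x  0.620  0.635 0.420 772    -0.176     1.382
#> 3 beta2_(Intercept)  0.845  0.838 0.262 718     0.344     1.372
#> 4           beta2_x -0.325 -0.329 0.437 691    -1.165     0.534
```

The posterior means sit within two posterior SDs of the generating values
(−1, 1, 0.5, 0.5); `ess` is the effective number of independent draws
out of the 1600 retained.  The fitted zero-modification parameter at the
covariate midpoint,

```r
p_from_omega(exp(sum(coef(fit)[1:2] * c(1, 0.5))),
             plogis(sum(coef(fit)[3:4] * c(1, 0.5))))
#> 1.64
```

exceeds 1, correctly recovering the zero **deflation** built into the
simulation.  The assessment layer summarizes fit quality:

```r
assess(fit, seed = 1)
#> Model assessment (zmps family)
#>     DIC    EAIC    EBIC   NLMPL      pB
#> 823.732 827.898 842.713 411.782   0.507
#> chi2 = 2.011 on 4 df (p = 0.734); n0_hat = 101.3; lambda_hat = 1.086; var_hat = 1.272
#> 3 observation row(s) flagged influential
```

A Bayesian p-value near 0.5 and a non-significant χ² say the model
reproduces its own data, as it should.  (The three "influential" rows
are the mild flags expected at this calibration threshold in a clean
sample of 300.)

The bundled dose–response application runs with one call — the 5800
cells collapse to 16 weighted sufficient-statistic cells, so the full
50,000-iteration chain takes under a minute:

```r
app <- fit_aberration(seed = 1)   # probit-hurdle ZMPS, dose as covariate
summary(app$fit)
app$assessment
```

A thin command-line front end with `fit`, `simulate`, `study` and
`reproduce` verbs is installed at `inst/cli/zmpsreg.R`.

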