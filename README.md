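# gedmix

Bayesian analysis of right-censored survival data with two-component
mixtures of generalized exponential distributions.

## The problem

Survival datasets from medical studies are often heterogeneous — a
cohort mixes sub-populations with different failure dynamics — and
right-censored: for some patients only a lower bound on the survival
time is observed. `gedmix` is for biostatisticians who want to model
such data with the two-component mixture of generalized exponential
distributions (2CMGED),

```
F(x; Ω) = π₁ (1 − e^{−θ₁x})^{λ₁} + (1 − π₁)(1 − e^{−θ₂x})^{λ₂},
Ω = (λ₁, λ₂, θ₁, θ₂, π₁),
```

a shape-flexible alternative to the exponential mixture (2CMED, the
λ₁ = λ₂ = 1 special case), and estimate it in a Bayesian way when the
Bayes estimators have no closed form. The package provides:

* `d/p/q/rged` and `d/p/rmixged` — the GED and its two-component
  mixture, with labelled inverse-CDF sampling;
* `censor_conventional()` / `censor_ce()` — type-II-style right
  censoring, either kept as censored (pooled survival factor at the
  largest observed failure `x_r`) or **completed by conditional
  expectations**: each censored item is replaced by
  `E[X | X > x_r]` for its component, a censoring treatment that
  markedly reduces estimation bias relative to the conventional
  scheme;
* `loglik_mixged()`, `score_mixged()`, `fit_mixged()` — the labelled
  censored likelihood, its analytic score and the MLE;
* `bayes_la()` / `bayes_is()` — Bayes estimates and posterior risks
  for all five parameters by **Lindley's approximation** (third-order
  expansion around the MLE) and by **importance sampling** (exact
  Beta/Gamma posterior factorisation with a residual log-weight),
  under flat or Beta–Gamma informative priors and squared-error,
  precautionary, entropy and LINEX losses;
* `reliability_chars()` / `bayes_rc()` — survival, hazard and reversed
  hazard at a time `t`, and their Bayes estimation;
* `run_simulation_study()` — a seeded Monte-Carlo driver producing
  tidy tables of replication-averaged estimates and posterior risks;
* `load_dataset()`, `descriptive_stats()`, `fit_and_score()` — two
  bundled cancer-survival datasets (121 breast-cancer times in months;
  51 + 45 head-and-neck-cancer times in days) with descriptive
  summaries and AIC/BIC/Cramér–von Mises/Anderson–Darling/
  Kolmogorov–Smirnov model comparison of 2CMGED vs 2CMED.

A thin command-line front end lives in `inst/cli/gedmix-cli.R`
(`simulate`, `fit`, `rc` subcommands).

## Worked example

```r
library(gedmix)
omega <- mixged_par(0.50, 1.20, 0.75, 1.50, 0.45)
reliability_chars(omega, t = 1)
#> Reliability characteristics at t = 1:
#>   R(t) = 0.1687   HR(t) = 1.4483   RHR(t) = 0.2939
```

At these reference parameter values, 16.9% of the population survives
past `t = 1`, the instantaneous failure rate among survivors is 1.448
per unit time, and the reversed hazard (failure density relative to
those already failed) is 0.294.

```r
set.seed(7)
s <- censor_conventional(rmixged(200, omega), censor_rate = 0.20)
s
#> Right-censored sample: n = 200, observed = 160, censored = 40
#>   censoring anchor t = 0.878905
#>   observed failures per component: r1 = 69, r2 = 91

fit_mixged(s)
#> Censored 2CMGED maximum-likelihood fit
#> Two-component generalized exponential mixture parameters
#>   component 1: lambda = 0.6397, theta = 2.441  (weight 0.3732)
#>   component 2: lambda = 0.8012, theta = 1.251  (weight 0.6268)
#>   log-likelihood -145.9160; converged: TRUE (max |score| = 7.82e-14)

bayes_la(s, prior_nip(), loss = "LLF")
#> Bayes estimates (LA, NIP prior, LLF loss)
#>  parameter  estimate posterior_risk flag
#>    lambda1 0.6438218   0.0053854755 <NA>
#>    lambda2 0.8231062   0.0049787498 <NA>
#>     theta1 2.1174230   0.2936118305 <NA>
#>     theta2 1.3254835   0.0259067132 <NA>
#>        pi1 0.3836660   0.0008051056 <NA>
```

The Bayes column is the LINEX-loss estimate of each parameter; the
posterior risk is the posterior expected loss at that estimate —
smaller is better, and risks shrink as `n` grows. On the bundled
breast-cancer data:

```r
descriptive_stats(load_dataset("dataset1"))
#>     n n_censored     mean median variance       sd skewness kurtosis
#> 1 121         53 32.29706  22.05 772.2083 27.78864 1.682674 5.655746

fit_and_score(load_dataset("dataset1"), "2cmged")
#> 2CMGED fit: loglik = -298.9939 (k = 5, n = 68)
#> Two-component generalized exponential mixture parameters
#>   component 1: lambda = 1.413, theta = 0.03088  (weight 0.6244)
#>   component 2: lambda = 4.841, theta = 0.1155  (weight 0.3756)
#>   AIC 607.9879  BIC 619.0854  CM 0.0222  AD 0.1835  KS 0.0473 (p = 0.9981)
```

(Descriptive statistics and the default goodness-of-fit comparison are
computed over the uncensored records; see the vignette for the
conventions and for the `censored = "likelihood"` alternative.) The
same comparison with `"2cmed"` gives AIC 614.60 and KS 0.131: every
fit statistic favours the shape-flexible mixture on both bundled
datasets.

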