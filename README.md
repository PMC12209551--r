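# frailcure

Penalized Weibull mixture cure models with gamma frailty, for
right-censored survival data in which a fraction of subjects is cured and
both model components may carry high-dimensional (e.g. transcriptomic)
covariates.

## The model

The population survival function is improper:

```
S_pop(t | x, z) = 1 − π(z) + π(z) · (1 + α t^γ e^{x'β} / θ)^(−θ)
```

* **Incidence**: π(z) = e^{z'b}/(1 + e^{z'b}) is the probability of being
  susceptible (uncured), with b = (b0, b_u, b_p).
* **Latency**: uncured subjects follow a Weibull baseline H0(t) = α t^γ
  with a multiplicative gamma frailty W (mean 1, variance 1/θ)
  marginalized through its Laplace transform, and coefficients
  β = (β_u, β_p).
* The `_p` blocks are high-dimensional and estimated under a multi-step
  adaptive elastic-net penalty; the `_u` blocks stay unpenalized.

Two fitters are provided: a penalized EM algorithm (`fit_mcfm_em()`) whose
E-step integrates the latent cure status and frailty in closed form and
whose M-steps are penalized logistic (with fractional responses), penalized
Weibull, and a 1-D frailty update; and a generalized monotone incremental
forward stagewise fitter (`fit_mcfm_gmifs()`) targeting the observed
likelihood directly, in a frailty (`"penMCFM"`) and a frailty-free
(`"MCM"`) variant. `cv_mcfm()` tunes the penalty by K-fold cross-validation
on a cure-adjusted concordance index; `simulate_mcfm()` draws data from the
model by inverse-CDF sampling adapted to the improper CDF; the metrics
module provides Harrell's and cure-adjusted concordance, selection
accuracy, relative model/estimation errors against a true-support oracle,
uncured-probability bias/MSE, and a prognostic risk score with median
dichotomization.

## A worked example

```r
library(frailcure)

design <- mcfm_design(n = 300, p_penalized = 100, s = 4, v = 2,
                      block_size = 25, n_x_u = 3, beta_u_range = c(-1, 1))
d <- simulate_mcfm(design, seed = 1)
d
#> <cure_data> n = 300  events = 82  (censoring 72.7%)
#>   incidence covariates: 2 unpenalized + 100 penalized
#>   latency covariates:   3 unpenalized + 100 penalized
#>   latent truth present (cured 67.0%)

fit <- fit_mcfm_em(d, lambda = 0.02, alpha_enet = 1, k_adaptive = 2)
fit
#> <mcfm_fit>  penMCFM(EM)   n = 300
#>   lambda=0.02 alpha_enet=1 k_adaptive=2
#>   alpha=0.4356 gamma=1.222 theta=584.7
#>   selected: 4 incidence, 5 latency; loglik -10.1164; 489 EM iters
```

`n = 300` subjects with 73% censoring; the fit retains 4 of 100 penalized
incidence coefficients and 5 of 100 latency coefficients (the true model
has 4 signals in each block at magnitude 2); `alpha`/`gamma` are the
Weibull scale and shape and `theta` the frailty parameter (here driven to
a large value: at this sample size the fit attributes the residual latency
heterogeneity to the selected covariates rather than the frailty).
`tidy(fit)` returns the full coefficient table,
`glance(fit)` a one-row summary, `autoplot(fit)` the (nondecreasing)
penalized log-likelihood trace, and `predict(fit, d, type = "uncured")`
the per-subject uncured probabilities.

Real data enter through a plain data frame plus column roles:

```r
cd <- cure_data(df, time = "os_years", status = "event",
                z_u = c("stage", "er_status"), x_u = c("age", "er_status"),
                z_p = gene_cols, x_p = gene_cols)   # shared penalized block
cv <- cv_mcfm(cd, alpha_enet = c(0.5, 1), K = 4, seed = 1)
```

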