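# abba — augmented binary analysis of responder endpoints in basket trials

Responder endpoints are composites: a continuous disease-activity score
dichotomised at a threshold (e.g. an ACR-N score of at least 20%, analysed
as `y1 >= log(20)` on the log scale) combined with a binary indicator `y2`
of rescue-medication use or discontinuation. Dichotomising the continuous
score discards information. **abba** analyses the composite *jointly*: the
score `y1` and a latent normal driver `y2*` of the binary indicator follow
a bivariate normal (multivariate probit) regression

    y1  = beta_k1 + gamma_k1 log(x) + theta_k1 t + e1
    y2* = beta_k2 + gamma_k2 log(x) + theta_k2 t + e2,
    (e1, e2) ~ MVN(0, Sigma),  Sigma = diag(sigma1, 1) Omega diag(sigma1, 1)

per subtrial `k` of a basket trial, with a participant counted as a
responder iff `y1 >= log(20)` and `y2 = 0` (equivalently `y2* > 0`). With
`sharing = TRUE` a Bayesian hierarchy borrows the intercepts, baseline
effects and treatment effects across subtrials; with `sharing = FALSE`
each subtrial is analysed separately. A logistic comparator
(`method = "bin"`) fits the dichotomised responder endpoint directly. The
treatment effect is reported as the posterior log odds ratio of response
per subtrial,

    lambda_k = mean_i [ logit r_i(t=1) - logit r_i(t=0) ],

where `r_i(t)` is the bivariate-normal upper-orthant probability of
response at participant i's own baseline covariate, summarised by the
posterior mean and 95% highest-density interval. Inference is by blocked
Gibbs sampling (sign-constrained latent-variable augmentation) implemented
in C++; a scenario simulator, intercept calibration, and a
replication harness for bias / precision / MSE / power / HDI width /
coverage are included.

## Worked example

Simulate a three-subtrial basket trial (50 participants per subtrial) with
a consistent treatment effect on both components, and fit the joint model
with borrowing:

```r
library(abba)
trial <- simulate_trial(make_scenario(4), seed = 1)
fit <- basket_fit(trial, seed = 1)   # ABBA with sharing, 2 x 10000 draws
print(fit)
```

```
ABBAs fit: joint latent-variable model, hierarchical borrowing across 3 subtrials
2 chains x 10000 draws (after 5000 warmup)

Posterior log odds ratio of response (95% HDI):
 subtrial mean hdi_low hdi_high width
        1 1.37   0.511     2.19  1.68
        2 1.50   0.653     2.38  1.73
        3 1.60   0.693     2.50  1.81
```

The true log odds ratio in this scenario is about 1.2 (see `true_lor()`);
every interval covers it and excludes 0. The dichotomised comparator on
the identical data gives wider intervals:

```r
bin <- basket_fit(trial, method = "bin", seed = 1)
round(100 * (bin$lor_summary$width - fit$lor_summary$width) /
        bin$lor_summary$width, 1)
#> [1] 20.6 21.0 20.7
```

i.e. the joint model shrinks the 95% HDI by about 21% here — information
recovered from the undichotomised score. `summary()`, `coef()`,
`predict()` and `plot()` methods expose the full posterior;
`run_replicates()` + `compute_metrics()` turn repeated simulate-and-fit
cycles into operating characteristics, and `read_trial_csv()` /
`run_analysis()` (or `inst/scripts/abba-analyze.R`) run the same analysis
on your own CSV data, including endpoints where response means being
below a cut (`direction = "less"`).

See the methods vignette (`vignettes/abba-methods.Rmd`) for the model,
priors, the simulator calibration, and numerical details.

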