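## Shared test helpers: short-chain MCMC settings and quiet fitting.

fast_ctrl <- function(warmup = 300L, iter = 500L, chains = 2L)
  mcmc_control(chains = chains, warmup = warmup, iter = iter)

## Fits with short chains legitimately trip the R-hat flag; the flag itself
## has a dedicated test.
quiet_fit <- function(...) suppressWarnings(basket_fit(...))

## Muffles only the R-hat convergence warning, letting data warnings through.
quiet_fit_warn <- function(d, ...) {
  withCallingHandlers(
    basket_fit(d, control = fast_ctrl(), ...),
    warning = function(w) {
      if (grepl("R-hat", conditionMessage(w))) invokeRestart("muffleWarning")
    })
}

## Small custom scenario builders used across files.
flat_scenario <- function(K = 1, beta = c(2.8, 0.3), gamma = c(0, 0),
                          theta = c(0, 0), sigma1 = 0.5, rho = 0.3,
                          n = 200L, law = baseline_law()) {
  scenario_params(beta = matrix(beta, K, 2, byrow = TRUE),
                  gamma = matrix(gamma, K, 2, byrow = TRUE),
                  theta = matrix(theta, K, 2, byrow = TRUE),
                  sigma1 = sigma1, rho = rho, baseline_law = law,
                  n_per_subtrial = n)
}
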