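test_that("latent sign partition splits and reassembles by the binary indicator", {
  p <- latent_signs(c(0, 1, 1, 0))
  expect_identical(p$positive, c(2L, 3L))
  expect_identical(p$negative, c(1L, 4L))
  expect_identical(latent_signs(c(0, 0))$positive, integer(0))
  y2 <- rep(c(0, 1, 1, 0, 1), 4)
  p <- latent_signs(y2)
  reassembled <- integer(length(y2))
  reassembled[p$positive] <- 1L
  reassembled[p$negative] <- 0L
  expect_identical(reassembled, as.integer(y2))
  expect_identical(sort(c(p$positive, p$negative)), seq_along(y2))
  expect_error(latent_signs(c(0, 2)), "binary")
})

test_that("malformed data are rejected with informative messages", {
  d <- simulate_trial(make_scenario(1), seed = 1)
  expect_error(basket_fit(d[setdiff(names(d), "y1")], control = fast_ctrl()),
               "missing columns: y1")
  d2 <- d; d2$y2[3] <- 2L
  expect_error(basket_fit(d2, control = fast_ctrl()), "binary")
  d3 <- d[!(d$subtrial == 2 & d$arm == 1), ]
  expect_error(basket_fit(d3, control = fast_ctrl()), "both arms")
})

test_that("a subtrial with a constant binary indicator warns but still fits", {
  d <- simulate_trial(make_scenario(1), seed = 2)
  d$y2[d$subtrial == 1] <- 0L
  expect_warning(f <- quiet_fit_warn(d), "identical")
  expect_s3_class(f, "basket_fit")
})

test_that("convergence diagnostics are computed and draws respect bounds", {
  d <- simulate_trial(make_scenario(4), seed = 3)
  f <- quiet_fit(d, control = fast_ctrl(warmup = 20, iter = 110, chains = 2),
                 seed = 1)
  expect_true(is.finite(f$diagnostics$max_rhat))
  g <- quiet_fit(d, control = mcmc_control(warmup = 2000, iter = 4000),
                 seed = 1)
  expect_lt(g$diagnostics$max_rhat, 1.05)
  expect_equal(nrow(g$draws), 2 * 4000)
  expect_true(all(abs(g$draws[, "rho"]) < 1))
  expect_true(all(g$draws[, grep("^sd_", colnames(g$draws))] >= 0.1))
})

test_that("parameters of a large single-subtrial dataset are recovered", {
  p <- flat_scenario(beta = c(0.93, 0.18), gamma = c(0.5, -0.1),
                     theta = c(0.5, 0.3), n = 5000L)
  d <- simulate_trial(p, seed = 4)
  f <- quiet_fit(d, sharing = FALSE,
                 control = mcmc_control(warmup = 1000, iter = 2000), seed = 5)
  truth <- c("beta[1,1]" = 0.93, "gamma[1,1]" = 0.5, "theta[1,1]" = 0.5,
             "beta[1,2]" = 0.18, "gamma[1,2]" = -0.1, "theta[1,2]" = 0.3,
             "sigma1" = 0.5, "rho" = 0.3)
  for (nm in names(truth)) {
    z <- (mean(f$draws[, nm]) - truth[nm]) / sd(f$draws[, nm])
    expect_lt(abs(z), 3)
  }
})

test_that("a stratified fit matches independent single-subtrial fits", {
  d <- simulate_trial(make_scenario(4, n_per_subtrial = 100), seed = 6)
  ctrl <- mcmc_control(warmup = 1000, iter = 3000)
  f_all <- quiet_fit(d, sharing = FALSE, control = ctrl, seed = 7)
  d2 <- d[d$subtrial == 2, ]
  d2$subtrial <- 1L
  f_one <- quiet_fit(d2, sharing = FALSE, control = ctrl, seed = 8)
  for (par in c("theta[1,1]", "theta[1,2]", "beta[1,1]")) {
    par_all <- sub("1,", "2,", par, fixed = TRUE)
    sd_ <- sd(f_one$draws[, par])
    expect_lt(abs(mean(f_all$draws[, par_all]) - mean(f_one$draws[, par])),
              0.3 * sd_)
  }
})

test_that("hierarchical borrowing shrinks subtrial effects together", {
  d <- simulate_trial(make_scenario(7), seed = 9)  # heterogeneous theta2
  ctrl <- mcmc_control(warmup = 500, iter = 1000)
  f_ns <- quiet_fit(d, sharing = FALSE, control = ctrl, seed = 10)
  f_s <- quiet_fit(d, sharing = TRUE, control = ctrl, seed = 10)
  ## force the hierarchy to its truncation bound: near-complete pooling
  tight <- abba_priors(sharing_sd_rate = 500)
  f_pool <- quiet_fit(d, sharing = TRUE, priors = tight, control = ctrl,
                      seed = 10)
  spread <- function(f) {
    th <- colMeans(f$draws)[sprintf("theta[%d,2]", 1:3)]
    max(th) - min(th)
  }
  expect_lt(spread(f_s), spread(f_ns))
  expect_lt(spread(f_pool), spread(f_s))
  expect_true(all(f_pool$draws[, "sd_theta[2]"] < 0.3))
})

test_that("posterior for sigma1 covers the generating value across replicates", {
  hits <- 0L
  for (r in 1:20) {
    d <- simulate_trial(make_scenario(4), seed = 100 + r)
    f <- quiet_fit(d, control = fast_ctrl(warmup = 400, iter = 800),
                   seed = 100 + r)
    h <- hdi(f$draws[, "sigma1"])
    hits <- hits + (h["lower"] <= 0.5 && 0.5 <= h["upper"])
  }
  expect_gte(hits, 18L)
})

test_that("fit methods expose the posterior coherently", {
  d <- simulate_trial(make_scenario(4), seed = 11)
  f <- quiet_fit(d, control = fast_ctrl(), seed = 12)
  expect_output(print(f), "ABBAs fit")
  s <- summary(f)
  expect_s3_class(s, "summary.basket_fit")
  expect_true(all(c("sigma1", "rho") %in% rownames(s$parameters)))
  expect_equal(unname(coef(f)["rho"]), mean(f$draws[, "rho"]))
  pr <- predict(f, data.frame(subtrial = 1, x = c(30, 60), arm = c(0, 1)))
  expect_true(all(pr > 0 & pr < 1))
  expect_identical(dim(f$lor), c(2L * f$control$iter, 3L))
  ## reproducibility under the same seed
  f2 <- quiet_fit(d, control = fast_ctrl(), seed = 12)
  expect_identical(f$draws, f2$draws)
})
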