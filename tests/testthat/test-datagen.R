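test_that("simulated data satisfy the generative definitions", {
  p <- make_scenario(4)
  d <- simulate_trial(p, seed = 1)
  expect_equal(nrow(d), 150L)
  expect_identical(d$y2, as.integer(d$y2star <= 0))
  expect_identical(d$responder,
                   as.integer(d$y1 >= p$response_threshold & d$y2 == 0))
  expect_identical(d$responder,
                   as.integer(d$y1 >= p$response_threshold & d$y2star > 0))
  tab <- table(d$subtrial, d$arm)
  expect_true(all(tab == 25L))
  expect_identical(d, simulate_trial(p, seed = 1))
  expect_false(identical(d$y1, simulate_trial(p, seed = 2)$y1))
})

test_that("a covariate law admitting nonpositive draws is rejected by name", {
  p <- flat_scenario(law = baseline_law("normal", mean = 1, sd = 5), n = 100)
  expect_error(simulate_trial(p, seed = 1), "nonpositive.*x ~ N\\(1, 5")
})

test_that("error correlation and the independence closed form are recovered", {
  ## gamma = 0 so the marginal (y1, y2star) correlation equals rho
  p <- flat_scenario(beta = c(3.0, 0.2), rho = 0.3, n = 100000L)
  d <- simulate_trial(p, seed = 3)
  se <- (1 - 0.3^2) / sqrt(nrow(d))
  expect_lt(abs(cor(d$y1, d$y2star) - 0.3), 3 * se)

  ## rho = 0, gamma = 0: responder rate factorises by arm
  p0 <- flat_scenario(beta = c(3.0, 0.2), theta = c(0.4, 0.3), rho = 0,
                      n = 100000L)
  d0 <- simulate_trial(p0, seed = 4)
  for (t in 0:1) {
    rate <- mean(d0$responder[d0$arm == t])
    want <- pnorm((3.0 + 0.4 * t - log(20)) / 0.5) * pnorm(0.2 + 0.3 * t)
    expect_lt(abs(rate - want), 3 * sqrt(want * (1 - want) / 50000))
  }
})

test_that("null treatment effects make the arms identical in law", {
  p <- make_scenario(1, n_per_subtrial = 334000L)  # ~1e6 participants total
  d <- simulate_trial(p, seed = 5)
  r1 <- mean(d$responder[d$arm == 1])
  r0 <- mean(d$responder[d$arm == 0])
  se <- sqrt(2 * 0.2 * 0.8 / (nrow(d) / 2))
  expect_lt(abs(r1 - r0), 3 * se)
  expect_lt(abs(mean(d$responder) - 0.20), 0.01)  # calibrated pooled rate
})

test_that("intercept calibration round-trips through an independent oracle", {
  g <- c(0.5, -0.1); th <- c(0.5, 0.3)
  b <- calibrate_intercepts(gamma = g, theta = th, sigma1 = 0.5, rho = 0.3,
                            target_rr_control = 0.2,
                            target_rr_treatment = 0.4)
  r <- attr(b, "rates")
  expect_lt(abs(r["control"] - 0.2), 0.005)
  expect_lt(abs(r["treatment"] - 0.4), 0.005)
  ## Monte-Carlo re-evaluation, independent of the quadrature used inside
  p <- flat_scenario(beta = b, gamma = g, theta = th, n = 200000L)
  d <- simulate_trial(p, seed = 6)
  for (t in 0:1) {
    emp <- mean(d$responder[d$arm == t])
    expect_lt(abs(emp - c(0.2, 0.4)[t + 1]),
              0.005 + 3 * sqrt(0.3 * 0.7 / 100000))
  }
})

test_that("null effects give the same intercepts for both arms", {
  b <- calibrate_intercepts(gamma = c(0.5, -0.1), theta = c(0, 0),
                            sigma1 = 0.5, rho = 0.3,
                            target_rr_control = 0.2,
                            target_rr_treatment = 0.2)
  r <- attr(b, "rates")
  expect_equal(unname(r["control"]), unname(r["treatment"]), tolerance = 1e-6)
})

test_that("with no baseline effect and rho = 0 calibration matches the closed form", {
  th <- c(0.4, 0.2)
  b <- calibrate_intercepts(gamma = c(0, 0), theta = th, sigma1 = 0.5,
                            rho = 0, target_rr_control = 0.2,
                            target_rr_treatment = 0.4)
  rate <- function(t) pnorm((b[1] + th[1] * t - log(20)) / 0.5) *
    pnorm(b[2] + th[2] * t)
  expect_equal(unname(rate(0)), 0.2, tolerance = 0.005)
  expect_equal(unname(rate(1)), 0.4, tolerance = 0.005)
})

test_that("true log odds ratios vanish exactly in null subtrials and order correctly", {
  t1 <- true_lor(make_scenario(1), n_large = 1e5, seed = 7)
  expect_true(all(abs(t1$lor) < 1e-10))        # theta = 0: exact symmetry
  t5 <- true_lor(make_scenario(5), n_large = 1e5, seed = 7)
  expect_lt(abs(t5$lor[3]), 1e-10)
  expect_gt(t5$lor[1], 1)                      # active subtrials near 1.2
  t8 <- true_lor(make_scenario(8), n_large = 1e5, seed = 7)
  expect_true(t8$lor[1] < t8$lor[2] && t8$lor[2] < t8$lor[3])
  expect_lt(t8$lor[1], 0)
})

test_that("degenerate response rates fail naming the arm", {
  p <- flat_scenario(beta = c(60, 60), n = 200)
  expect_error(true_lor(p, n_large = 1e5, seed = 1), "degenerate.*arm")
})
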