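test_that("orthant probability factorises at rho = 0 and matches known values", {
  set.seed(1)
  h <- runif(20, -3, 3); k <- runif(20, -3, 3)
  expect_equal(pbvn_upper(h, k, rep(0, 20)), pnorm(-h) * pnorm(-k),
               tolerance = 1e-12)
  expect_equal(pbvn_upper(0, 0, 0), 0.25, tolerance = 1e-12)
  ## P(X>0, Y>0) = 1/4 + asin(rho)/(2*pi)
  expect_equal(pbvn_upper(0, 0, 0.5), 0.25 + asin(0.5) / (2 * pi),
               tolerance = 1e-12)
  p <- response_probability_abba(c(log(20), 0), c(0, 0), c(0, 0),
                                 sigma1 = 1, rho = 0, x = 1, t = 0)
  expect_equal(p, 0.25, tolerance = 1e-12)
})

test_that("orthant probability agrees with an established implementation", {
  set.seed(42)
  for (i in 1:100) {
    h <- runif(1, -4, 4); k <- runif(1, -4, 4); r <- runif(1, -0.99, 0.99)
    want <- as.numeric(mvtnorm::pmvnorm(lower = c(h, k), upper = c(Inf, Inf),
                                        corr = matrix(c(1, r, r, 1), 2)))
    expect_equal(pbvn_upper(h, k, r), want, tolerance = 1e-10)
  }
})

test_that("orthant probability is monotone in the means and in rho", {
  mu <- seq(-2, 2, length.out = 9)
  for (r in c(-0.5, 0, 0.6)) {
    p1 <- pbvn_upper(-mu, rep(0.3, 9), rep(r, 9))   # increasing mu1
    expect_true(all(diff(p1) > 0))
    p2 <- pbvn_upper(rep(0.3, 9), -mu, rep(r, 9))
    expect_true(all(diff(p2) > 0))
  }
  rr <- seq(-0.95, 0.95, length.out = 20)
  for (hk in list(c(0.5, 0.5), c(-1, 0.7), c(1.5, -0.5)))
    expect_true(all(diff(pbvn_upper(rep(hk[1], 20), rep(hk[2], 20), rr)) > 0))
})

test_that("responder probability rejects invalid inputs", {
  expect_error(response_probability_abba(c(0, 0), c(0, 0), c(0, 0), 1, 1.2,
                                         x = 1, t = 0), "rho")
  expect_error(response_probability_abba(c(0, 0), c(0, 0), c(0, 0), 1, 0,
                                         x = -1, t = 0), "positive")
  expect_error(response_probability_bin(0, 1, 0, x = 0, t = 1), "positive")
})

test_that("individual log odds ratio has its closed-form properties", {
  expect_equal(individual_lor(0.37, 0.37), 0)
  expect_equal(individual_lor(0.8, 0.5), log(4))
  set.seed(2)
  a <- runif(50, 0.01, 0.99); b <- runif(50, 0.01, 0.99)
  expect_equal(individual_lor(a, b), -individual_lor(b, a))
  expect_error(individual_lor(1, 0.5), "infinite odds")
})

test_that("subtrial log odds ratio aggregates counterfactual probabilities", {
  draw <- list(beta = c(2.8, 0.3), gamma = c(0.5, -0.1),
               theta = c(0.5, 0.3), sigma1 = 0.5, rho = 0.3)
  d_hom <- data.frame(x = rep(40, 30), subtrial = 1)
  single <- individual_lor(
    response_probability_abba(draw$beta, draw$gamma, draw$theta, 0.5, 0.3,
                              40, 1),
    response_probability_abba(draw$beta, draw$gamma, draw$theta, 0.5, 0.3,
                              40, 0))
  expect_equal(subtrial_lor(draw, d_hom), single)

  draw0 <- draw; draw0$theta <- c(0, 0)
  set.seed(3)
  d <- data.frame(x = rlnorm(40, 3.76, 0.92), subtrial = 1)
  expect_equal(subtrial_lor(draw0, d), 0)

  expect_equal(subtrial_lor(draw, d),
               subtrial_lor(draw, d[rev(seq_len(nrow(d))), , drop = FALSE]))
  expect_equal(subtrial_lor(draw, d, aggregate = "sum"),
               nrow(d) * subtrial_lor(draw, d, aggregate = "mean"))
  expect_error(subtrial_lor(draw, d[0, , drop = FALSE]), "empty")

  bdraw <- list(beta = -1, gamma = 0.2, theta = 0.8)
  expect_equal(subtrial_lor(bdraw, d, method = "bin"), 0.8)
})

test_that("the highest-density interval is the shortest contiguous interval", {
  set.seed(8)
  z <- rnorm(1e6)
  h <- hdi(z)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.02)
  expect_equal(unname(h["upper"] - h["lower"]), 3.92, tolerance = 0.03)

  const <- rep(1.7, 200)
  expect_equal(unname(hdi(const)), c(1.7, 1.7))

  x <- rexp(5000)                     # skewed: HDI beats equal tails
  expect_equal(unname(hdi(x + 2) - hdi(x)), c(2, 2), tolerance = 1e-12)
  et <- unname(diff(quantile(x, c(0.025, 0.975))))
  expect_lte(unname(diff(hdi(x))), et)
  ## agreement with an independent HPD implementation
  expect_equal(unname(hdi(x)),
               as.numeric(coda::HPDinterval(coda::mcmc(x))),
               tolerance = 0.02)

  expect_error(hdi(rnorm(50)), "at least 100")
})
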