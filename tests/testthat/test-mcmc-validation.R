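## Independent validation of the Gibbs samplers: the same models (same
## likelihood, same priors) are fitted with JAGS via interval-censored
## latent-variable augmentation, and posterior moments are compared.

jags_abba_model <- "
model {
  for (i in 1:N) {
    mu1[i] <- beta[sub[i],1] + gamma[sub[i],1]*lx[i] + theta[sub[i],1]*t[i]
    mu2[i] <- beta[sub[i],2] + gamma[sub[i],2]*lx[i] + theta[sub[i],2]*t[i]
    y1[i] ~ dnorm(mu1[i], prec1)
    cm[i] <- mu2[i] + rho*(y1[i]-mu1[i])/sigma1
    ystar[i] ~ dnorm(cm[i], cprec)
    y2[i] ~ dinterval(ystar[i], 0)
  }
  cprec <- 1/(1-rho*rho)
  rho <- 2*u - 1
  u ~ dbeta(5, 5)                    # LKJ(5) for a 2x2 correlation
  isig1 ~ dgamma(0.5, 0.005)         # sigma1 ~ IG(0.5, 0.005)
  sigma1 <- 1/isig1
  prec1 <- pow(sigma1, -2)
  for (k in 1:K) { for (j in 1:2) {
    beta[k,j]  ~ dnorm(mub[j], taub[j])
    gamma[k,j] ~ dnorm(mug[j], taug[j])
    theta[k,j] ~ dnorm(mut[j], taut[j])
  }}
  for (j in 1:2) {
    mub[j] ~ dnorm(0, 0.04)
    mug[j] ~ dnorm(0, 0.04)
    mut[j] ~ dnorm(0, 0.04)
    sdb[j] ~ dexp(2) T(0.1,)
    sdg[j] ~ dexp(2) T(0.1,)
    sdt[j] ~ dexp(2) T(0.1,)
    taub[j] <- pow(sdb[j], -2)
    taug[j] <- pow(sdg[j], -2)
    taut[j] <- pow(sdt[j], -2)
  }
}"

jags_bin_model <- "
model {
  for (i in 1:N) {
    logit(p[i]) <- beta[sub[i]] + gamma[sub[i]]*lx[i] + theta[sub[i]]*t[i]
    resp[i] ~ dbern(p[i])
  }
  for (k in 1:K) {
    beta[k]  ~ dnorm(mub, taub)
    gamma[k] ~ dnorm(mug, taug)
    theta[k] ~ dnorm(mut, taut)
  }
  mub ~ dnorm(0, 0.04); mug ~ dnorm(0, 0.04); mut ~ dnorm(0, 0.04)
  sdb ~ dexp(2) T(0.3,); sdg ~ dexp(2) T(0.3,); sdt ~ dexp(2) T(0.3,)
  taub <- pow(sdb, -2); taug <- pow(sdg, -2); taut <- pow(sdt, -2)
}"

test_that("the latent-variable Gibbs sampler matches a JAGS fit of the same model", {
  library(rjags)
  d <- simulate_trial(make_scenario(4, n_per_subtrial = 100), seed = 5)
  f <- quiet_fit(d, "abba", sharing = TRUE,
                 control = mcmc_control(chains = 2, warmup = 2000,
                                        iter = 6000), seed = 9)
  ## the positively constrained latent part is the success (no-rescue) state
  dat <- list(N = nrow(d), K = 3, sub = d$subtrial, lx = log(d$x),
              t = d$arm, y1 = d$y1, y2 = 1 - d$y2)
  ini <- function(ch) list(ystar = ifelse(d$y2 == 0, 0.5, -0.5),
                           .RNG.name = "base::Mersenne-Twister",
                           .RNG.seed = ch)
  m <- jags.model(textConnection(jags_abba_model), dat,
                  inits = list(ini(1), ini(2)), n.chains = 2,
                  n.adapt = 1000, quiet = TRUE)
  update(m, 2000)
  s <- summary(coda.samples(m, c("theta", "beta", "sigma1", "rho"),
                            n.iter = 6000))$statistics
  for (p in c("theta[1,1]", "theta[2,1]", "theta[3,1]", "theta[1,2]",
              "theta[3,2]", "beta[1,1]", "beta[2,2]", "sigma1", "rho")) {
    expect_lt(abs(mean(f$draws[, p]) - s[p, "Mean"]), 0.2 * s[p, "SD"])
    expect_lt(abs(sd(f$draws[, p]) / s[p, "SD"] - 1), 0.2)
  }
})

test_that("the logistic Gibbs sampler matches a JAGS fit of the same model", {
  library(rjags)
  d <- simulate_trial(make_scenario(4, n_per_subtrial = 100), seed = 15)
  f <- quiet_fit(d, "bin", sharing = TRUE,
                 control = mcmc_control(chains = 2, warmup = 2000,
                                        iter = 6000), seed = 16)
  dat <- list(N = nrow(d), K = 3, sub = d$subtrial, lx = log(d$x),
              t = d$arm, resp = d$responder)
  ini <- function(ch) list(.RNG.name = "base::Mersenne-Twister",
                           .RNG.seed = ch)
  m <- jags.model(textConnection(jags_bin_model), dat,
                  inits = list(ini(1), ini(2)), n.chains = 2,
                  n.adapt = 1000, quiet = TRUE)
  update(m, 2000)
  s <- summary(coda.samples(m, c("theta", "beta"),
                            n.iter = 6000))$statistics
  for (p in c("theta[1]", "theta[2]", "theta[3]", "beta[1]", "beta[3]")) {
    expect_lt(abs(mean(f$draws[, p]) - s[p, "Mean"]), 0.2 * s[p, "SD"])
    expect_lt(abs(sd(f$draws[, p]) / s[p, "SD"] - 1), 0.2)
  }
})
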