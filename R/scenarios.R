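#' Scenario parameter sets for the simulation study
#'
#' Generative parameters for a basket trial with a composite responder
#' endpoint: a continuous score \code{y1} (analysed on the log scale) and a
#' binary rescue-medication indicator \code{y2} driven by a latent normal
#' variable \code{y2star}. Per subtrial \code{k}, the outcome means are
#' \deqn{\mu_{1} = \beta_{k1} + \gamma_{k1}\log x + \theta_{k1} t, \qquad
#'       \mu_{2} = \beta_{k2} + \gamma_{k2}\log x + \theta_{k2} t,}
#' with errors bivariate normal with SDs \code{(sigma1, 1)} and correlation
#' \code{rho}. The latent SD is fixed at 1 for identifiability.
#'
#' @param beta K x 2 matrix of intercepts (columns: continuous, latent).
#' @param gamma K x 2 matrix of baseline (log covariate) effects.
#' @param theta K x 2 matrix of treatment effects.
#' @param sigma1 SD of the continuous outcome (> 0).
#' @param rho Correlation between the two error components, in (-1, 1).
#' @param baseline_law Distribution of the positive baseline covariate
#'   \code{x}; see [baseline_law()].
#' @param n_per_subtrial Participants per subtrial (even; equal
#'   randomisation within subtrial).
#' @param response_threshold Responder cut for \code{y1} (default
#'   \code{log(20)}, the 20 percent-improvement criterion on the log scale).
#' @return An object of class \code{"scenario_params"}.
#' @seealso [make_scenario()] for the eight predefined scenarios.
#' @export
scenario_params <- function(beta, gamma, theta, sigma1 = 0.5, rho = 0.3,
                            baseline_law = abba::baseline_law(),
                            n_per_subtrial = 50L,
                            response_threshold = log(20)) {
  beta <- as.matrix(beta); gamma <- as.matrix(gamma); theta <- as.matrix(theta)
  K <- nrow(beta)
  stopifnot(K >= 1, ncol(beta) == 2, dim(gamma) == dim(beta),
            dim(theta) == dim(beta))
  if (!is.finite(sigma1) || sigma1 <= 0)
    stop("'sigma1' must be positive")
  if (!is.finite(rho) || rho <= -1 || rho >= 1)
    stop("'rho' must lie strictly inside (-1, 1)")
  n_per_subtrial <- as.integer(n_per_subtrial)
  if (any(n_per_subtrial %% 2L != 0L) || any(n_per_subtrial < 2L))
    stop("'n_per_subtrial' must be even (equal randomisation within subtrial)")
  if (length(n_per_subtrial) == 1L)
    n_per_subtrial <- rep(n_per_subtrial, K)
  stopifnot(length(n_per_subtrial) == K, is.finite(response_threshold))
  structure(list(K = K, beta = beta, gamma = gamma, theta = theta,
                 sigma1 = sigma1, sigma2 = 1, rho = rho,
                 baseline_law = baseline_law,
                 n_per_subtrial = n_per_subtrial,
                 response_threshold = response_threshold),
            class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Basket-trial scenario:", x$K, "subtrials,",
      paste(x$n_per_subtrial, collapse = "/"), "participants per subtrial\n")
  cat(sprintf("sigma1 = %g, sigma2 = 1, rho = %g, threshold = %.4f\n",
              x$sigma1, x$rho, x$response_threshold))
  tab <- data.frame(subtrial = seq_len(x$K),
                    beta1 = x$beta[, 1], beta2 = x$beta[, 2],
                    gamma1 = x$gamma[, 1], gamma2 = x$gamma[, 2],
                    theta1 = x$theta[, 1], theta2 = x$theta[, 2])
  print(tab, row.names = FALSE)
  cat("baseline covariate:", format_baseline_law(x$baseline_law), "\n")
  invisible(x)
}

#' Baseline covariate distribution
#'
#' Law of the positive baseline measure \code{x}. The default is
#' \code{log(x) ~ N(3.76, 0.92^2)}, calibrated so that, together with the
#' scenario intercepts, the model-implied responder rates match the target
#' rates of the simulation study (0.2 in null arms, 0.2/0.4 control/treated
#' otherwise). A \code{"normal"} family (x itself normal) is also supported;
#' it can produce nonpositive draws, which [simulate_trial()] rejects.
#'
#' @param family \code{"lognormal"} or \code{"normal"}.
#' @param meanlog,sdlog Parameters of \code{log(x)} for the lognormal family.
#' @param mean,sd Parameters of \code{x} for the normal family.
#' @return An object of class \code{"baseline_law"}.
#' @export
baseline_law <- function(family = c("lognormal", "normal"),
                         meanlog = 3.76, sdlog = 0.92,
                         mean = 45, sd = 15) {
  family <- match.arg(family)
  out <- if (family == "lognormal") {
    stopifnot(is.finite(meanlog), is.finite(sdlog), sdlog > 0)
    list(family = family, meanlog = meanlog, sdlog = sdlog)
  } else {
    stopifnot(is.finite(mean), is.finite(sd), sd > 0)
    list(family = family, mean = mean, sd = sd)
  }
  structure(out, class = "baseline_law")
}

format_baseline_law <- function(law) {
  if (law$family == "lognormal")
    sprintf("log(x) ~ N(%g, %g^2)", law$meanlog, law$sdlog)
  else
    sprintf("x ~ N(%g, %g^2)", law$mean, law$sd)
}

draw_baseline <- function(law, n) {
  if (law$family == "lognormal")
    stats::rlnorm(n, law$meanlog, law$sdlog)
  else
    stats::rnorm(n, law$mean, law$sd)
}

## Generative parameters of the eight simulation scenarios (per subtrial:
## beta1 beta2 gamma1 gamma2 theta1 theta2), with sigma1 = 0.5, sigma2 = 1,
## rho = 0.3 and K = 3 throughout.
.scenario_table <- list(
  `1` = rbind(c(1.07, 0.04, 0.5, -0.1, 0.0, 0.0),
              c(1.07, 0.04, 0.5, -0.1, 0.0, 0.0),
              c(1.07, 0.04, 0.5, -0.1, 0.0, 0.0)),
  `2` = rbind(c(0.84, 0.39, 0.5, -0.1, 0.7, 0.0),
              c(0.84, 0.39, 0.5, -0.1, 0.7, 0.0),
              c(0.84, 0.39, 0.5, -0.1, 0.7, 0.0)),
  `3` = rbind(c(2.91, 0.22, 0.0, -0.1, 0.0, 1.0),
              c(2.91, 0.22, 0.0, -0.1, 0.0, 1.0),
              c(2.91, 0.22, 0.0, -0.1, 0.0, 1.0)),
  `4` = rbind(c(0.93, 0.18, 0.5, -0.1, 0.5, 0.3),
              c(0.93, 0.18, 0.5, -0.1, 0.5, 0.3),
              c(0.93, 0.18, 0.5, -0.1, 0.5, 0.3)),
  `5` = rbind(c(0.24, 0.52, 0.7, -0.2, 0.4, 0.4),
              c(0.24, 0.52, 0.7, -0.2, 0.4, 0.4),
              c(0.56, 0.56, 0.7, -0.2, 0.0, 0.0)),
  `6` = rbind(c(1.15, 0.00, 0.5,  0.0, 0.0, 0.0),
              c(1.15, 0.00, 0.5,  0.0, 0.0, 0.0),
              c(1.04, -0.17, 0.5, 0.0, 0.4, 0.4)),
  `7` = rbind(c(0.90, 0.94, 0.5, -0.1, 0.5, -0.5),
              c(0.90, 0.43, 0.5, -0.1, 0.5,  0.0),
              c(0.98, 0.18, 0.5, -0.1, 0.5,  0.5)),
  `8` = rbind(c(1.28, 1.11, 0.5, -0.4, -0.5, 0.8),
              c(1.14, 1.16, 0.5, -0.4,  0.0, 0.8),
              c(1.14, 1.18, 0.5, -0.4,  0.5, 0.8)))

#' Predefined simulation scenarios
#'
#' Returns the generative parameters of one of the eight simulation-study
#' scenarios (three subtrials each). Scenarios 1-4 have a global
#' (consistent) treatment effect: none, continuous component only, latent
#' component only, or both. Scenarios 5-8 mix effective and null subtrials
#' or make one component inconsistent across subtrials.
#'
#' @param id Scenario number, 1 to 8.
#' @param n_per_subtrial Participants per subtrial (default 50).
#' @param baseline_law Covariate law; default as in [baseline_law()].
#' @return A [scenario_params()] object with K = 3.
#' @examples
#' make_scenario(4)
#' @export
make_scenario <- function(id, n_per_subtrial = 50L,
                          baseline_law = abba::baseline_law()) {
  key <- as.character(id)
  if (length(id) != 1L || !key %in% names(.scenario_table))
    stop("unknown scenario id; valid ids: ",
         paste(names(.scenario_table), collapse = ", "))
  m <- .scenario_table[[key]]
  scenario_params(beta = m[, 1:2], gamma = m[, 3:4], theta = m[, 5:6],
                  sigma1 = 0.5, rho = 0.3, baseline_law = baseline_law,
                  n_per_subtrial = n_per_subtrial)
}
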