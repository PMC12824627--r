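## Responder probabilities, per-subtrial log odds ratios and
## highest-density intervals computed from posterior draws.

#' Responder probability under the latent-variable model
#'
#' Probability that a participant with baseline covariate \code{x} in arm
#' \code{t} is a responder: the upper-orthant probability
#' \eqn{P(y_1 \ge \mathrm{threshold},\ y_2^\star > 0)} of the bivariate
#' normal with means \eqn{(\mu_1, \mu_2)}, SDs \code{(sigma1, 1)} and
#' correlation \code{rho}, evaluated by Genz's algorithm (accurate to about
#' 1e-14; see [pbvn_upper()]).
#'
#' @param beta,gamma,theta Length-2 parameter vectors (continuous
#'   component first).
#' @param sigma1,rho Outcome SD (> 0) and latent correlation in (-1, 1).
#' @param x Positive baseline covariate (vectorised).
#' @param t Arm indicator, 0 or 1 (vectorised).
#' @param threshold Responder cut for \code{y1} (default \code{log(20)}).
#' @return Probabilities in (0, 1).
#' @examples
#' # with rho = 0 the orthant factorises:
#' response_probability_abba(c(log(20), 0), c(0, 0), c(0, 0),
#'                           sigma1 = 1, rho = 0, x = 1, t = 0)  # 0.25
#' @export
response_probability_abba <- function(beta, gamma, theta, sigma1, rho,
                                      x, t, threshold = log(20)) {
  stopifnot(length(beta) == 2, length(gamma) == 2, length(theta) == 2,
            sigma1 > 0)
  if (!all(is.finite(rho)) || any(abs(rho) >= 1))
    stop("'rho' must lie strictly inside (-1, 1)")
  if (any(x <= 0)) stop("'x' must be positive (log baseline undefined)")
  lx <- log(x)
  mu1 <- beta[1] + gamma[1] * lx + theta[1] * t
  mu2 <- beta[2] + gamma[2] * lx + theta[2] * t
  pbvn_upper((threshold - mu1) / sigma1, -mu2, rho)
}

#' Responder probability under the logistic comparator model
#'
#' Inverse-logit of \eqn{\xi = \beta + \gamma \log x + \theta t}.
#'
#' @param beta,gamma,theta Scalar coefficients.
#' @param x Positive baseline covariate (vectorised).
#' @param t Arm indicator, 0 or 1 (vectorised).
#' @return Probabilities in (0, 1).
#' @export
response_probability_bin <- function(beta, gamma, theta, x, t) {
  if (any(x <= 0)) stop("'x' must be positive (log baseline undefined)")
  stats::plogis(beta + gamma * log(x) + theta * t)
}

#' Individual log odds ratio
#'
#' \eqn{\lambda_i = \log\{r_t/(1-r_t)\} - \log\{r_c/(1-r_c)\}} for
#' counterfactual responder probabilities under treatment and control.
#'
#' @param r_t,r_c Probabilities strictly inside (0, 1).
#' @return Log odds ratio(s).
#' @examples
#' individual_lor(0.8, 0.5)  # log(4)
#' @export
individual_lor <- function(r_t, r_c) {
  if (any(r_t <= 0 | r_t >= 1 | r_c <= 0 | r_c >= 1))
    stop("probabilities on the boundary give infinite odds")
  stats::qlogis(r_t) - stats::qlogis(r_c)
}

#' Subtrial log odds ratio for one posterior draw
#'
#' For every participant of the subtrial (both arms), computes the
#' counterfactual responder probabilities at the participant's own baseline
#' covariate under \code{t = 1} and \code{t = 0} from a single draw of the
#' model parameters, transforms to individual log odds ratios, and
#' aggregates. The default aggregation is the mean over participants, which
#' puts \eqn{\lambda_k} on the scale of a single individual's log odds
#' ratio; \code{"sum"} multiplies by the subtrial size.
#'
#' @param draw Named list of parameters for the subtrial. For
#'   \code{method = "abba"}: \code{beta}, \code{gamma}, \code{theta}
#'   (length-2 each), \code{sigma1}, \code{rho}. For \code{method = "bin"}:
#'   scalar \code{beta}, \code{gamma}, \code{theta}.
#' @param data Data frame of the subtrial's participants (column \code{x}).
#' @param method \code{"abba"} or \code{"bin"}.
#' @param threshold Responder cut for the continuous score.
#' @param aggregate \code{"mean"} (default) or \code{"sum"}.
#' @return Scalar \eqn{\lambda_k} for the draw.
#' @export
subtrial_lor <- function(draw, data, method = c("abba", "bin"),
                         threshold = log(20),
                         aggregate = c("mean", "sum")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  if (nrow(data) == 0L) stop("empty subtrial")
  if (method == "abba") {
    r_t <- response_probability_abba(draw$beta, draw$gamma, draw$theta,
                                     draw$sigma1, draw$rho, data$x, 1,
                                     threshold)
    r_c <- response_probability_abba(draw$beta, draw$gamma, draw$theta,
                                     draw$sigma1, draw$rho, data$x, 0,
                                     threshold)
  } else {
    r_t <- response_probability_bin(draw$beta, draw$gamma, draw$theta,
                                    data$x, 1)
    r_c <- response_probability_bin(draw$beta, draw$gamma, draw$theta,
                                    data$x, 0)
  }
  li <- individual_lor(r_t, r_c)
  if (aggregate == "mean") mean(li) else sum(li)
}

#' Highest-density interval of posterior draws
#'
#' Shortest contiguous interval containing the requested posterior mass:
#' the minimising window of \code{ceiling(mass * n)} consecutive sorted
#' draws (ties broken toward the lower window).
#'
#' @param draws Numeric vector of at least 100 draws.
#' @param mass Probability mass (default 0.95).
#' @return Named numeric \code{c(lower, upper)}.
#' @examples
#' set.seed(1)
#' hdi(rnorm(1e5))  # close to (-1.96, 1.96)
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  n <- length(draws)
  m <- ceiling(mass * n)
  if (n < 100 || m >= n)
    stop("need at least 100 draws (and enough to leave both tails)")
  s <- sort(draws)
  lo <- s[seq_len(n - m)]
  hi <- s[seq.int(m + 1, n)]
  i <- which.min(hi - lo)
  c(lower = lo[i], upper = hi[i])
}

## Posterior lambda_k draws for a fitted model: draws x K matrix.
posterior_lor_draws <- function(draws, data, K, method, threshold,
                                aggregate) {
  mean_agg <- aggregate == "mean"
  out <- matrix(NA_real_, nrow(draws), K)
  colnames(out) <- paste0("lambda[", seq_len(K), "]")
  for (k in seq_len(K)) {
    lx <- log(data$x[data$subtrial == k])
    if (method == "abba") {
      ## stratified multi-subtrial fits carry per-subtrial sigma1/rho
      s1 <- if ("sigma1" %in% colnames(draws)) "sigma1"
            else sprintf("sigma1[%d]", k)
      rh <- if ("rho" %in% colnames(draws)) "rho" else sprintf("rho[%d]", k)
      out[, k] <- lor_abba_cpp(draws[, sprintf("beta[%d,1]", k)],
                               draws[, sprintf("beta[%d,2]", k)],
                               draws[, sprintf("gamma[%d,1]", k)],
                               draws[, sprintf("gamma[%d,2]", k)],
                               draws[, sprintf("theta[%d,1]", k)],
                               draws[, sprintf("theta[%d,2]", k)],
                               draws[, s1], draws[, rh],
                               lx, threshold, mean_agg)
    } else {
      ## log odds are linear in the logistic model, so the individual log
      ## odds ratio equals theta_k for every participant.
      th <- draws[, sprintf("theta[%d]", k)]
      out[, k] <- if (mean_agg) th else th * length(lx)
    }
  }
  out
}
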