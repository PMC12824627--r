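## S3 methods for fitted basket-trial models.

#' @export
print.basket_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s model, %s across %d subtrials\n",
              x$method_tag,
              if (x$method == "abba") "joint latent-variable"
              else "logistic responder",
              if (x$sharing) "hierarchical borrowing" else "stratified",
              x$K))
  cat(sprintf("%d chains x %d draws (after %d warmup)\n",
              x$control$chains, x$control$iter, x$control$warmup))
  cat("\nPosterior log odds ratio of response (95% HDI):\n")
  print(format(x$lor_summary, digits = 3), row.names = FALSE)
  if (isTRUE(x$diagnostics$flagged))
    cat(sprintf("\nWARNING: max R-hat %.3f > 1.01\n", x$diagnostics$max_rhat))
  invisible(x)
}

#' @export
summary.basket_fit <- function(object, ...) {
  pars <- colnames(object$draws)
  tab <- data.frame(
    mean = colMeans(object$draws),
    sd = apply(object$draws, 2, stats::sd),
    row.names = pars)
  h <- t(apply(object$draws, 2, hdi))
  tab$hdi_low <- h[, 1]; tab$hdi_high <- h[, 2]
  if (length(object$diagnostics$rhat) == nrow(tab))
    tab$rhat <- object$diagnostics$rhat
  out <- list(parameters = tab, lor = object$lor_summary,
              diagnostics = object$diagnostics,
              method_tag = object$method_tag)
  class(out) <- "summary.basket_fit"
  out
}

#' @export
print.summary.basket_fit <- function(x, ...) {
  cat(x$method_tag, "posterior summary\n\nParameters:\n")
  print(format(x$parameters, digits = 3))
  cat("\nLog odds ratio of response per subtrial:\n")
  print(format(x$lor, digits = 3), row.names = FALSE)
  cat(sprintf("\nmax R-hat: %.3f   min ESS: %.0f\n",
              x$diagnostics$max_rhat, x$diagnostics$min_ess))
  invisible(x)
}

#' @export
coef.basket_fit <- function(object, ...) {
  colMeans(object$draws)
}

#' Posterior mean responder probabilities
#'
#' @param object A [basket_fit()] object.
#' @param newdata Data frame with columns \code{subtrial}, \code{x} and
#'   \code{arm}; defaults to the fitted data.
#' @param ... Unused.
#' @return Vector of posterior mean responder probabilities.
#' @export
predict.basket_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  stopifnot(all(c("subtrial", "x", "arm") %in% names(newdata)),
            all(newdata$x > 0),
            all(newdata$subtrial %in% seq_len(object$K)))
  d <- object$draws
  vapply(seq_len(nrow(newdata)), function(i) {
    k <- newdata$subtrial[i]; lx <- log(newdata$x[i]); t <- newdata$arm[i]
    if (object$method == "abba") {
      mu1 <- d[, sprintf("beta[%d,1]", k)] +
        d[, sprintf("gamma[%d,1]", k)] * lx +
        d[, sprintf("theta[%d,1]", k)] * t
      mu2 <- d[, sprintf("beta[%d,2]", k)] +
        d[, sprintf("gamma[%d,2]", k)] * lx +
        d[, sprintf("theta[%d,2]", k)] * t
      s1 <- if ("sigma1" %in% colnames(d)) "sigma1"
            else sprintf("sigma1[%d]", k)
      rh <- if ("rho" %in% colnames(d)) "rho" else sprintf("rho[%d]", k)
      mean(pbvn_upper((object$threshold - mu1) / d[, s1], -mu2, d[, rh]))
    } else {
      mean(stats::plogis(d[, sprintf("beta[%d]", k)] +
                           d[, sprintf("gamma[%d]", k)] * lx +
                           d[, sprintf("theta[%d]", k)] * t))
    }
  }, numeric(1))
}

#' Interval plot of the posterior log odds ratios
#'
#' @param x A [basket_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.basket_fit <- function(x, ...) {
  s <- x$lor_summary
  graphics::plot(s$mean, s$subtrial, xlim = range(s$hdi_low, s$hdi_high, 0),
                 ylim = c(0.5, x$K + 0.5), pch = 19, yaxt = "n",
                 xlab = "log odds ratio of response", ylab = "subtrial",
                 main = paste(x$method_tag, "posterior (95% HDI)"), ...)
  graphics::axis(2, at = s$subtrial)
  graphics::segments(s$hdi_low, s$subtrial, s$hdi_high, s$subtrial)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}
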