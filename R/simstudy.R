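## Replicated simulation harness and operating characteristics.

#' Run replicated simulate-and-fit cycles
#'
#' For each replicate, simulates a trial from the scenario, fits the
#' requested model and records the posterior summary of the per-subtrial
#' log odds ratio. Child seeds are derived deterministically from
#' \code{master_seed} and the replicate index, so any single replicate can
#' be reproduced in isolation and interrupted runs resume from a partial
#' results file.
#'
#' @param scenario A [scenario_params()] object or a scenario id (1-8).
#' @param method One of \code{"ABBAs"}, \code{"ABBAns"}, \code{"BINs"},
#'   \code{"BINns"} (model + sharing variant).
#' @param M Number of replicates.
#' @param n_per_subtrial Overrides the scenario's subtrial size if given.
#' @param control An [mcmc_control()] object (scale it down for large M).
#' @param master_seed Integer master seed.
#' @param out_file Optional CSV path; per-replicate rows are appended as
#'   they complete, and existing rows are reused on restart.
#' @return Data frame with one row per (replicate, subtrial): posterior
#'   mean, variance, 95\% HDI limits, width and a convergence flag.
#'   Attribute \code{"failures"} counts failed replicates.
#' @export
run_replicates <- function(scenario, method = c("ABBAs", "ABBAns", "BINs",
                                                "BINns"),
                           M, n_per_subtrial = NULL,
                           control = mcmc_control(warmup = 1000L,
                                                  iter = 1000L),
                           master_seed = 1L, out_file = NULL) {
  method <- match.arg(method)
  if (!inherits(scenario, "scenario_params"))
    scenario <- make_scenario(scenario)
  if (!is.null(n_per_subtrial))
    scenario$n_per_subtrial <- rep(as.integer(n_per_subtrial), scenario$K)
  stopifnot(M >= 1)
  fit_method <- if (grepl("^ABBA", method)) "abba" else "bin"
  sharing <- !grepl("ns$", method)

  done <- NULL
  if (!is.null(out_file) && file.exists(out_file)) {
    done <- utils::read.csv(out_file)
    done <- done[done$method == method, , drop = FALSE]
  }

  rows <- list()
  failures <- 0L
  for (m in seq_len(M)) {
    if (!is.null(done) && m %in% done$replicate) {
      rows[[m]] <- done[done$replicate == m, , drop = FALSE]
      next
    }
    child <- (as.integer(master_seed) + 104729L * m) %% .Machine$integer.max
    res <- tryCatch({
      d <- simulate_trial(scenario, seed = child)
      f <- withCallingHandlers(
        basket_fit(d, method = fit_method, sharing = sharing,
                   control = control, seed = child),
        warning = function(w) invokeRestart("muffleWarning"))
      data.frame(method = method, replicate = m,
                 subtrial = f$lor_summary$subtrial,
                 mean = f$lor_summary$mean,
                 post_var = apply(f$lor, 2, stats::var),
                 hdi_low = f$lor_summary$hdi_low,
                 hdi_high = f$lor_summary$hdi_high,
                 width = f$lor_summary$width,
                 flagged = f$diagnostics$flagged,
                 row.names = NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      message("replicate ", m, " failed: ", conditionMessage(res))
      next
    }
    rows[[m]] <- res
    if (!is.null(out_file))
      utils::write.table(res, out_file, sep = ",", append = file.exists(out_file),
                         col.names = !file.exists(out_file),
                         row.names = FALSE, qmethod = "double")
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  attr(out, "method") <- method
  attr(out, "M") <- M
  if (failures > 0.05 * M)
    warning(sprintf("%d of %d replicates failed (> 5%%); run flagged",
                    failures, M), call. = FALSE)
  out
}

#' Operating characteristics over simulation replicates
#'
#' Computes, per subtrial: bias of the posterior mean against the true log
#' odds ratio, average posterior precision (mean reciprocal posterior
#' variance), mean squared error, one-sided power (proportion of
#' replicates whose 95\% HDI lower limit exceeds 0; the type I error rate
#' in null subtrials), mean HDI width and coverage (proportion of HDIs
#' containing the true value), with Monte-Carlo standard errors.
#'
#' @param replicates Output of [run_replicates()].
#' @param true_lor Numeric vector of true log odds ratios per subtrial, or
#'   the data frame returned by [true_lor()]. If omitted, bias, MSE and
#'   coverage are omitted with a warning.
#' @return Data frame with one row per subtrial.
#' @export
compute_metrics <- function(replicates, true_lor = NULL) {
  if (is.data.frame(true_lor)) true_lor <- true_lor$lor
  ks <- sort(unique(replicates$subtrial))
  if (length(unique(replicates$replicate)) < 2)
    stop("need at least 2 successful replicates")
  if (is.null(true_lor))
    warning("no true log odds ratios supplied; bias, MSE and coverage ",
            "omitted", call. = FALSE)
  out <- lapply(ks, function(k) {
    r <- replicates[replicates$subtrial == k, , drop = FALSE]
    M <- nrow(r)
    pow <- mean(r$hdi_low > 0)
    row <- data.frame(subtrial = k, M = M,
                      precision = mean(1 / r$post_var),
                      power = pow,
                      power_mcse = sqrt(pow * (1 - pow) / M),
                      width = mean(r$width),
                      width_mcse = stats::sd(r$width) / sqrt(M))
    if (!is.null(true_lor)) {
      lt <- true_lor[k]
      cov <- mean(r$hdi_low <= lt & lt <= r$hdi_high)
      row$bias <- mean(r$mean) - lt
      row$bias_mcse <- stats::sd(r$mean) / sqrt(M)
      row$mse <- mean((r$mean - lt)^2)
      row$mse_mcse <- stats::sd((r$mean - lt)^2) / sqrt(M)
      row$coverage <- cov
      row$coverage_mcse <- sqrt(cov * (1 - cov) / M)
    }
    row
  })
  do.call(rbind, out)
}

#' Two-proportion power by the arcsine approximation
#'
#' Cohen's effect size \eqn{h = 2\arcsin\sqrt{p_2} - 2\arcsin\sqrt{p_1}};
#' power \eqn{\Phi(|h|\sqrt{n_1 n_2/(n_1+n_2)} - z_{1-\alpha})} one-sided
#' (plus the opposite tail when two-sided). The frequentist baseline for a
#' single subtrial with 25 per arm and rates 0.2 vs 0.4 is about 0.47.
#'
#' @param n1,n2 Arm sample sizes (>= 2).
#' @param p1,p2 Response rates in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @param sided 1 (default) or 2.
#' @return Power.
#' @examples
#' binary_power_two_prop(25, 25, 0.2, 0.4)  # ~0.47
#' @export
binary_power_two_prop <- function(n1, n2, p1, p2, alpha = 0.05, sided = 1) {
  stopifnot(n1 >= 2, n2 >= 2, p1 > 0, p1 < 1, p2 > 0, p2 < 1,
            sided %in% c(1, 2))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  h <- 2 * asin(sqrt(p2)) - 2 * asin(sqrt(p1))
  s <- sqrt(n1 * n2 / (n1 + n2))
  z <- stats::qnorm(1 - alpha / sided)
  pow <- stats::pnorm(abs(h) * s - z)
  if (sided == 2) pow <- pow + stats::pnorm(-abs(h) * s - z)
  pow
}

#' Compare operating characteristics of two methods
#'
#' Percent reduction in mean HDI width and percent increase in power of
#' method A relative to method B, per subtrial.
#'
#' @param metrics_a,metrics_b Outputs of [compute_metrics()] on aligned
#'   subtrials.
#' @return Data frame with columns \code{subtrial},
#'   \code{width_reduction_pct}, \code{power_increase_pct}; a zero
#'   denominator yields a non-finite delta rather than dropping the row.
#' @examples
#' a <- data.frame(subtrial = 1, power = 0.91, width = 1.82)
#' b <- data.frame(subtrial = 1, power = 0.54, width = 2.40)
#' compare_methods(a, b)
#' @export
compare_methods <- function(metrics_a, metrics_b) {
  stopifnot(identical(metrics_a$subtrial, metrics_b$subtrial))
  data.frame(subtrial = metrics_a$subtrial,
             width_reduction_pct =
               (metrics_b$width - metrics_a$width) / metrics_b$width * 100,
             power_increase_pct =
               (metrics_a$power - metrics_b$power) / metrics_b$power * 100)
}
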