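## CSV input/output, analysis configuration and the end-to-end analysis
## entry point used by the command-line wrapper.

#' Analysis configuration
#'
#' Bundles everything needed to run a responder analysis on a basket-trial
#' CSV file. \code{direction = "less"} covers endpoints where response
#' means being \emph{below} the cut (e.g. a disease-activity remission
#' threshold of 2.6): the continuous endpoint and threshold are negated
#' internally so the "at or above threshold" machinery applies unchanged.
#'
#' @param method \code{"abba"} or \code{"bin"}.
#' @param sharing Hierarchical borrowing across subtrials.
#' @param threshold Responder cut for the continuous endpoint (default
#'   \code{log(20)}).
#' @param direction \code{"greater"} (response at/above the cut) or
#'   \code{"less"} (below).
#' @param baseline_col Name of the positive baseline covariate column.
#' @param control An [mcmc_control()] object.
#' @param seed Integer seed.
#' @param out_prefix Path prefix for result files written by
#'   [run_analysis()]; \code{NULL} writes nothing.
#' @return A list of class \code{"analysis_config"}.
#' @export
analysis_config <- function(method = c("abba", "bin"), sharing = TRUE,
                            threshold = log(20),
                            direction = c("greater", "less"),
                            baseline_col = "x",
                            control = mcmc_control(), seed = 1L,
                            out_prefix = NULL) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  stopifnot(is.finite(threshold), inherits(control, "mcmc_control"))
  structure(list(method = method, sharing = sharing, threshold = threshold,
                 direction = direction, baseline_col = baseline_col,
                 control = control, seed = as.integer(seed),
                 out_prefix = out_prefix),
            class = "analysis_config")
}

#' Read basket-trial data from CSV
#'
#' Expects columns \code{subtrial}, \code{arm}, the baseline covariate
#' (named by \code{config$baseline_col}), \code{y1} and \code{y2}
#' (optionally \code{y2star} and \code{responder}). Rows with missing
#' values are reported by row number and rejected. For
#' \code{direction = "less"}, \code{y1} and the threshold are negated on
#' the way in and a \code{responder} column is derived accordingly. A
#' per-subtrial summary (arm sizes and the responder cross-tabulation) is
#' printed unless \code{quiet}.
#'
#' @param path CSV file path.
#' @param config An [analysis_config()] object.
#' @param quiet Suppress the data summary.
#' @return Validated data frame (with the working \code{y1} on the
#'   "greater" orientation and a \code{responder} column).
#' @export
read_trial_csv <- function(path, config = analysis_config(),
                           quiet = FALSE) {
  d <- utils::read.csv(path)
  bcol <- config$baseline_col
  need <- c("subtrial", "arm", bcol, "y1", "y2")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  bad <- which(!stats::complete.cases(d[need]))
  if (length(bad))
    stop("missing values in rows: ", paste(utils::head(bad, 20),
                                           collapse = ", "))
  names(d)[names(d) == bcol] <- "x"
  if (config$direction == "less") {
    d$y1 <- -d$y1
    thr <- -config$threshold
  } else thr <- config$threshold
  validate_trial_data(d)
  if (is.null(d$responder))
    d$responder <- as.integer(d$y1 >= thr & d$y2 == 0)
  if (!quiet) {
    for (k in sort(unique(d$subtrial))) {
      dk <- d[d$subtrial == k, ]
      cat(sprintf("subtrial %d: n = %d (control %d / treatment %d)\n", k,
                  nrow(dk), sum(dk$arm == 0), sum(dk$arm == 1)))
      print(stats::xtabs(~ arm + responder, dk))
    }
  }
  attr(d, "threshold") <- thr
  d
}

#' Write basket-trial data to CSV
#'
#' @param data Trial data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  keep <- intersect(c("subtrial", "arm", "x", "y1", "y2", "y2star",
                      "responder"), names(data))
  utils::write.csv(data[keep], path, row.names = FALSE)
  invisible(path)
}

#' Run a configured analysis end to end
#'
#' Fits the configured model to the data, and (when
#' \code{config$out_prefix} is set) writes the per-subtrial log odds ratio
#' summary as CSV and JSON, the pooled posterior draws as CSV, and a run
#' manifest (seed, configuration, package version) as JSON.
#'
#' @param config An [analysis_config()] object.
#' @param data Trial data frame (e.g. from [read_trial_csv()]); or a path
#'   to a CSV file.
#' @return The [basket_fit()] object, invisibly; its \code{lor_summary}
#'   carries the per-subtrial posterior means and 95\% HDIs.
#' @export
run_analysis <- function(config, data) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(data)) data <- read_trial_csv(data, config, quiet = TRUE)
  thr <- attr(data, "threshold")
  if (is.null(thr))
    thr <- if (config$direction == "less") -config$threshold
           else config$threshold
  fit <- basket_fit(data, method = config$method, sharing = config$sharing,
                    control = config$control, seed = config$seed,
                    threshold = thr)
  if (!is.null(config$out_prefix)) {
    p <- config$out_prefix
    res <- cbind(method = fit$method_tag, fit$lor_summary)
    utils::write.csv(res, paste0(p, "_lor.csv"), row.names = FALSE)
    jsonlite::write_json(list(method = fit$method_tag,
                              lor = fit$lor_summary,
                              diagnostics = fit$diagnostics[c("max_rhat",
                                                              "min_ess",
                                                              "flagged")]),
                         paste0(p, "_result.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(as.data.frame(fit$draws), paste0(p, "_draws.csv"),
                     row.names = FALSE)
    cfg <- config
    cfg$control <- unclass(cfg$control)
    jsonlite::write_json(list(config = unclass(cfg), seed = config$seed,
                              package_version =
                                as.character(utils::packageVersion("abba"))),
                         paste0(p, "_manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(fit)
}
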