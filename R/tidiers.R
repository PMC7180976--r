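#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for agreement analyses
#'
#' `tidy()` returns the fit terms; `glance()` a one-row summary with the
#' slope, correlation, relative error and Bland-Altman quantities.
#'
#' @param x An `agreement` object from [compare_angle_series()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.agreement <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.agreement
#' @export
glance.agreement <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 correlation = x$correlation,
                 mean_error_pct = x$mean_error_pct,
                 sd_error_pct = x$sd_error_pct,
                 bias = x$bias, loa_lower = x$loa_lower,
                 loa_upper = x$loa_upper, n = x$n)
}

#' Tidiers for stroke metrics
#'
#' `glance()` gives the one-row stroke-quality summary; `tidy()` the
#' per-cycle phase durations (empty without phase labels).
#'
#' @param x A `stroke_metrics` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.stroke_metrics <- function(x, ...) {
  tibble::tibble(period_mean = x$period_mean, period_sd = x$period_sd,
                 stroke_rate = x$stroke_rate, n_cycles = x$n_cycles,
                 ratio_mean = x$ratio_mean, ratio_sd = x$ratio_sd)
}

#' @rdname glance.stroke_metrics
#' @export
tidy.stroke_metrics <- function(x, ...) {
  if (is.null(x$cycles)) return(tibble::tibble())
  x$cycles
}

#' Tidiers for per-cycle statistics
#'
#' @param x A `cycle_stats` object.
#' @param ... Unused.
#' @return `tidy()`: the `channel, stat, mean, sd` table.
#' @export
tidy.cycle_stats <- function(x, ...) x$stats

#' Tidiers for classifier reports
#'
#' @param x A `model_report`.
#' @param ... Unused.
#' @return `tidy()`: chosen hyperparameters; `glance()`: accuracy and AUC.
#' @export
tidy.model_report <- function(x, ...) {
  tibble::tibble(parameter = names(x$params),
                 value = as.character(unlist(x$params)))
}

#' @rdname tidy.model_report
#' @export
glance.model_report <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, accuracy = x$accuracy,
                 auc = x$auc, n_train = x$n_train, n_test = x$n_test)
}
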