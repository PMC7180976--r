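#' Detect stroke cycles by peak picking
#'
#' Finds local maxima of a joint-angle channel (by default the left
#' shoulder flexion, whose peak marks the catch) subject to a topographic
#' prominence threshold and a minimum inter-peak distance; consecutive
#' retained peaks delimit stroke cycles. The detector is invariant to
#' constant offsets of the signal.
#'
#' @param series A joint-angle tibble (`t` + channel columns) or a numeric
#'   vector (then supply `t`).
#' @param channel Channel column to use when `series` is a tibble.
#' @param t Time vector when `series` is numeric.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   signal range (default 0.2).
#' @param min_distance_frac Minimum inter-peak distance as a fraction of
#'   the median inter-peak spacing of the prominent peaks (default 0.5).
#' @return A `stroke_events` object: list with `boundary_times` (s),
#'   `periods` (s), `peak_index`, `channel`. Zero events (with a warning)
#'   if no prominent peaks exist.
#' @export
detect_cycles <- function(series, channel = "SFl", t = NULL,
                          prominence_frac = 0.2, min_distance_frac = 0.5) {
  if (is.data.frame(series)) {
    if (!channel %in% names(series))
      stop("channel '", channel, "' not present in series")
    x <- series[[channel]]
    tt <- series$t
  } else {
    x <- as.numeric(series)
    tt <- if (is.null(t)) seq_along(x) - 1 else t
  }
  empty <- structure(list(boundary_times = numeric(0), periods = numeric(0),
                          peak_index = integer(0), channel = channel),
                     class = "stroke_events")
  rng <- diff(range(x))
  if (length(x) < 3 || rng < .Machine$double.eps) {
    warning("constant or too-short signal: no stroke cycles detected")
    return(empty)
  }
  # candidate interior local maxima (plateaus take the left edge)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) {
    warning("no peaks found")
    return(empty)
  }
  prom <- vapply(cand, function(i) peak_prominence(x, i), 0)
  keep <- cand[prom >= prominence_frac * rng]
  if (!length(keep)) {
    warning("no peaks exceed the prominence threshold")
    return(empty)
  }
  # minimum distance: greedy suppression, highest peaks first
  if (length(keep) > 1) {
    min_dist <- min_distance_frac * stats::median(diff(tt[keep]))
    ord <- keep[order(-x[keep])]
    sel <- integer(0)
    for (i in ord) {
      if (!length(sel) || all(abs(tt[i] - tt[sel]) >= min_dist)) sel <- c(sel, i)
    }
    keep <- sort(sel)
  }
  structure(list(boundary_times = tt[keep], periods = diff(tt[keep]),
                 peak_index = keep, channel = channel),
            class = "stroke_events")
}

# topographic prominence of a local maximum: on each side, minimum until
# the nearest strictly higher sample (or the series end); prominence is the
# peak height above the higher of the two side minima
peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]; j <- i - 1
  while (j >= 1 && x[j] <= x[i]) { left_min <- min(left_min, x[j]); j <- j - 1 }
  right_min <- x[i]; j <- i + 1
  while (j <= n && x[j] <= x[i]) { right_min <- min(right_min, x[j]); j <- j + 1 }
  x[i] - max(left_min, right_min)
}

#' @export
print.stroke_events <- function(x, ...) {
  cat("<stroke_events>", length(x$periods), "cycles on channel", x$channel, "\n")
  if (length(x$periods))
    cat("  period: mean", signif(mean(x$periods), 4), "s, sd",
        signif(stats::sd(x$periods), 3), "s\n")
  invisible(x)
}

#' Stroke-quality metrics
#'
#' Period mean and SD (sample, n-1 convention), cadence (60 / mean period,
#' strokes per minute) and, when per-sample phase labels are supplied, the
#' propulsion and recovery durations of every cycle and their ratio
#' (mean +/- SD across cycles).
#'
#' @param events A [detect_cycles()] result with at least 2 cycles.
#' @param phase_labels Optional tibble `t, phase` with phase in
#'   `c("propulsion", "recovery")` (per-sample or per-window midpoint
#'   times).
#' @return A `stroke_metrics` list: `period_mean`, `period_sd`,
#'   `stroke_rate`, `n_cycles`, and with labels `ratio_mean`, `ratio_sd`
#'   and a `cycles` tibble of per-cycle phase durations.
#' @export
stroke_metrics <- function(events, phase_labels = NULL) {
  stopifnot(inherits(events, "stroke_events"))
  if (length(events$periods) < 2)
    stop("insufficient data: need at least 2 complete stroke cycles")
  out <- list(period_mean = mean(events$periods),
              period_sd = stats::sd(events$periods),
              stroke_rate = 60 / mean(events$periods),
              n_cycles = length(events$periods),
              ratio_mean = NA_real_, ratio_sd = NA_real_, cycles = NULL)
  if (!is.null(phase_labels)) {
    phase_labels <- phase_labels[!is.na(phase_labels$phase), ]
    b <- events$boundary_times
    rows <- list()
    for (k in seq_len(length(b) - 1)) {
      in_cycle <- phase_labels$t >= b[k] & phase_labels$t < b[k + 1]
      if (!any(in_cycle)) next
      ph <- phase_labels$phase[in_cycle]
      n_prop <- sum(ph == "propulsion"); n_rec <- sum(ph == "recovery")
      dur <- b[k + 1] - b[k]
      rows[[k]] <- tibble::tibble(
        cycle = k,
        propulsion_s = dur * n_prop / length(ph),
        recovery_s = dur * n_rec / length(ph),
        ratio = if (n_rec > 0) n_prop / n_rec else NA_real_)
    }
    cyc <- dplyr::bind_rows(rows)
    out$cycles <- cyc
    r <- cyc$ratio[is.finite(cyc$ratio)]
    if (length(r)) {
      out$ratio_mean <- mean(r)
      out$ratio_sd <- if (length(r) > 1) stats::sd(r) else 0
    }
  }
  structure(out, class = "stroke_metrics")
}

#' @export
print.stroke_metrics <- function(x, ...) {
  cat("<stroke_metrics>", x$n_cycles, "cycles\n")
  cat(sprintf("  period : %.3f +/- %.3f s\n", x$period_mean, x$period_sd))
  cat(sprintf("  cadence: %.2f strokes/min\n", x$stroke_rate))
  if (is.finite(x$ratio_mean))
    cat(sprintf("  propulsion/recovery: %.2f +/- %.2f\n", x$ratio_mean, x$ratio_sd))
  invisible(x)
}

#' Per-cycle joint-angle statistics
#'
#' Resamples every complete cycle of every channel onto a fixed 101-point
#' normalized phase axis (0-100 percent of the cycle), computes per-cycle MAX,
#' MIN, ROM (= MAX - MIN, identically) and MEAN, and summarizes them as
#' mean +/- SD across cycles, together with the pointwise mean curve and
#' extremal envelope.
#'
#' @param series Joint-angle tibble (`t` + channel columns).
#' @param events A [detect_cycles()] result with >= 2 complete cycles.
#' @param n_phase Number of phase points (default 101).
#' @return A `cycle_stats` list: `stats` (tibble `channel, stat, mean, sd`),
#'   `curves` (tibble `channel, phase, mean, min, max`), `per_cycle`
#'   (tibble of per-cycle values), `n_cycles`.
#' @export
cycle_statistics <- function(series, events, n_phase = 101) {
  stopifnot(inherits(events, "stroke_events"))
  b <- events$boundary_times
  if (length(b) < 3) stop("insufficient data: need at least 2 complete cycles")
  channels <- setdiff(names(series), "t")
  phase <- seq(0, 1, length.out = n_phase)
  stats_rows <- list(); curve_rows <- list(); cyc_rows <- list()
  for (ch in channels) {
    mat <- matrix(NA_real_, length(b) - 1, n_phase)
    for (k in seq_len(length(b) - 1)) {
      sel <- series$t >= b[k] & series$t <= b[k + 1]
      if (sum(sel) < 3) {
        warning("skipping cycle ", k, " on ", ch, ": fewer than 3 samples")
        next
      }
      u <- (series$t[sel] - b[k]) / (b[k + 1] - b[k])
      mat[k, ] <- stats::approx(u, series[[ch]][sel], xout = phase, rule = 2)$y
    }
    ok <- stats::complete.cases(mat)
    mat <- mat[ok, , drop = FALSE]
    if (nrow(mat) < 2) stop("fewer than 2 usable cycles for channel ", ch)
    per <- tibble::tibble(channel = ch, cycle = which(ok),
                          MAX = apply(mat, 1, max), MIN = apply(mat, 1, min),
                          MEAN = rowMeans(mat))
    per$ROM <- per$MAX - per$MIN
    cyc_rows[[ch]] <- per
    stats_rows[[ch]] <- tibble::tibble(
      channel = ch, stat = c("ROM", "MAX", "MIN", "MEAN"),
      mean = c(mean(per$ROM), mean(per$MAX), mean(per$MIN), mean(per$MEAN)),
      sd = c(stats::sd(per$ROM), stats::sd(per$MAX), stats::sd(per$MIN),
             stats::sd(per$MEAN)))
    curve_rows[[ch]] <- tibble::tibble(
      channel = ch, phase = phase * 100, mean = colMeans(mat),
      min = apply(mat, 2, min), max = apply(mat, 2, max),
      sd = apply(mat, 2, stats::sd))
  }
  structure(list(stats = dplyr::bind_rows(stats_rows),
                 curves = dplyr::bind_rows(curve_rows),
                 per_cycle = dplyr::bind_rows(cyc_rows),
                 n_cycles = length(b) - 1),
            class = "cycle_stats")
}

#' @export
print.cycle_stats <- function(x, ...) {
  cat("<cycle_stats> over", x$n_cycles, "cycles\n")
  print(tidyr::pivot_wider(x$stats, names_from = "stat",
                           values_from = c("mean", "sd")))
  invisible(x)
}

#' Agreement between two joint-angle series
#'
#' Ordinary least-squares fit of the test series on the reference,
#' Pearson correlation, range-normalized relative error (per-sample
#' `|test - ref| / ROM(ref) * 100`, mean and SD in percent) and
#' Bland-Altman bias with 95 percent limits of agreement
#' (`bias +/- 1.96 * SD(diff)`).
#'
#' @param test,reference Numeric vectors of equal length (resample before
#'   calling if the timebases differ).
#' @return An `agreement` object (list) with `slope`, `intercept`,
#'   `correlation`, `mean_error_pct`, `sd_error_pct`, `bias`, `loa_lower`,
#'   `loa_upper`, `n`.
#' @export
compare_angle_series <- function(test, reference) {
  stopifnot(length(test) == length(reference))
  if (stats::sd(reference) < .Machine$double.eps)
    stop("degenerate reference series: zero variance")
  fit <- stats::lm(test ~ reference)
  d <- test - reference
  rel <- abs(d) / diff(range(reference)) * 100
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 correlation = stats::cor(test, reference),
                 mean_error_pct = mean(rel),
                 sd_error_pct = stats::sd(rel),
                 bias = mean(d),
                 loa_lower = mean(d) - 1.96 * stats::sd(d),
                 loa_upper = mean(d) + 1.96 * stats::sd(d),
                 n = length(d),
                 differences = d, means = (test + reference) / 2),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat("<agreement> n =", x$n, "\n")
  cat(sprintf("  fit      : slope %.4f, intercept %.4f, r %.4f\n",
              x$slope, x$intercept, x$correlation))
  cat(sprintf("  rel error: %.2f +/- %.2f %%\n", x$mean_error_pct, x$sd_error_pct))
  cat(sprintf("  Bland-Altman: bias %.4f, LoA [%.4f, %.4f]\n",
              x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}
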