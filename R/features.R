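#' Sliding-window segmentation
#'
#' Divides a sample sequence into fixed-length windows starting every
#' `length - overlap` samples; only complete windows are emitted. The
#' defaults (10-sample windows, 5-sample overlap) are the segmentation used
#' for propulsion/recovery phase analysis.
#'
#' @param x Numeric vector.
#' @param length Window length in samples (default 10).
#' @param overlap Overlap between consecutive windows in samples
#'   (default 5); must satisfy `0 <= overlap < length`.
#' @return List of numeric windows, with attribute `starts` (1-based start
#'   indices). Zero windows if `x` is shorter than `length`.
#' @export
#' @examples
#' length(sliding_windows(1:20))  # 3 windows starting at samples 1, 6, 11
sliding_windows <- function(x, length = 10, overlap = 5) {
  stopifnot(length >= 1, overlap >= 0, overlap < length)
  step <- length - overlap
  n <- base::length(x)
  if (n < length) {
    out <- list()
    attr(out, "starts") <- integer(0)
    return(out)
  }
  starts <- seq(1L, n - length + 1L, by = step)
  out <- lapply(starts, function(s) x[s:(s + length - 1L)])
  attr(out, "starts") <- starts
  out
}

# fixed order of the 33 per-channel features
feature_names <- function() {
  c("mean", "median", "std", "mad", "quantile1", "quantile2", "iqr",
    "skewness", "kurtosis", "var", "sigentropy", "sepentropy",
    paste0("powersp", 1:3), paste0("acorr", 1:3), paste0("spwf", 1:15))
}

#' Extract the standard 33-feature vector from a signal segment
#'
#' Time-domain statistics (mean, median, SD, median absolute deviation,
#' 25th/75th percentiles, IQR, moment skewness, excess kurtosis, variance),
#' signal entropy (Shannon entropy of a 16-bin amplitude histogram),
#' spectral entropy (Shannon entropy of the normalized one-sided power
#' spectrum of the demeaned segment), three power-spectrum features (total
#' power, peak power, peak frequency in Hz), normalized autocorrelation at
#' lags 1-3, and relative spectral power in 15 equal-width bands from 0 to
#' the Nyquist frequency. Degenerate (constant) segments yield zeros for
#' the dispersion, entropy and spectral features rather than NaN.
#'
#' @param x Numeric segment (length >= 2).
#' @param sample_rate Sampling rate in Hz (default 100); only the
#'   frequency-valued features depend on it.
#' @return Named numeric vector of exactly 33 features, in fixed order.
#' @export
extract_features <- function(x, sample_rate = 100) {
  n <- length(x)
  stopifnot(n >= 2)
  m <- mean(x)
  v <- stats::var(x)
  ctr <- x - m
  q <- unname(stats::quantile(x, c(0.25, 0.75)))
  out <- c(mean = m, median = stats::median(x), std = sqrt(v),
           mad = stats::median(abs(x - stats::median(x))),
           quantile1 = q[1], quantile2 = q[2], iqr = q[2] - q[1],
           skewness = 0, kurtosis = 0, var = v,
           sigentropy = 0, sepentropy = 0,
           powersp1 = 0, powersp2 = 0, powersp3 = 0,
           acorr1 = 0, acorr2 = 0, acorr3 = 0)
  m2 <- mean(ctr^2)
  if (m2 > .Machine$double.eps^2) {
    out["skewness"] <- mean(ctr^3) / m2^1.5
    out["kurtosis"] <- mean(ctr^4) / m2^2 - 3
    denom <- sum(ctr^2)
    for (k in 1:3)
      if (n > k) out[paste0("acorr", k)] <-
        sum(ctr[1:(n - k)] * ctr[(k + 1):n]) / denom
    # 16-bin amplitude histogram entropy
    h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = 17),
                        plot = FALSE)$counts
    p <- h[h > 0] / n
    out["sigentropy"] <- -sum(p * log(p))
  }
  # one-sided power spectrum of the demeaned segment
  nf <- floor(n / 2)
  spw <- numeric(15)
  if (nf >= 1) {
    sp <- stats::fft(ctr)
    P <- Mod(sp[2:(nf + 1)])^2
    freqs <- (1:nf) * sample_rate / n
    tot <- sum(P)
    if (tot > .Machine$double.eps^2) {
      out["powersp1"] <- tot
      out["powersp2"] <- max(P)
      out["powersp3"] <- freqs[which.max(P)]
      pp <- P[P > 0] / tot
      out["sepentropy"] <- -sum(pp * log(pp))
      ny <- sample_rate / 2
      band <- pmin(ceiling(freqs / (ny / 15)), 15)
      for (b in seq_len(15)) spw[b] <- sum(P[band == b]) / tot
    }
  }
  names(spw) <- paste0("spwf", 1:15)
  c(out, spw)[feature_names()]
}

#' Build a per-record feature matrix from joint-angle series
#'
#' Applies [extract_features()] to each record of each requested channel
#' and binds the results into one row per record with channel-prefixed,
#' stably ordered column names (`SFl_mean, ..., EFr_spwf15`). Records are
#' either fixed sliding windows (`mode = "windows"`, default 10/5) or
#' complete stroke cycles delimited by [detect_cycles()] events
#' (`mode = "strokes"`).
#'
#' @param angles Joint-angle tibble (`t` + channel columns).
#' @param channels Channels to featurize (default the four upper-limb
#'   flexion channels present).
#' @param mode `"windows"` or `"strokes"`.
#' @param window_length,window_overlap Sliding-window parameters (samples).
#' @param events [detect_cycles()] result, required for
#'   `mode = "strokes"`.
#' @param sample_rate Hz; inferred from `t` when `NULL`.
#' @return Tibble with meta columns `record, t_start, t_end` followed by
#'   `length(channels) * 33` feature columns (132 for four channels).
#'   Empty (with header) when no complete record fits.
#' @export
build_feature_matrix <- function(angles, channels = NULL,
                                 mode = c("windows", "strokes"),
                                 window_length = 10, window_overlap = 5,
                                 events = NULL, sample_rate = NULL) {
  mode <- match.arg(mode)
  if (is.null(channels))
    channels <- intersect(c("SFl", "SFr", "EFl", "EFr"), names(angles))
  missing <- setdiff(channels, names(angles))
  if (length(missing))
    stop("channels not present in series: ", paste(missing, collapse = ", "))
  if (is.null(sample_rate))
    sample_rate <- 1 / stats::median(diff(angles$t))

  if (mode == "windows") {
    idx <- sliding_windows(seq_len(nrow(angles)), window_length, window_overlap)
  } else {
    if (is.null(events)) stop("mode = 'strokes' requires detect_cycles() events")
    b <- events$boundary_times
    idx <- list()
    if (length(b) >= 2)
      for (k in seq_len(length(b) - 1)) {
        sel <- which(angles$t >= b[k] & angles$t < b[k + 1])
        if (length(sel) >= 3) idx[[length(idx) + 1L]] <- sel
      }
  }

  feat_cols <- as.vector(t(outer(channels, feature_names(), paste, sep = "_")))
  if (!length(idx)) {
    empty <- c(list(record = integer(0), t_start = numeric(0), t_end = numeric(0)),
               stats::setNames(rep(list(numeric(0)), length(feat_cols)), feat_cols))
    return(tibble::as_tibble(empty))
  }
  rows <- lapply(seq_along(idx), function(r) {
    sel <- idx[[r]]
    vals <- unlist(lapply(channels, function(ch)
      stats::setNames(extract_features(angles[[ch]][sel], sample_rate),
                      paste0(ch, "_", feature_names()))))
    tibble::as_tibble(c(list(record = r, t_start = angles$t[sel[1]],
                             t_end = angles$t[sel[length(sel)]]),
                        as.list(vals)))
  })
  dplyr::bind_rows(rows)[, c("record", "t_start", "t_end", feat_cols)]
}

#' Phase labels for feature-matrix records
#'
#' Majority-vote phase label of each record from per-sample ground-truth or
#' annotated phases.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param phase Tibble `t, phase` with per-sample phase strings.
#' @return Character vector, one label per record row.
#' @export
label_records <- function(fm, phase) {
  vapply(seq_len(nrow(fm)), function(i) {
    sel <- phase$t >= fm$t_start[i] & phase$t <= fm$t_end[i]
    ph <- phase$phase[sel]
    ph <- ph[!is.na(ph)]
    if (!length(ph)) return(NA_character_)
    names(which.max(table(ph)))
  }, character(1))
}
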