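#' Remove missing and out-of-bound samples
#'
#' Wearable sensors report a data point completely outside the sensor's
#' physical range (a sentinel, e.g. 65535) to represent a missing value;
#' such samples, and records with `NA` values, are removed rather than
#' imputed. Valid ranges are closed intervals: a value exactly at a range
#' limit is a legitimate saturated reading and is kept. Surviving records
#' keep their original relative order.
#'
#' @param stream A [sensor_stream()].
#' @param ranges Named list of `c(min, max)` per channel; every channel
#'   present in the stream must have a declared range.
#' @return List with `stream` (the cleaned stream) and `report` (a
#'   `clean_report` data frame with per-channel counts `n_input`, `n_kept`,
#'   `n_removed_out_of_bound`, `n_removed_missing` and a `removed_t`
#'   list-column of removed timestamps; counts always reconcile).
#' @export
remove_invalid <- function(stream, ranges = default_channel_ranges()) {
  stream <- as_sensor_stream(as.data.frame(stream))
  chans <- unique(stream$channel)
  undeclared <- setdiff(chans, names(ranges))
  if (length(undeclared) > 0L)
    stop("no valid range declared for channel(s): ",
         paste(sQuote(undeclared), collapse = ", "))
  k <- sensor_channels()[stream$channel]
  missing_rec <- is.na(stream$v1) | (k >= 2L & is.na(stream$v2)) |
    (k >= 3L & is.na(stream$v3))
  lo <- vapply(ranges, `[`, numeric(1L), 1L)[stream$channel]
  hi <- vapply(ranges, `[`, numeric(1L), 2L)[stream$channel]
  # unused trailing components take the in-range placeholder `lo`
  vals <- cbind(stream$v1, ifelse(k >= 2L, stream$v2, lo),
                ifelse(k >= 3L, stream$v3, lo))
  oob <- !missing_rec & (vals[, 1L] < lo | vals[, 1L] > hi |
                           vals[, 2L] < lo | vals[, 2L] > hi |
                           vals[, 3L] < lo | vals[, 3L] > hi)
  keep <- !missing_rec & !oob
  rep_df <- do.call(rbind, lapply(chans, function(ch) {
    i <- stream$channel == ch
    data.frame(channel = ch, n_input = sum(i), n_kept = sum(i & keep),
               n_removed_out_of_bound = sum(i & oob),
               n_removed_missing = sum(i & missing_rec))
  }))
  rep_df$removed_t <- lapply(chans, function(ch)
    stream$t[stream$channel == ch & !keep])
  class(rep_df) <- c("clean_report", "data.frame")
  out <- stream[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sensor_stream", "data.frame")
  list(stream = out, report = rep_df)
}

#' @export
print.clean_report <- function(x, ...) {
  cat("stream cleaning report\n")
  print.data.frame(x[, c("channel", "n_input", "n_kept",
                         "n_removed_out_of_bound", "n_removed_missing")],
                   row.names = FALSE)
  invisible(x)
}

#' Moving-window smoothing of a stream
#'
#' Replaces each sample by the arithmetic mean of the samples of the same
#' subject/channel in the trailing half-open window `(t - window_s, t]`.
#' The window is trailing (causal), consistent with real-time operation;
#' output timestamps are unchanged, and a sample alone in its window is
#' returned as-is.
#'
#' @param stream A time-sorted [sensor_stream()].
#' @param window_s Window length in seconds (> 0; default 6).
#' @param channels Channels to smooth (default: all present).
#' @return The smoothed stream.
#' @export
smooth_stream <- function(stream, window_s = 6, channels = NULL) {
  if (!is.numeric(window_s) || length(window_s) != 1L || !(window_s > 0))
    stop("smoothing window must be a positive number of seconds")
  stream <- as_sensor_stream(as.data.frame(stream))
  if (is.null(channels)) channels <- unique(stream$channel)
  key <- paste(stream$subject, stream$channel)
  for (g in unique(key[stream$channel %in% channels])) {
    i <- which(key == g)
    t <- stream$t[i]
    # first index inside (t - window_s, t]; t sorted, so cumulative sums
    # give O(n log n) trailing means
    first <- findInterval(t - window_s, t) + 1L
    for (col in c("v1", "v2", "v3")) {
      v <- stream[[col]][i]
      if (all(is.na(v))) next
      cs <- cumsum(v)
      sums <- cs - c(0, cs)[first]
      stream[[col]][i] <- sums / (seq_along(v) - first + 1L)
    }
  }
  stream
}

#' Baseline-deviation scaling
#'
#' Increases sensitivity to departures from a baseline by an affine gain
#' about that baseline: `v -> baseline + gain * (v - baseline)`. A gain of
#' 1 is the identity (scaling off); the baseline itself is a fixed point
#' for any gain.
#'
#' @param v Numeric values.
#' @param baseline Finite scalar baseline.
#' @param gain Non-negative scalar gain (default 1).
#' @return Scaled values.
#' @export
baseline_scale <- function(v, baseline, gain = 1) {
  if (!is.numeric(baseline) || length(baseline) != 1L || !is.finite(baseline))
    stop("baseline must be a finite scalar")
  if (!is.numeric(gain) || length(gain) != 1L || is.na(gain) || gain < 0)
    stop("gain must be non-negative")
  baseline + gain * (v - baseline)
}

#' Clean, calibrate and smooth a raw stream
#'
#' The standard preprocessing chain applied before feature extraction:
#' out-of-bound/missing removal against the profile's channel ranges,
#' dust-voltage calibration to dust density, then 6-s trailing-mean
#' smoothing of the environmental channels (dust density, particulate
#' matter, temperature, humidity). Accelerometer and heart-rate samples
#' are left unsmoothed: the activity statistic is a within-window variance
#' and smoothing would suppress it.
#'
#' @param stream A raw [sensor_stream()].
#' @param profile A [subject_profile()] supplying channel ranges.
#' @param coeffs Dust [dust_coefficients()].
#' @param smooth_window_s Smoothing window, seconds (default 6).
#' @return List with `stream` (processed) and `report` (clean report).
#' @export
preprocess_stream <- function(stream, profile = subject_profile(),
                              coeffs = dust_coefficients(),
                              smooth_window_s = 6) {
  cleaned <- remove_invalid(stream, profile$channel_ranges)
  cal <- calibrate_dust_stream(cleaned$stream, coeffs)
  sm <- smooth_stream(cal, window_s = smooth_window_s,
                      channels = c("dust_density", "pm25",
                                   "temperature", "humidity"))
  list(stream = sm, report = cleaned$report)
}
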