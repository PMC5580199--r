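#' The 16 risk-model feature names, in declared order
#'
#' Order is part of the model contract: serialized feature tables and model
#' bundles both use it, and prediction refuses mismatched order.
#'
#' @return Character vector of length 16.
#' @export
feature_names <- function() {
  c("percent_fev1", "percent_pef", "dust_density", "particulate_matter",
    "temperature", "humidity", "heart_rate_reserve",
    "total_energy_expenditure", online_feature_names())
}

#' Composite acceleration statistic Km
#'
#' Activity/energy-expenditure proxy for a short tri-axial accelerometer
#' window: with `Q` the sum of squared samples over all three axes and `P`
#' the sum of the squared per-axis sums, `Km = (Q - P/n) / (n - 1)` — the
#' summed per-axis sample variance. `as_printed = TRUE` switches to the
#' degenerate reading with `P = Q` (then `Km = Q/n`), kept for audit;
#' `sqrt_norm = TRUE` returns the square root.
#'
#' @param samples Numeric n x 3 matrix (or data frame) of x, y, z readings,
#'   n >= 2.
#' @param as_printed Use the literal degenerate `P = Q` reading.
#' @param sqrt_norm Return `sqrt(Km)`.
#' @return Non-negative scalar.
#' @export
composite_accel_km <- function(samples, as_printed = FALSE, sqrt_norm = FALSE) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("accel samples must have three columns (x, y, z)")
  n <- nrow(samples)
  if (n < 2L) stop("composite acceleration needs at least 2 samples")
  if (any(!is.finite(samples))) stop("accel samples must be finite")
  q <- sum(samples^2)
  p <- if (as_printed) q else sum(colSums(samples)^2)
  km <- (q - p / n) / (n - 1)
  km <- max(km, 0)  # guard tiny negative rounding
  if (sqrt_norm) sqrt(km) else km
}

#' Total energy expenditure over a classification window
#'
#' Partitions the window into complete 5-s sub-windows, computes the
#' composite acceleration Km in each sub-window holding at least two
#' samples, and aggregates (mean by default; `aggregate = "sum"` available).
#'
#' @param t Accelerometer timestamps (seconds), sorted.
#' @param xyz n x 3 matrix of accelerometer samples matching `t`.
#' @param window `c(start, end)` half-open window bounds `[start, end)`.
#' @param subwindow_s Sub-window length, seconds (default 5).
#' @param aggregate `"mean"` (default) or `"sum"` over sub-window Km values.
#' @param ... Passed to [composite_accel_km()].
#' @return Scalar, or `NA_real_` when no sub-window holds enough samples
#'   (missing-feature flag).
#' @export
energy_expenditure <- function(t, xyz, window, subwindow_s = 5,
                               aggregate = c("mean", "sum"), ...) {
  aggregate <- match.arg(aggregate)
  xyz <- as.matrix(xyz)
  inside <- t >= window[1L] & t < window[2L]
  if (!any(inside)) return(NA_real_)
  t <- t[inside]
  xyz <- xyz[inside, , drop = FALSE]
  n_sub <- floor((window[2L] - window[1L]) / subwindow_s)
  if (n_sub < 1L) stop("window shorter than one accel sub-window")
  sub <- floor((t - window[1L]) / subwindow_s)
  kms <- vapply(seq_len(n_sub) - 1L, function(s) {
    i <- sub == s
    if (sum(i) < 2L) return(NA_real_)
    composite_accel_km(xyz[i, , drop = FALSE], ...)
  }, numeric(1L))
  kms <- kms[!is.na(kms)]
  if (length(kms) == 0L) return(NA_real_)
  if (aggregate == "mean") mean(kms) else sum(kms)
}

#' Age-predicted maximum heart rate
#'
#' `HRmax = 208 - 0.7 * age`, the age-based estimate suited to children
#' as well as adults.
#'
#' @param age Years.
#' @return bpm.
#' @export
hr_max <- function(age) 208 - 0.7 * age

#' Heart rate reserve
#'
#' `HRR = HRmax - HRrest`: the bpm span between the resting and the
#' age-predicted maximum heart rate. A per-subject constant.
#'
#' @param age Years, > 0.
#' @param hr_rest Resting heart rate, bpm, > 0.
#' @return bpm.
#' @export
hr_reserve <- function(age, hr_rest) {
  hrr <- hr_max(age) - hr_rest
  if (any(hrr <= 0))
    stop("heart rate reserve must be positive; check age and resting HR")
  hrr
}

#' Fraction of heart rate reserve in use
#'
#' The per-window heart-rate feature: `(mean window HR - HRrest) / HRR`,
#' clipped to [0, 1.5]. 0 means at rest, 1 means at the age-predicted
#' maximum; values slightly above 1 can occur and are retained up to 1.5.
#'
#' @param profile A [subject_profile()].
#' @param hr_window_mean Mean heart rate over the window, bpm.
#' @return Dimensionless fraction in [0, 1.5], `NA` for `NA` input.
#' @export
hr_reserve_fraction <- function(profile, hr_window_mean) {
  hrr <- hr_reserve(profile$age, profile$hr_rest)
  pmin(pmax((hr_window_mean - profile$hr_rest) / hrr, 0), 1.5)
}

#' Spirometry percent of personal baseline
#'
#' `100 * current / mean(baseline triplet)`, the percent-of-personal-best
#' convention used in asthma management plans.
#'
#' @param current Current PEF (L/min) or FEV1 (L) reading.
#' @param baseline_triplet The three at-rest baseline measurements.
#' @return Percent (100 = at personal baseline).
#' @export
percent_of_baseline <- function(current, baseline_triplet) {
  if (length(baseline_triplet) != 3L || any(!is.finite(baseline_triplet)))
    stop("baseline triplet must hold three finite values")
  m <- mean(baseline_triplet)
  if (m <= 0) stop("baseline mean must be positive")
  100 * current / m
}

#' Classification windows over a time span
#'
#' Half-open windows `[start, start + width)` tiled from `from`; only
#' complete windows ending at or before `to` are returned.
#'
#' @param from,to Span bounds, epoch seconds.
#' @param width_s Window length, seconds (default 60).
#' @param hop_s Hop between window starts (default `width_s`).
#' @return Data frame with columns `window_start`, `window_end`.
#' @export
make_windows <- function(from, to, width_s = 60, hop_s = width_s) {
  stopifnot(width_s > 0, hop_s > 0, to >= from + width_s)
  starts <- seq(from, to - width_s, by = hop_s)
  data.frame(window_start = starts, window_end = starts + width_s)
}

# split a preprocessed stream by channel with sorted times, for fast
# per-window slicing
split_channels <- function(stream) {
  lapply(split(stream[c("t", "v1", "v2", "v3")], stream$channel),
         function(d) d[order(d$t), , drop = FALSE])
}

window_mean <- function(chan_df, window) {
  if (is.null(chan_df)) return(NA_real_)
  i1 <- findInterval(window[1L], chan_df$t, left.open = TRUE) + 1L
  i2 <- findInterval(window[2L], chan_df$t, left.open = TRUE)
  if (i2 < i1) return(NA_real_)
  mean(chan_df$v1[i1:i2])
}

locf_value <- function(chan_df, at, max_age_s = Inf) {
  if (is.null(chan_df) || nrow(chan_df) == 0L) return(NA_real_)
  i <- findInterval(at, chan_df$t)
  if (i == 0L || at - chan_df$t[i] > max_age_s) return(NA_real_)
  chan_df$v1[i]
}

#' Build the 16-entry feature vector for one window
#'
#' Environmental and heart-rate channels are summarized by their mean over
#' the half-open window; acceleration becomes the mean Km over complete 5-s
#' sub-windows; spirometry features carry the last observation at or before
#' the window end (spirometry is episodic), up to a staleness horizon, as
#' percent of the profile baseline; online-source features are copied from
#' the row joined to the window end. Features that cannot be computed are
#' `NA` (flagged missing), never zero-filled.
#'
#' @param stream A preprocessed [sensor_stream()] (see
#'   [preprocess_stream()]): dust already calibrated to `dust_density`.
#' @param profile A [subject_profile()].
#' @param online_row One row of an online table joined to this window (or
#'   `NULL`: online features missing).
#' @param window `c(start, end)`, half-open.
#' @param spiro_max_age_s Staleness horizon for spirometry carry-forward,
#'   seconds (default 24 h).
#' @param ... Passed to [energy_expenditure()].
#' @return One-row data frame: `window_start`, `window_end`, then the 16
#'   features of [feature_names()] in declared order.
#' @export
build_feature_vector <- function(stream, profile, online_row, window,
                                 spiro_max_age_s = 86400, ...) {
  chans <- split_channels(as_sensor_stream(as.data.frame(stream)))
  build_feature_vector_split(chans, profile, online_row, window,
                             spiro_max_age_s = spiro_max_age_s, ...)
}

build_feature_vector_split <- function(chans, profile, online_row, window,
                                       spiro_max_age_s = 86400, ...) {
  in_window <- function(d) !is.null(d) &&
    any(d$t >= window[1L] & d$t < window[2L])
  if (!any(vapply(chans, in_window, logical(1L))) &&
      is.na(locf_value(chans$pef, window[2L], spiro_max_age_s)) &&
      is.na(locf_value(chans$fev1, window[2L], spiro_max_age_s)))
    stop(sprintf("no sensor data in window [%s, %s)",
                 format(window[1L]), format(window[2L])))
  hr_mean <- window_mean(chans$heart_rate, window)
  tee <- if (is.null(chans$accel)) NA_real_ else
    energy_expenditure(chans$accel$t,
                       as.matrix(chans$accel[c("v1", "v2", "v3")]),
                       window, ...)
  pef_last <- locf_value(chans$pef, window[2L], spiro_max_age_s)
  fev1_last <- locf_value(chans$fev1, window[2L], spiro_max_age_s)
  fv <- data.frame(
    window_start = window[1L], window_end = window[2L],
    percent_fev1 = if (is.na(fev1_last)) NA_real_ else
      percent_of_baseline(fev1_last, profile$baseline_fev1),
    percent_pef = if (is.na(pef_last)) NA_real_ else
      percent_of_baseline(pef_last, profile$baseline_pef),
    dust_density = window_mean(chans$dust_density, window),
    particulate_matter = window_mean(chans$pm25, window),
    temperature = window_mean(chans$temperature, window),
    humidity = window_mean(chans$humidity, window),
    heart_rate_reserve = if (is.na(hr_mean)) NA_real_ else
      hr_reserve_fraction(profile, hr_mean),
    total_energy_expenditure = tee)
  for (nm in online_feature_names())
    fv[[nm]] <- if (is.null(online_row)) NA_real_ else
      as.numeric(online_row[[nm]])
  fv
}

#' Extract feature vectors for a set of windows
#'
#' Vectorized driver around [build_feature_vector()]: splits the stream by
#' channel once, joins the online table to window end-times by last
#' observation carried forward, and emits one feature row per window.
#'
#' @param stream A preprocessed [sensor_stream()].
#' @param profile A [subject_profile()].
#' @param online An online table ([as_online_table()]) or `NULL`.
#' @param windows Data frame from [make_windows()].
#' @param ... Passed to [build_feature_vector()].
#' @return Data frame, one row per window, 18 columns.
#' @export
extract_features <- function(stream, profile, online, windows, ...) {
  chans <- split_channels(as_sensor_stream(as.data.frame(stream)))
  joined <- if (is.null(online)) NULL else
    join_online_features(windows$window_end, online)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    build_feature_vector_split(
      chans, profile,
      if (is.null(joined)) NULL else joined[i, , drop = FALSE],
      c(windows$window_start[i], windows$window_end[i]), ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
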