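#' Sensor channels understood by the pipeline
#'
#' The wearable kit emits nine channels: raw dust-sensor voltage, PM2.5,
#' temperature, humidity, peak expiratory flow (PEF), forced expiratory
#' volume in one second (FEV1), tri-axial acceleration, heart rate and GPS
#' location. A gyroscope channel is accepted on input (the watch records it)
#' but is ignored by the feature stage. `dust_density` is the derived
#' channel produced by [calibrate_dust_stream()].
#'
#' @return Named integer vector mapping channel name to its number of value
#'   components (1 for scalars, 2 for location, 3 for accel/gyro).
#' @export
sensor_channels <- function() {
  c(dust_raw = 1L, pm25 = 1L, temperature = 1L, humidity = 1L,
    pef = 1L, fev1 = 1L, accel = 3L, heart_rate = 1L,
    location = 2L, gyro = 3L, dust_density = 1L)
}

#' Build a sensor stream
#'
#' A sensor stream is a data frame with columns `subject`, `channel`, `t`
#' (UTC epoch seconds), and value components `v1`, `v2`, `v3` (`v2`/`v3`
#' are `NA` for scalar channels). Records are kept sorted by `t` with a
#' stable order for ties.
#'
#' @param subject Subject identifier (recycled).
#' @param channel Channel name, one of [sensor_channels()] (recycled).
#' @param t Numeric timestamps, seconds since epoch, finite and >= 0.
#' @param value Numeric vector (scalar channels) or matrix with one row per
#'   record and as many columns as the channel has components.
#' @return A `sensor_stream` data frame sorted by time.
#' @export
sensor_stream <- function(subject, channel, t, value) {
  value <- if (is.matrix(value)) value else matrix(as.numeric(value), ncol = 1L)
  n <- max(length(t), nrow(value))
  df <- data.frame(
    subject = rep_len(as.character(subject), n),
    channel = rep_len(as.character(channel), n),
    t = rep_len(as.numeric(t), n),
    v1 = rep_len(value[, 1L], n),
    v2 = if (ncol(value) >= 2L) rep_len(value[, 2L], n) else NA_real_,
    v3 = if (ncol(value) >= 3L) rep_len(value[, 3L], n) else NA_real_,
    stringsAsFactors = FALSE
  )
  as_sensor_stream(df)
}

#' Validate and normalize a stream data frame
#'
#' Checks the stream invariants: known channel names, finite non-negative
#' timestamps, and the right number of value components per channel
#' (accel/gyro carry three, location two, everything else one). `NA` values
#' in the leading components are allowed (they denote missing samples and
#' are handled by [remove_invalid()]), but trailing components must be `NA`
#' exactly when the channel does not use them.
#'
#' @param df Data frame with columns subject, channel, t, v1, v2, v3.
#' @return The stream, time-sorted (stable), with class `sensor_stream`.
#' @export
as_sensor_stream <- function(df) {
  need <- c("subject", "channel", "t", "v1", "v2", "v3")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("stream is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[need]
  chans <- sensor_channels()
  bad <- setdiff(unique(df$channel), names(chans))
  if (length(bad) > 0L)
    stop("unknown channel name(s): ", paste(sQuote(bad), collapse = ", "))
  if (any(!is.finite(df$t)) || any(df$t < 0))
    stop("timestamps must be finite and non-negative")
  k <- chans[df$channel]
  if (any(k < 3L & !is.na(df$v3)))
    stop("scalar/2-component channels must not carry v3")
  if (any(k < 2L & !is.na(df$v2)))
    stop("scalar channels must not carry v2")
  if (any(k >= 2L & is.na(df$v2) & !is.na(df$v1)))
    stop("multi-component channels must carry all components")
  if (any(k >= 3L & is.na(df$v3) & !is.na(df$v1)))
    stop("3-component channels must carry all components")
  df <- df[order(df$t), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sensor_stream", "data.frame")
  df
}

parse_stream_lines <- function(lines, format) {
  n <- length(lines)
  out <- vector("list", n)
  bad <- list()
  for (i in seq_len(n)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    rec <- tryCatch({
      if (format == "jsonl") {
        x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
        if (is.null(x$subject) || is.null(x$channel) || is.null(x$t) ||
            is.null(x$value))
          stop("record needs fields subject, channel, t, value")
        v <- suppressWarnings(as.numeric(x$value))
        if (any(is.na(v) & !is.na(x$value)) || length(v) < 1L)
          stop("non-numeric value: ", sQuote(paste(x$value, collapse = ",")))
        list(subject = as.character(x$subject),
             channel = as.character(x$channel),
             t = as.numeric(x$t), v = v)
      } else {
        f <- strsplit(ln, ",", fixed = TRUE)[[1L]]
        length(f) <- 6L
        f[is.na(f)] <- ""
        v <- suppressWarnings(as.numeric(f[4:6]))
        raw_nonempty <- nzchar(trimws(f[4:6]))
        if (any(is.na(v) & raw_nonempty))
          stop("non-numeric value: ",
               sQuote(paste(f[4:6][is.na(v) & raw_nonempty], collapse = ",")))
        tt <- suppressWarnings(as.numeric(f[3L]))
        if (is.na(tt)) stop("non-numeric timestamp: ", sQuote(f[3L]))
        list(subject = f[1L], channel = f[2L], t = tt,
             v = v[raw_nonempty])
      }
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      bad[[length(bad) + 1L]] <- data.frame(line = i, reason = conditionMessage(rec))
      next
    }
    chans <- sensor_channels()
    if (!rec$channel %in% names(chans)) {
      bad[[length(bad) + 1L]] <- data.frame(
        line = i, reason = paste0("unknown channel name: ", sQuote(rec$channel)))
      next
    }
    k <- chans[[rec$channel]]
    if (length(rec$v) != k || any(is.na(rec$v) & FALSE)) {
      bad[[length(bad) + 1L]] <- data.frame(
        line = i,
        reason = sprintf("channel %s expects %d value component(s), got %d",
                         sQuote(rec$channel), k, length(rec$v)))
      next
    }
    out[[i]] <- data.frame(
      subject = rec$subject, channel = rec$channel, t = rec$t,
      v1 = rec$v[1L],
      v2 = if (k >= 2L) rec$v[2L] else NA_real_,
      v3 = if (k >= 3L) rec$v[3L] else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(records = out[!vapply(out, is.null, logical(1L))],
       bad = if (length(bad)) do.call(rbind, bad)
             else data.frame(line = integer(), reason = character()))
}

#' Read a sensor stream file
#'
#' Reads CSV (columns `subject,channel,t,v1,v2,v3`, header required) or
#' JSON-lines (one object `{"subject","channel","t","value"}` per line,
#' value scalar or array). Records are returned sorted by timestamp with a
#' stable order for ties.
#'
#' @param path File to read.
#' @param format `"csv"` or `"jsonl"`.
#' @param on_error `"stop"` (default) aborts on the first malformed line,
#'   naming the line number and offending token; `"report"` skips malformed
#'   lines and attaches them as the `"bad_lines"` attribute (a data frame
#'   with columns `line`, `reason`), so that parsed + reported lines always
#'   account for every input line.
#' @return A [sensor_stream()] data frame.
#' @export
read_stream <- function(path, format = c("csv", "jsonl"),
                        on_error = c("stop", "report")) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "csv" && length(lines) > 0L &&
      grepl("^subject,channel,t", lines[[1L]]))
    lines <- lines[-1L]
  res <- parse_stream_lines(lines, format)
  if (on_error == "stop" && nrow(res$bad) > 0L)
    stop(sprintf("line %d: %s", res$bad$line[1L], res$bad$reason[1L]))
  df <- if (length(res$records)) do.call(rbind, res$records) else
    data.frame(subject = character(), channel = character(), t = numeric(),
               v1 = numeric(), v2 = numeric(), v3 = numeric())
  out <- as_sensor_stream(df)
  attr(out, "bad_lines") <- res$bad
  out
}

#' Write a sensor stream file
#'
#' Writes records in time order (stable sort) in a format [read_stream()]
#' can read back verbatim. JSON-lines output carries one record per line.
#'
#' @param records A [sensor_stream()] (or coercible data frame).
#' @param path Output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  records <- as_sensor_stream(as.data.frame(records))
  k <- sensor_channels()[records$channel]
  lines <- if (format == "jsonl") {
    vapply(seq_len(nrow(records)), function(i) {
      v <- c(records$v1[i], records$v2[i], records$v3[i])[seq_len(k[i])]
      jsonlite::toJSON(
        list(subject = records$subject[i], channel = records$channel[i],
             t = records$t[i],
             value = if (length(v) == 1L) jsonlite::unbox(v) else v),
        auto_unbox = TRUE, digits = NA)
    }, character(1L))
  } else {
    num <- function(x) ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE,
                                                   scientific = FALSE))
    c("subject,channel,t,v1,v2,v3",
      paste(records$subject, records$channel,
            num(records$t), num(records$v1), num(records$v2), num(records$v3),
            sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Validate an online-source feature table
#'
#' Online sources (replayed from a fixture, never fetched live) supply per
#' timestamp: ozone, barometric pressure, cloud cover, wind speed,
#' precipitation probability and intensity, traffic density and the Air
#' Quality Index.
#'
#' @param df Data frame with columns `t, ozone, pressure, cloud_cover,
#'   wind_speed, precip_probability, precip_intensity, traffic_density, aqi`.
#' @return The validated table (strictly increasing `t`).
#' @export
as_online_table <- function(df) {
  need <- c("t", online_feature_names())
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("online table is missing columns: ", paste(miss, collapse = ", "))
  df <- df[need]
  if (nrow(df) == 0L) stop("online table must be non-empty")
  if (any(!is.finite(df$t)) || is.unsorted(df$t, strictly = TRUE))
    stop("online table timestamps must be finite and strictly increasing")
  for (nm in need) df[[nm]] <- as.numeric(df[[nm]])
  rownames(df) <- NULL
  df
}

#' @rdname as_online_table
#' @param path CSV file with the header named above.
#' @export
read_online_table <- function(path) {
  as_online_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The eight online-source feature names, in feature-vector order
#' @export
online_feature_names <- function() {
  c("ozone", "pressure", "cloud_cover", "wind_speed",
    "precip_probability", "precip_intensity", "traffic_density", "aqi")
}

#' Align online features to window end-times
#'
#' Each requested time is matched to the most recent table row at or before
#' it (last observation carried forward). A time earlier than the first
#' table row has no defensible value and is an error.
#'
#' @param times Numeric vector of window end-times (epoch seconds).
#' @param table An [as_online_table()] table.
#' @return Data frame with one row per element of `times` (the original
#'   `t` column holds the matched row's timestamp).
#' @export
join_online_features <- function(times, table) {
  table <- as_online_table(table)
  idx <- findInterval(times, table$t)
  if (any(idx == 0L))
    stop("window time(s) earlier than first online row: ",
         paste(format(times[idx == 0L]), collapse = ", "))
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subject profile
#'
#' Per-subject constants used by the feature stage: age (drives the
#' age-predicted maximum heart rate 208 - 0.7*age), resting heart rate, the
#' three at-rest baseline spirometry measurements (personal best reference),
#' and the physically valid range per channel (used to drop out-of-bound
#' sentinel samples).
#'
#' @param subject_id Opaque identifier.
#' @param age Years, > 0.
#' @param hr_rest Resting heart rate, bpm, > 0.
#' @param baseline_pef Three at-rest PEF measurements (L/min), all > 0.
#' @param baseline_fev1 Three at-rest FEV1 measurements (L), all > 0.
#' @param channel_ranges Named list of `c(min, max)` closed valid ranges.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(subject_id = "s1", age = 29, hr_rest = 60,
                            baseline_pef = c(310, 320, 330),
                            baseline_fev1 = c(3.0, 3.1, 3.2),
                            channel_ranges = default_channel_ranges()) {
  stopifnot(is.numeric(age), length(age) == 1L, is.finite(age), age > 0,
            is.numeric(hr_rest), length(hr_rest) == 1L, hr_rest > 0)
  for (tri in list(baseline_pef, baseline_fev1))
    if (length(tri) != 3L || any(!is.finite(tri)) || any(tri <= 0))
      stop("baseline spirometry triplets must hold exactly three strictly positive values")
  for (nm in names(channel_ranges)) {
    r <- channel_ranges[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] >= r[2L])
      stop("channel range for ", sQuote(nm), " must satisfy min < max")
  }
  structure(list(subject_id = as.character(subject_id), age = age,
                 hr_rest = hr_rest, baseline_pef = as.numeric(baseline_pef),
                 baseline_fev1 = as.numeric(baseline_fev1),
                 channel_ranges = channel_ranges),
            class = "subject_profile")
}

#' Default closed valid ranges per channel
#'
#' Chosen to cover the physical range of each sensor while excluding the
#' out-of-range sentinel (e.g. 65535) some sensors emit for a missing value.
#' @export
default_channel_ranges <- function() {
  list(dust_raw = c(0, 4000), dust_density = c(0, 50), pm25 = c(0, 1000),
       temperature = c(-40, 80), humidity = c(0, 100),
       pef = c(50, 900), fev1 = c(0.25, 8), accel = c(-60, 60),
       heart_rate = c(30, 220), location = c(-180, 180), gyro = c(-35, 35))
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("subject %s: age %.1f y, resting HR %.0f bpm\n",
              x$subject_id, x$age, x$hr_rest))
  cat(sprintf("  baseline PEF  %s L/min (mean %.1f)\n",
              paste(x$baseline_pef, collapse = "/"), mean(x$baseline_pef)))
  cat(sprintf("  baseline FEV1 %s L (mean %.2f)\n",
              paste(x$baseline_fev1, collapse = "/"), mean(x$baseline_fev1)))
  invisible(x)
}
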