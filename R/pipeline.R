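#' Window features (and labels) for a recorded session
#'
#' The standard path from raw records to model input: clean and calibrate
#' the stream ([preprocess_stream()]), tile the recorded span with
#' fixed-size half-open windows, extract the 16-entry feature vector per
#' window ([extract_features()]) and, when ACT observations are supplied,
#' align ground-truth risk labels to the windows ([align_labels()]).
#'
#' @param records Raw [sensor_stream()].
#' @param profile A [subject_profile()].
#' @param online Online table or `NULL`.
#' @param acts ACT observations (`t`, `score`) or `NULL`.
#' @param coeffs Dust [dust_coefficients()].
#' @param window_s Window length, seconds (default 60).
#' @param hop_s Hop between windows (default `window_s`).
#' @param horizon_s Label alignment horizon, seconds (default 1800).
#' @param ... Passed to [extract_features()].
#' @return List: `features` (data frame), `labels` (factor or `NULL`),
#'   `windows`, `report` (clean report), `n_unlabeled`.
#' @export
windowed_features <- function(records, profile = subject_profile(),
                              online = NULL, acts = NULL,
                              coeffs = dust_coefficients(),
                              window_s = 60, hop_s = window_s,
                              horizon_s = 1800, ...) {
  prep <- preprocess_stream(records, profile, coeffs)
  t <- prep$stream$t
  from <- floor(min(t))
  to <- from + ceiling((max(t) - from) / window_s) * window_s
  windows <- make_windows(from, to, window_s, hop_s)
  features <- extract_features(prep$stream, profile, online, windows, ...)
  labels <- NULL
  n_unlabeled <- NA_integer_
  if (!is.null(acts)) {
    labels <- align_labels(windows, acts, horizon_s)
    n_unlabeled <- sum(is.na(labels))
  }
  list(features = features, labels = labels, windows = windows,
       report = prep$report, n_unlabeled = n_unlabeled)
}

#' Window features for a generated session
#'
#' Convenience wrapper running [windowed_features()] on the output of
#' [generate()], using the generator's own window length.
#'
#' @param sim Output of [generate()].
#' @param ... Passed to [windowed_features()].
#' @return See [windowed_features()]; also carries `truth` through.
#' @export
session_features <- function(sim, ...) {
  out <- windowed_features(sim$records, sim$profile, sim$online, sim$acts,
                           window_s = sim$config$window_s, ...)
  out$truth <- sim$truth
  out
}
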