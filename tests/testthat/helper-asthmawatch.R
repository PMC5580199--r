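# shared helpers: independent oracles and small random-input builders

# naive two-pass summed per-axis sample variance (oracle for the composite
# acceleration statistic)
km_oracle <- function(samples) {
  samples <- as.matrix(samples)
  sum(apply(samples, 2L, stats::var))
}

# brute-force trailing windowed mean over (t - w, t]
trailing_mean_oracle <- function(t, v, w) {
  vapply(seq_along(t), function(i) {
    mean(v[t > t[i] - w & t <= t[i]])
  }, numeric(1L))
}

# a random valid sensor stream exercising every channel arity
random_stream <- function(n, subjects = c("s1", "s2")) {
  chans <- c("dust_raw", "pm25", "temperature", "humidity", "pef", "fev1",
             "accel", "heart_rate", "location", "gyro")
  channel <- sample(chans, n, replace = TRUE)
  k <- sensor_channels()[channel]
  data.frame(
    subject = sample(subjects, n, replace = TRUE),
    channel = channel,
    t = round(stats::runif(n, 0, 1e4), 3),
    v1 = round(stats::rnorm(n, 50, 20), 6),
    v2 = ifelse(k >= 2L, round(stats::rnorm(n, 0, 5), 6), NA_real_),
    v3 = ifelse(k >= 3L, round(stats::rnorm(n, 0, 5), 6), NA_real_),
    stringsAsFactors = FALSE)
}

# random labeled feature table (no feature-label association unless asked)
random_features <- function(n, shift_by_class = 0) {
  labels <- factor(sample(risk_levels(), n, replace = TRUE),
                   levels = risk_levels())
  x <- as.data.frame(matrix(stats::rnorm(n * 16), n,
                            dimnames = list(NULL, feature_names())))
  if (shift_by_class != 0)
    x[] <- x + shift_by_class * (as.integer(labels) - 2) # class-shifted means
  x$window_start <- seq_len(n) * 60 - 60
  x$window_end <- seq_len(n) * 60
  list(features = x, labels = labels)
}

# small fast generator setup for unit tests (short duration, quick cadence)
quick_config <- function(duration_s = 1200, seed = 5L, ...) {
  generator_config(duration_s = duration_s, act_period_s = 300,
                   seed = seed, ...)
}
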