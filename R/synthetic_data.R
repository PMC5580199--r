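#' Episode script
#'
#' Declares exacerbation episodes on the simulated timeline. `smoke`
#' episodes raise dust/PM and depress spirometry; `exercise` episodes
#' raise heart rate and accelerometer variance; `quiet` rows are allowed
#' as explicit no-op markers. Intensity 1 applies the configured effect
#' sizes in full; values in (0, 1) are mild episodes, >= 1 severe.
#'
#' @param kind Character vector over `{"smoke", "exercise", "quiet"}`.
#' @param start,end Episode bounds, epoch seconds, `start < end`; episodes
#'   of the same kind must not overlap.
#' @param intensity Non-negative severity scalar per episode.
#' @return An `episode_script` data frame.
#' @export
episode_script <- function(kind, start, end, intensity = 1) {
  df <- data.frame(kind = as.character(kind), start = as.numeric(start),
                   end = as.numeric(end),
                   intensity = as.numeric(rep_len(intensity, length(kind))))
  if (!all(df$kind %in% c("smoke", "exercise", "quiet")))
    stop("episode kind must be smoke, exercise or quiet")
  if (any(df$start >= df$end)) stop("episodes need start < end")
  if (any(df$intensity < 0)) stop("episode intensity must be >= 0")
  for (k in unique(df$kind)) {
    e <- df[df$kind == k, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("overlapping episodes of kind ", sQuote(k))
  }
  class(df) <- c("episode_script", "data.frame")
  df
}

# max episode intensity covering each time (half-open [start, end)),
# restricted to the given kinds; quiet rows contribute zero
severity_at <- function(script, t, kinds = c("smoke", "exercise")) {
  sev <- numeric(length(t))
  if (is.null(script) || nrow(script) == 0L) return(sev)
  for (i in seq_len(nrow(script))) {
    if (!script$kind[i] %in% kinds || script$kind[i] == "quiet") next
    cover <- t >= script$start[i] & t < script$end[i]
    sev[cover] <- pmax(sev[cover], script$intensity[i])
  }
  sev
}

#' Generator configuration
#'
#' Sample rates, baselines, noise levels and episode effect sizes of the
#' synthetic sensor-stream generator. Defaults emulate the deployed kit:
#' accelerometer at 20 Hz, heart rate at 1 Hz, dust/PM at 0.2 Hz,
#' temperature/humidity at 0.1 Hz and spirometry once a minute, with
#' Gaussian channel noise and occasional dropout emitting an out-of-range
#' sentinel. A smoke episode at intensity 1 multiplies mean dust/PM by 5
#' and depresses spirometry draws by 35% of baseline; an exercise episode
#' drives heart rate toward `HRrest + intensity * HRR` (capped at the
#' age-predicted maximum) and multiplies accelerometer variance by 25.
#'
#' @param duration_s Simulated span, seconds (default 21600 = 6 h).
#' @param rates Named samples-per-second per channel.
#' @param baselines Named quiet-state levels (dust_raw in raw sensor
#'   units, pm25 in ug/m3, temperature degC, humidity %RH, accel_g m/s2
#'   gravity on the z axis). Spirometry baselines come from the profile.
#' @param noise_sd Named Gaussian noise SDs per channel.
#' @param effects Episode effect sizes at intensity 1.
#' @param act_period_s ACT questionnaire cadence, seconds (default hourly).
#' @param window_s Ground-truth labelling window, seconds (default 60).
#' @param dropout_prob Per-record probability of a sentinel dropout.
#' @param sentinel Out-of-range sentinel value (default 65535).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    duration_s = 21600,
    rates = list(dust_raw = 0.2, pm25 = 0.2, temperature = 0.1,
                 humidity = 0.1, pef = 1 / 60, fev1 = 1 / 60,
                 heart_rate = 1, accel = 20),
    baselines = list(dust_raw = 600, pm25 = 10, temperature = 24,
                     humidity = 45, accel_g = 9.81),
    noise_sd = list(dust_raw = 40, pm25 = 2, temperature = 0.5,
                    humidity = 2, pef = 15, fev1 = 0.15,
                    heart_rate = 3, accel = 0.4),
    effects = list(dust_multiplier = 5, pm_multiplier = 5,
                   spiro_drop = 0.35, accel_var_multiplier = 25,
                   hr_rise = 1),
    act_period_s = 3600, window_s = 60,
    dropout_prob = 0.01, sentinel = 65535, seed = 1L) {
  if (any(unlist(rates) <= 0)) stop("sample rates must be positive")
  if (any(unlist(effects) < 0)) stop("effect sizes must be >= 0")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("dropout probability must lie in [0, 1]")
  structure(list(duration_s = duration_s, rates = rates,
                 baselines = baselines, noise_sd = noise_sd,
                 effects = effects, act_period_s = act_period_s,
                 window_s = window_s, dropout_prob = dropout_prob,
                 sentinel = sentinel, seed = as.integer(seed)),
            class = "generator_config")
}

#' Zero out all episode effect sizes
#'
#' Returns a config whose streams are statistically independent of the
#' episode script (labels still follow the script): the negative control
#' for classifier validation.
#'
#' @param config A [generator_config()].
#' @return The config with all effect sizes set to zero.
#' @export
zero_effect_config <- function(config) {
  config$effects <- list(dust_multiplier = 1, pm_multiplier = 1,
                         spiro_drop = 0, accel_var_multiplier = 1,
                         hr_rise = 0)
  config
}

#' Hour-block mixed exacerbation script
#'
#' Six equal blocks: quiet, mild exercise (0.6), severe smoke (1.0),
#' quiet, mild smoke (0.5), severe exercise (1.2) — two blocks per risk
#' tier, so the ground-truth label distribution is balanced.
#'
#' @param duration_s Total span (default 21600 s = 6 h).
#' @return An [episode_script()].
#' @export
default_mixed_script <- function(duration_s = 21600) {
  b <- duration_s / 6
  episode_script(
    kind = c("exercise", "smoke", "smoke", "exercise"),
    start = b * c(1, 2, 4, 5), end = b * c(2, 3, 5, 6),
    intensity = c(0.6, 1.0, 0.5, 1.2))
}

act_score_for_severity <- function(sev) {
  vapply(sev, function(s) {
    if (s >= 1) sample(5:14, 1L)
    else if (s > 0) sample(15:19, 1L)
    else sample(20:25, 1L)
  }, numeric(1L))
}

#' Generate a synthetic multi-sensor session
#'
#' Simulates the full input surface of the pipeline for one subject:
#' sensor records for all channels, an online-source fixture table, hourly
#' ACT observations whose scores follow the episode severity at the
#' observation time (quiet -> 20-25, mild -> 15-19, severe -> 5-14,
#' uniform within the bin), and per-window ground-truth risk labels from
#' the same severity mapping. Identical seeds give identical output.
#'
#' @param config A [generator_config()].
#' @param script An [episode_script()] (or `NULL` for an all-quiet run);
#'   episodes must lie within `[0, duration_s]`.
#' @param profile A [subject_profile()]; spirometry baselines and resting
#'   heart rate come from here.
#' @return List with `records` (a [sensor_stream()]), `online`
#'   ([as_online_table()]), `acts` (`t`, `score`), `truth` (window bounds
#'   plus `label`), and the `config`, `script`, `profile` used.
#' @export
generate <- function(config = generator_config(), script = NULL,
                     profile = subject_profile()) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(script)) {
    stopifnot(inherits(script, "episode_script"))
    if (any(script$start < 0) || any(script$end > config$duration_s))
      stop("episode script exceeds the configured duration")
  }
  set.seed(config$seed)
  dur <- config$duration_s
  times_for <- function(rate) seq(0, dur - 1 / rate, by = 1 / rate)
  hrr <- hr_reserve(profile$age, profile$hr_rest)
  ef <- config$effects
  parts <- list()
  add <- function(channel, t, v1, v2 = NA_real_, v3 = NA_real_) {
    parts[[length(parts) + 1L]] <<- data.frame(
      subject = profile$subject_id, channel = channel, t = t,
      v1 = v1, v2 = v2, v3 = v3, stringsAsFactors = FALSE)
  }
  # environmental channels; smoke scales the mean multiplicatively
  for (ch in c("dust_raw", "pm25")) {
    t <- times_for(config$rates[[ch]])
    sev <- severity_at(script, t, "smoke")
    mult_1 <- if (ch == "dust_raw") ef$dust_multiplier else ef$pm_multiplier
    mult <- 1 + sev * (mult_1 - 1)
    add(ch, t, config$baselines[[ch]] * mult +
          stats::rnorm(length(t), 0, config$noise_sd[[ch]]))
  }
  for (ch in c("temperature", "humidity")) {
    t <- times_for(config$rates[[ch]])
    add(ch, t, config$baselines[[ch]] +
          stats::rnorm(length(t), 0, config$noise_sd[[ch]]))
  }
  # spirometry: percent drop proportional to smoke severity (capped at 90%)
  for (ch in c("pef", "fev1")) {
    t <- times_for(config$rates[[ch]])
    sev <- severity_at(script, t, "smoke")
    base <- mean(if (ch == "pef") profile$baseline_pef else profile$baseline_fev1)
    drop <- pmin(ef$spiro_drop * sev, 0.9)
    add(ch, t, base * (1 - drop) +
          stats::rnorm(length(t), 0, config$noise_sd[[ch]]))
  }
  # heart rate: exercise drives it toward HRrest + intensity * HRR
  t <- times_for(config$rates$heart_rate)
  sev <- severity_at(script, t, "exercise")
  target <- pmin(profile$hr_rest + ef$hr_rise * sev * hrr,
                 hr_max(profile$age))
  add("heart_rate", t, target +
        stats::rnorm(length(t), 0, config$noise_sd$heart_rate))
  # accelerometer: exercise multiplies variance
  t <- times_for(config$rates$accel)
  sev <- severity_at(script, t, "exercise")
  sd_eff <- config$noise_sd$accel *
    sqrt(pmax(1 + sev * (ef$accel_var_multiplier - 1), 0))
  n <- length(t)
  add("accel", t, stats::rnorm(n, 0, sd_eff), stats::rnorm(n, 0, sd_eff),
      config$baselines$accel_g + stats::rnorm(n, 0, sd_eff))
  records <- do.call(rbind, parts)
  # dropout: replace whole records with the out-of-range sentinel
  if (config$dropout_prob > 0) {
    hit <- stats::runif(nrow(records)) < config$dropout_prob
    k <- sensor_channels()[records$channel]
    records$v1[hit] <- config$sentinel
    records$v2[hit & k >= 2L] <- config$sentinel
    records$v3[hit & k >= 3L] <- config$sentinel
  }
  records <- as_sensor_stream(records)
  # online fixture rows at the ACT cadence, independent of the script
  ot <- seq(0, dur, by = config$act_period_s)
  # weather/traffic vary between days far more than within a session: one
  # session-level draw per variable, held for the session (within-session
  # drift is negligible at these spans and would otherwise act as a
  # memorizable session-time index)
  slow <- function(base, sd) {
    rep(base + stats::rnorm(1L, 0, sd), length(ot))
  }
  online <- as_online_table(data.frame(
    t = ot,
    ozone = slow(30, 3),
    pressure = slow(1013, 2),
    cloud_cover = pmin(pmax(slow(0.3, 0.1), 0), 1),
    wind_speed = pmax(slow(3, 1), 0),
    precip_probability = pmin(pmax(slow(0.1, 0.05), 0), 1),
    precip_intensity = 0,
    traffic_density = pmax(slow(50, 10), 0),
    aqi = pmax(slow(40, 5), 0)))
  # ACT at period midpoints so every window end lies within a half-period
  at <- seq(config$act_period_s / 2, dur, by = config$act_period_s)
  acts <- data.frame(t = at,
                     score = act_score_for_severity(severity_at(script, at)))
  truth_w <- make_windows(0, dur, config$window_s)
  mid <- (truth_w$window_start + truth_w$window_end) / 2
  sev_w <- severity_at(script, mid)
  truth_w$label <- factor(
    ifelse(sev_w >= 1, "high", ifelse(sev_w > 0, "medium", "low")),
    levels = risk_levels())
  list(records = records, online = online, acts = acts, truth = truth_w,
       config = config, script = script, profile = profile)
}

#' Write the canonical fixture suite
#'
#' Generates four small scenarios (quiet half-hour, smoky half-hour,
#' exercise half-hour, and a one-hour mixed session with all three risk
#' tiers) from embedded seeds and writes them under `out_dir`, one
#' sub-directory each with `records.csv` (or `.jsonl` for the smoke
#' scenario, to exercise both formats), `online.csv`, `acts.csv` and
#' `truth.csv`. Running twice produces bit-identical files.
#'
#' @param out_dir Writable directory (created if absent).
#' @return Invisible character vector of the files written.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  half <- 1800
  scen <- list(
    quiet_hour = list(cfg = generator_config(duration_s = half,
                                             act_period_s = 600, seed = 11L),
                      script = NULL, fmt = "csv"),
    smoky_hour = list(cfg = generator_config(duration_s = half,
                                             act_period_s = 600, seed = 12L),
                      script = episode_script("smoke", 600, 1500, 1.0),
                      fmt = "jsonl"),
    exercise_hour = list(cfg = generator_config(duration_s = half,
                                                act_period_s = 600, seed = 13L),
                         script = episode_script("exercise", 600, 1500, 1.1),
                         fmt = "csv"),
    mixed_session = list(cfg = generator_config(duration_s = 3600,
                                                act_period_s = 600, seed = 14L),
                         script = {
                           b <- 600
                           episode_script(
                             kind = c("exercise", "smoke", "smoke", "exercise"),
                             start = b * c(1, 2, 4, 5), end = b * c(2, 3, 5, 6),
                             intensity = c(0.6, 1.0, 0.5, 1.2))
                         }, fmt = "csv"))
  written <- character()
  for (nm in names(scen)) {
    s <- scen[[nm]]
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    sim <- generate(s$cfg, s$script)
    rec_path <- file.path(d, paste0("records.", s$fmt))
    write_stream(sim$records, rec_path, s$fmt)
    utils::write.csv(sim$online, file.path(d, "online.csv"), row.names = FALSE)
    utils::write.csv(sim$acts, file.path(d, "acts.csv"), row.names = FALSE)
    utils::write.csv(sim$truth, file.path(d, "truth.csv"), row.names = FALSE)
    written <- c(written, rec_path,
                 file.path(d, c("online.csv", "acts.csv", "truth.csv")))
  }
  invisible(written)
}
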