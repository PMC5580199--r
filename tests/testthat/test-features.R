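test_that("composite acceleration equals the naive per-axis variance sum", {
  set.seed(31)
  for (case in 1:500) {
    n <- sample(2:120, 1L)
    s <- matrix(rnorm(n * 3, sd = runif(1, 0.1, 10)), n)
    expect_equal(composite_accel_km(s), km_oracle(s), tolerance = 1e-10)
  }
})

test_that("composite acceleration worked examples and degenerate cases", {
  expect_identical(composite_accel_km(matrix(0, 5, 3)), 0)
  expect_identical(composite_accel_km(cbind(rep(3.7, 9), 0, 0)), 0)
  expect_equal(composite_accel_km(rbind(c(1, 0, 0), c(3, 0, 0))), 2)
  expect_error(composite_accel_km(matrix(1, 1, 3)), "at least 2")
  expect_error(composite_accel_km(matrix(1, 4, 2)), "three columns")
  # literal degenerate reading: P = Q, so Km = Q/n
  s <- rbind(c(1, 0, 0), c(3, 0, 0))
  expect_equal(composite_accel_km(s, as_printed = TRUE), 10 / 2)
  expect_equal(composite_accel_km(s, sqrt_norm = TRUE), sqrt(2))
})

test_that("Km is translation invariant and scales quadratically", {
  set.seed(32)
  for (case in 1:50) {
    n <- sample(2:50, 1L)
    s <- matrix(rnorm(n * 3), n)
    shift <- matrix(rep(rnorm(3, 0, 20), each = n), n)
    expect_equal(composite_accel_km(s + shift), composite_accel_km(s),
                 tolerance = 1e-8)
    k <- runif(1, 1, 5)
    expect_equal(composite_accel_km(k * s), k^2 * composite_accel_km(s),
                 tolerance = 1e-8)
  }
})

test_that("energy expenditure averages Km over complete 5-s sub-windows", {
  # two sub-windows with known Km 2 and 4 (two-sample variance (d^2)/2)
  t <- c(0, 2.5, 5, 7.5)
  xyz <- rbind(c(1, 0, 0), c(3, 0, 0),          # var {1,3} = 2
               c(0, 0, 0), c(sqrt(8), 0, 0))    # var {0, sqrt 8} = 4
  expect_equal(energy_expenditure(t, xyz, c(0, 10)), 3)
  expect_equal(energy_expenditure(t, xyz, c(0, 10), aggregate = "sum"), 6)
  # all-zero windows give zero
  expect_equal(energy_expenditure(t, matrix(0, 4, 3), c(0, 10)), 0)
  # no accel data in the window flags the feature missing
  expect_true(is.na(energy_expenditure(t, xyz, c(100, 160))))
  # a lone sample in a sub-window cannot yield a variance
  expect_true(is.na(energy_expenditure(0, matrix(1, 1, 3), c(0, 5))))
})

test_that("a vigorous regime yields a larger energy expenditure than rest", {
  cfg <- quick_config(duration_s = 600, seed = 33)
  cfg$dropout_prob <- 0
  sim <- generate(cfg, episode_script("exercise", 300, 600, 1))
  acc <- sim$records[sim$records$channel == "accel", ]
  xyz <- as.matrix(acc[c("v1", "v2", "v3")])
  quiet <- energy_expenditure(acc$t, xyz, c(0, 300))
  vigorous <- energy_expenditure(acc$t, xyz, c(300, 600))
  expect_gt(vigorous, quiet)
})

test_that("heart rate reserve follows the age-predicted maximum", {
  expect_equal(hr_max(29), 187.7)
  expect_equal(hr_reserve(29, 60), 127.7)
  expect_equal(hr_max(0), 208)  # formula at zero (validation rejects age 0)
  p <- subject_profile(age = 29, hr_rest = 60)
  expect_equal(hr_reserve_fraction(p, 60), 0)          # at rest
  expect_equal(hr_reserve_fraction(p, 60 + 127.7 / 2), 0.5)
  expect_equal(hr_reserve_fraction(p, 500), 1.5)       # clipped
  expect_equal(hr_reserve_fraction(p, 30), 0)          # clipped below
  expect_error(hr_reserve(300, 60), "positive")
})

test_that("spirometry percent of baseline uses the triplet mean", {
  expect_equal(percent_of_baseline(320, c(310, 320, 330)), 100)
  expect_equal(percent_of_baseline(160, c(300, 320, 340)), 50)
  expect_equal(percent_of_baseline(0, c(300, 320, 340)), 0)
  expect_error(percent_of_baseline(100, c(0, 0, 0)), "positive")
  expect_error(percent_of_baseline(100, c(300, 320)), "three")
})

test_that("feature vectors carry the 16 declared features in fixed order", {
  expect_identical(length(feature_names()), 16L)
  cfg <- quick_config(duration_s = 600, seed = 34)
  cfg$dropout_prob <- 0
  sim <- generate(cfg)
  prep <- preprocess_stream(sim$records, sim$profile)
  fv <- build_feature_vector(prep$stream, sim$profile,
                             join_online_features(60, sim$online),
                             c(0, 60))
  expect_identical(names(fv), c("window_start", "window_end", feature_names()))
  expect_true(all(is.finite(unlist(fv))))
  # purity: identical inputs give the identical vector
  fv2 <- build_feature_vector(prep$stream, sim$profile,
                              join_online_features(60, sim$online),
                              c(0, 60))
  expect_identical(fv, fv2)
  # order survives a serialization round trip
  tmp <- withr::local_tempfile()
  utils::write.csv(fv, tmp, row.names = FALSE)
  expect_identical(names(utils::read.csv(tmp)), names(fv))
})

test_that("absent spirometry and online data flag features missing, not zero", {
  stream <- as_sensor_stream(rbind(
    data.frame(subject = "s", channel = "heart_rate", t = 0:59,
               v1 = 62, v2 = NA_real_, v3 = NA_real_)))
  fv <- build_feature_vector(stream, subject_profile(), NULL, c(0, 60))
  expect_true(is.na(fv$percent_pef))
  expect_true(is.na(fv$percent_fev1))
  expect_true(is.na(fv$ozone))
  expect_false(is.na(fv$heart_rate_reserve))
  # stale spirometry (beyond the horizon) is also flagged
  stream2 <- as_sensor_stream(rbind(
    data.frame(subject = "s", channel = "pef", t = 0,
               v1 = 320, v2 = NA_real_, v3 = NA_real_),
    data.frame(subject = "s", channel = "heart_rate", t = 2e5 + (0:59),
               v1 = 62, v2 = NA_real_, v3 = NA_real_)))
  fv2 <- build_feature_vector(stream2, subject_profile(), NULL,
                              c(2e5, 2e5 + 60))
  expect_true(is.na(fv2$percent_pef))
  # an all-empty window is an error
  expect_error(build_feature_vector(stream, subject_profile(), NULL,
                                    c(1e6, 1e6 + 60)),
               "no sensor data")
})

test_that("windows are half-open and tile the span", {
  w <- make_windows(0, 300, 60)
  expect_identical(nrow(w), 5L)
  expect_equal(w$window_end - w$window_start, rep(60, 5))
  # a sample exactly at a boundary lands in exactly one window
  stream <- sensor_stream("s", "pm25", c(59.999, 60), c(1, 100))
  f <- extract_features(stream, subject_profile(), NULL,
                        make_windows(0, 120, 60))
  expect_equal(f$particulate_matter, c(1, 100))
})
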