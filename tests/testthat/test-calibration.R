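test_that("calibration reproduces the printed worked examples", {
  co <- dust_coefficients()
  # no deviation: plain affine in raw voltage
  expect_identical(dust_density(0, co$ref_temperature, co$ref_humidity), -0.15)
  expect_equal(dust_density(1000, co$ref_temperature, co$ref_humidity), 0.39)
  # humidity up, temperature up (refs below the operating point so both
  # deviations are positive): humidity branch with the T1 correction
  co2 <- dust_coefficients(ref_temperature = 20, ref_humidity = 40)
  expect_equal(dust_density(5, 25, 50, co2),
               2.8e-3 * 50 + 0.1647 - (0.0005 * 25 + 0.0133))
  expect_equal(dust_density(5, 25, 50, co2), 0.2789)
})

test_that("with no deviations the map is affine in x with slope 5.4e-4", {
  co <- dust_coefficients()
  set.seed(11)
  x <- runif(50, 0, 4000)
  h <- 1e-3
  slopes <- (dust_density(x + h, co$ref_temperature, co$ref_humidity) -
               dust_density(x, co$ref_temperature, co$ref_humidity)) / h
  expect_equal(slopes, rep(5.4e-4, 50), tolerance = 1e-8)
})

test_that("every sign combination of the deviations maps to one branch", {
  co <- dust_coefficients()
  rT <- co$ref_temperature; rH <- co$ref_humidity
  grid <- expand.grid(dH = c(-5, 0, 5), dT = c(-3, 0, 3))
  x <- 800
  got <- dust_density(x, rT + grid$dT, rH + grid$dH, co)
  expect_true(all(is.finite(got)))
  affine <- co$slope * x + co$intercept
  expected <- with(grid, ifelse(
    dH == 0 & dT == 0, affine,
    ifelse(dH > 0 & dT > 0, co$alpha_h * (rH + dH) + co$beta_h -
             (co$alpha_t1 * (rT + dT) + co$beta_t1),
    ifelse(dH > 0, co$alpha_h * (rH + dH) + co$beta_h -
             (co$alpha_t2 * (rT + dT) + co$beta_t2),
    ifelse(dT > 0, affine - (co$alpha_t1 + co$beta_t1),
           affine - (co$alpha_t2 + co$beta_t2))))))
  expect_equal(got, expected)
})

test_that("zero deviations route to the branches that keep the voltage term", {
  co <- dust_coefficients()
  x <- c(100, 900)
  # dH = 0 with dT != 0 behaves as the dH < 0 family (affine retained)
  expect_equal(dust_density(x, co$ref_temperature + 2, co$ref_humidity, co),
               co$slope * x + co$intercept - (co$alpha_t1 + co$beta_t1))
  # the deviation hook adds the affine term to the humid branches
  with_x <- dust_density(x, co$ref_temperature + 2, co$ref_humidity + 5, co,
                         humid_branch_adds_affine = TRUE)
  without <- dust_density(x, co$ref_temperature + 2, co$ref_humidity + 5, co)
  expect_equal(with_x - without, co$slope * x + co$intercept)
  expect_equal(without[1L], without[2L])  # as printed: no x dependence
})

test_that("default coefficients carry the printed constants exactly", {
  co <- dust_coefficients()
  expect_identical(co$slope, 5.4e-4)
  expect_identical(co$intercept, -0.15)
  expect_identical(co$alpha_h, 2.8e-3)
  expect_identical(co$beta_h, 0.1647)
  expect_identical(co$alpha_t1, 0.0005)
  expect_identical(co$beta_t1, 0.0133)
  expect_identical(co$alpha_t2, 0.0002)
  expect_identical(co$beta_t2, 0.0329)
  expect_error(dust_coefficients(slope = NA), "finite")
  expect_error(dust_density(NaN, 25, 40), "finite")
})

test_that("negative densities clamp to zero and are flagged", {
  cl <- clamp_nonnegative(c(-0.15, 0.39, 0))
  expect_equal(cl$value, c(0, 0.39, 0))
  expect_identical(cl$clamped, c(TRUE, FALSE, FALSE))
})

test_that("coefficients load from a YAML section with printed defaults as fallback", {
  tmp <- withr::local_tempfile(
    lines = c("dust_calibration:", "  slope: 1.0e-3", "  ref_humidity: 55"))
  co <- dust_coefficients_from_config(tmp)
  expect_identical(co$slope, 1e-3)
  expect_identical(co$ref_humidity, 55)
  expect_identical(co$beta_h, 0.1647)
  tmp2 <- withr::local_tempfile(lines = c("dust_calibration:",
                                          "  bogus_key: 1"))
  expect_error(dust_coefficients_from_config(tmp2), "bogus_key")
})

test_that("stream calibration pairs dust samples with carried-forward T/H", {
  co <- dust_coefficients()
  df <- rbind(
    data.frame(subject = "s", channel = "temperature", t = 0,
               v1 = co$ref_temperature + 2, v2 = NA_real_, v3 = NA_real_),
    data.frame(subject = "s", channel = "humidity", t = 0,
               v1 = co$ref_humidity, v2 = NA_real_, v3 = NA_real_),
    data.frame(subject = "s", channel = "dust_raw", t = c(5, 10),
               v1 = c(1000, 100), v2 = NA_real_, v3 = NA_real_))
  out <- calibrate_dust_stream(as_sensor_stream(df), co, clamp = FALSE)
  d <- out[out$channel == "dust_density", ]
  expect_equal(d$v1, co$slope * c(1000, 100) + co$intercept -
                 (co$alpha_t1 + co$beta_t1))
  # with no T/H observations, reference conditions apply (plain affine)
  df2 <- df[df$channel == "dust_raw", ]
  out2 <- calibrate_dust_stream(as_sensor_stream(df2), co, clamp = FALSE)
  expect_equal(out2$v1, co$slope * c(1000, 100) + co$intercept)
  # clamping counts flow through the stream wrapper
  out3 <- calibrate_dust_stream(as_sensor_stream(df2[2, ]), co)
  expect_identical(attr(out3, "n_clamped"),
                   as.integer(co$slope * 100 + co$intercept < 0))
})
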