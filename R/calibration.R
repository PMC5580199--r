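#' Dust-sensor calibration coefficients
#'
#' Constants of the piecewise dust-density calibration that compensates the
#' optical dust sensor's raw voltage for temperature and humidity changes.
#' Defaults are the constants obtained from the original co-measurement
#' calibration against a professional particle counter; deviations of
#' humidity (dH) and temperature (dT) are taken relative to the reference
#' calibration conditions stored here.
#'
#' @param slope Affine slope on raw voltage (default 5.4e-4).
#' @param intercept Affine intercept (default -0.15).
#' @param alpha_h,beta_h Humidity-branch coefficients (2.8e-3, 0.1647).
#' @param alpha_t1,beta_t1 Temperature coefficients used when dT > 0
#'   (0.0005, 0.0133).
#' @param alpha_t2,beta_t2 Temperature coefficients used when dT < 0
#'   (0.0002, 0.0329).
#' @param ref_temperature Reference temperature, degrees C (default 25).
#' @param ref_humidity Reference relative humidity, %RH (default 40).
#' @return A `dust_coefficients` list.
#' @export
dust_coefficients <- function(slope = 5.4e-4, intercept = -0.15,
                              alpha_h = 2.8e-3, beta_h = 0.1647,
                              alpha_t1 = 0.0005, beta_t1 = 0.0133,
                              alpha_t2 = 0.0002, beta_t2 = 0.0329,
                              ref_temperature = 25, ref_humidity = 40) {
  co <- list(slope = slope, intercept = intercept, alpha_h = alpha_h,
             beta_h = beta_h, alpha_t1 = alpha_t1, beta_t1 = beta_t1,
             alpha_t2 = alpha_t2, beta_t2 = beta_t2,
             ref_temperature = ref_temperature, ref_humidity = ref_humidity)
  bad <- names(co)[!vapply(co, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1L))]
  co <- lapply(co, as.numeric)
  if (length(bad) > 0L)
    stop("coefficients must be finite scalars: ", paste(bad, collapse = ", "))
  structure(co, class = "dust_coefficients")
}

#' Load dust calibration coefficients from a YAML config
#'
#' Reads the `dust_calibration` section of a YAML file; keys omitted there
#' fall back to the printed defaults of [dust_coefficients()].
#'
#' @param path YAML file with a `dust_calibration` mapping.
#' @return A [dust_coefficients()] object.
#' @export
dust_coefficients_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sec <- cfg$dust_calibration
  if (is.null(sec)) sec <- list()
  known <- names(formals(dust_coefficients))
  unknown <- setdiff(names(sec), known)
  if (length(unknown) > 0L)
    stop("unknown dust_calibration key(s): ", paste(unknown, collapse = ", "))
  do.call(dust_coefficients, sec)
}

#' Calibrated dust density from raw voltage, temperature and humidity
#'
#' Piecewise calibration selected by the signs of the humidity deviation
#' dH = H - ref_humidity and temperature deviation dT = T - ref_temperature:
#'
#' * dH = 0, dT = 0: `slope*x + intercept`
#' * dH > 0, dT > 0: `alpha_h*H + beta_h - (alpha_t1*T + beta_t1)`
#' * dH > 0, dT < 0: `alpha_h*H + beta_h - (alpha_t2*T + beta_t2)`
#' * dH < 0, dT > 0: `slope*x + intercept - (alpha_t1 + beta_t1)`
#' * dH < 0, dT < 0: `slope*x + intercept - (alpha_t2 + beta_t2)`
#'
#' Zero deviations on one axis only are routed to the corresponding
#' negative-deviation branch (the family that retains the affine term in
#' `x`), which is continuous with the no-change case; dH = dT = 0 uses the
#' plain affine case. The dH > 0 branches carry no `x` term; set
#' `humid_branch_adds_affine = TRUE` to add `slope*x + intercept` to them
#' (a deviation hook, off by default). Note the dH < 0 branches subtract
#' the constant `(alpha_t + beta_t)` with no temperature multiplier.
#'
#' The linear fit can return negative densities at low voltage; see
#' [clamp_nonnegative()].
#'
#' @param x Raw dust-sensor voltage (native sensor units), finite.
#' @param temperature Ambient temperature, degrees C, finite.
#' @param humidity Relative humidity, %RH, finite.
#' @param coeffs A [dust_coefficients()] object.
#' @param humid_branch_adds_affine Add the affine voltage term to the
#'   dH > 0 branches (default `FALSE`: branches exactly as calibrated).
#' @return Dust density (calibrated sensor units), vectorized over inputs.
#' @export
dust_density <- function(x, temperature, humidity,
                         coeffs = dust_coefficients(),
                         humid_branch_adds_affine = FALSE) {
  stopifnot(inherits(coeffs, "dust_coefficients"))
  n <- max(length(x), length(temperature), length(humidity))
  x <- rep_len(as.numeric(x), n)
  temperature <- rep_len(as.numeric(temperature), n)
  humidity <- rep_len(as.numeric(humidity), n)
  if (any(!is.finite(x)) || any(!is.finite(temperature)) ||
      any(!is.finite(humidity)))
    stop("dust_density inputs must be finite")
  dH <- humidity - coeffs$ref_humidity
  dT <- temperature - coeffs$ref_temperature
  affine <- coeffs$slope * x + coeffs$intercept
  humid <- coeffs$alpha_h * humidity + coeffs$beta_h
  t1 <- coeffs$alpha_t1 * temperature + coeffs$beta_t1
  t2 <- coeffs$alpha_t2 * temperature + coeffs$beta_t2
  out <- numeric(n)
  both_zero <- dH == 0 & dT == 0
  hum_pos <- dH > 0
  warm <- dT > 0  # dT == 0 falls to the dT < 0 family (continuity)
  out[both_zero] <- affine[both_zero]
  i <- !both_zero & hum_pos & warm
  out[i] <- humid[i] - t1[i]
  i <- !both_zero & hum_pos & !warm
  out[i] <- humid[i] - t2[i]
  if (humid_branch_adds_affine) {
    i <- !both_zero & hum_pos
    out[i] <- out[i] + affine[i]
  }
  i <- !both_zero & !hum_pos & warm
  out[i] <- affine[i] - (coeffs$alpha_t1 + coeffs$beta_t1)
  i <- !both_zero & !hum_pos & !warm
  out[i] <- affine[i] - (coeffs$alpha_t2 + coeffs$beta_t2)
  out
}

#' Clamp calibrated densities to the physical range
#'
#' Dust density is physically non-negative; the affine calibration can dip
#' below zero at low voltage. Clamped values are flagged rather than
#' silently altered.
#'
#' @param rho Numeric densities, finite.
#' @return List with `value` (clamped densities) and `clamped` (logical,
#'   `TRUE` where the input was negative).
#' @export
clamp_nonnegative <- function(rho) {
  if (any(!is.finite(rho))) stop("densities must be finite")
  list(value = pmax(rho, 0), clamped = rho < 0)
}

#' Calibrate the dust channel of a sensor stream
#'
#' Replaces `dust_raw` records with `dust_density` records. The temperature
#' and humidity at each dust sample are taken from the stream's own
#' temperature/humidity channels by last observation carried forward;
#' before the first such observation the reference calibration conditions
#' are assumed (deviations of zero).
#'
#' @param stream A [sensor_stream()].
#' @param coeffs A [dust_coefficients()] object.
#' @param clamp Clamp negative densities to zero (default `TRUE`).
#' @param ... Passed on to [dust_density()].
#' @return The stream with the dust channel calibrated; the number of
#'   clamped records is attached as attribute `"n_clamped"`.
#' @export
calibrate_dust_stream <- function(stream, coeffs = dust_coefficients(),
                                  clamp = TRUE, ...) {
  stream <- as_sensor_stream(as.data.frame(stream))
  is_dust <- stream$channel == "dust_raw" & !is.na(stream$v1)
  stream$channel[stream$channel == "dust_raw" & is.na(stream$v1)] <- "dust_density"
  if (!any(is_dust)) {
    attr(stream, "n_clamped") <- 0L
    return(stream)
  }
  locf <- function(chan, default) {
    obs <- stream[stream$channel == chan & !is.na(stream$v1), ]
    if (nrow(obs) == 0L) return(rep(default, sum(is_dust)))
    idx <- findInterval(stream$t[is_dust], obs$t)
    ifelse(idx == 0L, default, obs$v1[pmax(idx, 1L)])
  }
  temp <- locf("temperature", coeffs$ref_temperature)
  hum <- locf("humidity", coeffs$ref_humidity)
  rho <- dust_density(stream$v1[is_dust], temp, hum, coeffs, ...)
  n_clamped <- 0L
  if (clamp) {
    cl <- clamp_nonnegative(rho)
    rho <- cl$value
    n_clamped <- sum(cl$clamped)
  }
  stream$channel[is_dust] <- "dust_density"
  stream$v1[is_dust] <- rho
  out <- as_sensor_stream(stream)
  attr(out, "n_clamped") <- n_clamped
  out
}
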