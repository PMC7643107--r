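# Focusing-threshold models TM1-TM4 and the density-coefficient
# calibration. The threshold criterion is a/x >= 0.07 with x a
# characteristic channel length (TM1: hydraulic diameter D; TM2: height h;
# TM3: the blend (D + 3h)/4), and TM4 generalises TM1 to a/D >= 0.07 c
# with a density coefficient c >= 1 that grows linearly with particle
# density.

.FOCUS_CONSTANT <- 0.07
.TM_IDS <- c("TM1", "TM2", "TM3", "TM4")

.check_model_id <- function(model) {
  if (!is.character(model) || length(model) != 1L ||
      !(model %in% .TM_IDS)) {
    stop("unknown threshold model id; expected one of ",
         paste(.TM_IDS, collapse = ", "), call. = FALSE)
  }
  model
}

#' Linear density-coefficient model for TM4
#'
#' c(rho) = slope * rho + intercept with rho the particle density in g/ml.
#' The coefficient is defined to be >= 1 (TM4 never predicts a threshold
#' below TM1), so predictions are clamped below at 1 by
#' [density_coefficient()]. The published calibration has slope 0.127 per
#' g/ml and intercept 0.867, valid for densities between 1.05 g/ml
#' (polystyrene) and 2.75 g/ml (talc).
#'
#' @param slope slope in 1/(g/ml).
#' @param intercept dimensionless intercept.
#' @param valid_range length-2 numeric, density validity window in g/ml.
#' @return an object of class `density_coefficient_model`.
#' @export
density_coefficient_model <- function(slope = 0.127, intercept = 0.867,
                                      valid_range = c(1.05, 2.75)) {
  if (length(valid_range) != 2L || valid_range[1] >= valid_range[2]) {
    stop("valid_range must be an increasing density interval (g/ml)",
         call. = FALSE)
  }
  m <- structure(list(slope = slope, intercept = intercept,
                      valid_range = as.numeric(valid_range)),
                 class = "density_coefficient_model")
  # c must be >= 1 somewhere meaningful; clamping enforces the floor, but a
  # model entirely below 1 over its validity window is a calibration error.
  if (max(slope * valid_range + intercept) < 1 - 1e-9) {
    stop("density-coefficient model predicts c < 1 over its whole validity ",
         "range", call. = FALSE)
  }
  m
}

#' @export
print.density_coefficient_model <- function(x, ...) {
  cat(sprintf("Density coefficient model: c = %.4g rho + %.4g (rho in g/ml)\n",
              x$slope, x$intercept))
  cat(sprintf("  valid for rho in [%.2f, %.2f] g/ml; c clamped at >= 1\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Characteristic length of a threshold model
#'
#' TM1 and TM4 use the hydraulic diameter D, TM2 the channel height h,
#' TM3 the blend (D + 3h)/4.
#'
#' @param model one of `"TM1"`, `"TM2"`, `"TM3"`, `"TM4"`.
#' @param channel a [rect_channel()].
#' @return characteristic length x (m).
#' @export
characteristic_length <- function(model, channel) {
  .check_model_id(model)
  stopifnot(inherits(channel, "rect_channel"))
  D <- hydraulic_diameter(channel)
  switch(model,
         TM1 = D,
         TM2 = channel$height,
         TM3 = (D + 3 * channel$height) / 4,
         TM4 = D)
}

#' Focusing-threshold diameter under a threshold model
#'
#' The smallest particle diameter predicted to focus: 0.07 x for TM1-TM3
#' and 0.07 c D for TM4. With c = 1 TM4 coincides exactly with TM1.
#' Values are never rounded internally; see [round_threshold_um()] for
#' human-readable reporting.
#'
#' @param model one of `"TM1"`-`"TM4"`.
#' @param channel a [rect_channel()].
#' @param c density coefficient (TM4 only; must be >= 1). Ignored with a
#'   warning-free pass-through for TM1-TM3.
#' @return threshold diameter (m).
#' @export
threshold_diameter <- function(model, channel, c = 1) {
  .check_model_id(model)
  x <- characteristic_length(model, channel)
  if (model == "TM4") {
    if (!is.numeric(c) || any(c < 1)) {
      stop("TM4 requires a density coefficient c >= 1", call. = FALSE)
    }
    return(.FOCUS_CONSTANT * c * x)
  }
  .FOCUS_CONSTANT * x
}

#' Density coefficient for TM4
#'
#' Evaluates the linear model c = slope * rho + intercept (rho in g/ml)
#' and clamps the result below at 1: the coefficient is by definition
#' greater than or equal to unity, and low-density particles such as
#' polystyrene (1.05 g/ml) use c = 1 exactly. Densities outside the
#' model's validity range produce a warning, not an error.
#'
#' @param density_g_ml particle density in g/ml (the calibration's native
#'   unit). Pass SI kg/m^3 through `/ 1000` or [g_ml()] inversion at the
#'   boundary.
#' @param model a [density_coefficient_model()].
#' @return dimensionless coefficient c >= 1.
#' @export
density_coefficient <- function(density_g_ml,
                                model = density_coefficient_model()) {
  stopifnot(inherits(model, "density_coefficient_model"))
  if (!is.numeric(density_g_ml) || any(density_g_ml <= 0)) {
    stop("particle density must be positive", call. = FALSE)
  }
  if (any(density_g_ml > 50)) {
    stop("density ", max(density_g_ml), " looks like kg/m^3; ",
         "density_coefficient() expects g/ml", call. = FALSE)
  }
  out <- any(density_g_ml < model$valid_range[1] |
               density_g_ml > model$valid_range[2])
  if (out) {
    warning(sprintf(
      "density outside the calibrated range [%.2f, %.2f] g/ml; ",
      model$valid_range[1], model$valid_range[2]),
      "coefficient is an extrapolation", call. = FALSE)
  }
  pmax(1, model$slope * density_g_ml + model$intercept)
}

#' Calibrate a density-coefficient line from (density, c) anchors
#'
#' Least-squares fit of c against density in g/ml; with exactly two
#' anchors this is exact interpolation. The validity range is set to the
#' anchor density span.
#'
#' @param densities_g_ml anchor densities (g/ml), at least two distinct.
#' @param c_values anchor coefficients, same length.
#' @return a [density_coefficient_model()].
#' @export
calibrate_density_model <- function(densities_g_ml, c_values) {
  if (length(densities_g_ml) < 2L ||
      length(densities_g_ml) != length(c_values)) {
    stop("calibration needs >= 2 (density, c) anchor pairs", call. = FALSE)
  }
  if (anyDuplicated(densities_g_ml)) {
    stop("calibration anchors must have distinct densities", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, densities_g_ml), c_values)
  density_coefficient_model(slope = unname(fit$coefficients[2]),
                            intercept = unname(fit$coefficients[1]),
                            valid_range = range(densities_g_ml))
}

#' Density coefficient implied by an observed threshold
#'
#' Inverts TM4: c = a_t / (0.07 D). The talc threshold of 26 um in the
#' reference channel gives c = 1.216, the anchor used to calibrate the
#' density-coefficient line.
#'
#' @param a_t observed threshold diameter (m).
#' @param channel a [rect_channel()].
#' @return dimensionless coefficient.
#' @export
coefficient_from_threshold <- function(a_t, channel) {
  if (!is.numeric(a_t) || any(a_t <= 0)) {
    stop("threshold diameter must be positive", call. = FALSE)
  }
  a_t / (.FOCUS_CONSTANT * hydraulic_diameter(channel))
}

#' Is a particle above the focusing threshold?
#'
#' Compares the particle diameter to the model threshold with a relative
#' tolerance of 1e-9 so that exact round-trips (a threshold recovered via
#' [coefficient_from_threshold()]) classify as focused.
#'
#' @param a particle diameter (m).
#' @param model threshold model id.
#' @param channel a [rect_channel()].
#' @param density_g_ml particle density in g/ml (TM4 only).
#' @param dcm a [density_coefficient_model()] (TM4 only).
#' @return logical: does the particle meet the focusing criterion?
#' @export
is_focused <- function(a, model, channel, density_g_ml = NULL,
                       dcm = density_coefficient_model()) {
  .check_model_id(model)
  c_val <- 1
  if (model == "TM4") {
    if (is.null(density_g_ml)) {
      stop("TM4 needs the particle density (g/ml)", call. = FALSE)
    }
    c_val <- density_coefficient(density_g_ml, dcm)
  }
  a_t <- threshold_diameter(model, channel, c = c_val)
  a >= a_t * (1 - 1e-9)
}

#' Round a threshold for human-readable reporting
#'
#' Thresholds are reported to the nearest micrometre by default, or to the
#' nearest half micrometre (`granularity = 0.5`), the granularity matching
#' +/- 2 um particle size bins. Internal computations never round.
#'
#' @param a_t threshold diameter (m).
#' @param granularity reporting step in um (1 or 0.5).
#' @return rounded threshold in um.
#' @export
round_threshold_um <- function(a_t, granularity = 1) {
  round(a_t * 1e6 / granularity) * granularity
}

#' Display threshold of TM3 via the rounded-chain convention
#'
#' TM3's definition is 0.07 (D + 3h)/4, which evaluates to 16.9 um for the
#' reference channel. A common reporting convention instead averages the
#' already-rounded TM1 and TM2 thresholds, (21 + 3*15)/4 = 16.5 um. Both
#' are available: the formula through [threshold_diameter()], this chain
#' through `round_chain = TRUE`.
#'
#' @param channel a [rect_channel()].
#' @param round_chain average the integer-rounded TM1/TM2 thresholds
#'   instead of evaluating the formula.
#' @return threshold in um.
#' @export
tm3_display_threshold <- function(channel, round_chain = FALSE) {
  if (!round_chain) {
    return(threshold_diameter("TM3", channel) * 1e6)
  }
  t1 <- round_threshold_um(threshold_diameter("TM1", channel))
  t2 <- round_threshold_um(threshold_diameter("TM2", channel))
  (t1 + 3 * t2) / 4
}
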