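# Channel geometry, fluid description and the dimensionless flow
# quantities used by every downstream module.

#' Rectangular spiral channel geometry
#'
#' Describes a spiral (curvilinear) microchannel with a rectangular
#' cross-section whose end is evenly split into `n_outlets` outlets.
#' All lengths are SI metres; use [um()] / [mm()] for convenience.
#'
#' @param width channel width w (m), the longer cross-section side for
#'   high-aspect-ratio devices.
#' @param height channel height h (m).
#' @param spiral_radius radius of curvature R of the channel path (m).
#'   Devices rarely quote a single value; a mid-spiral radius is the
#'   conventional choice.
#' @param n_loops number of spiral loops.
#' @param loop_spacing spacing between consecutive loops (m).
#' @param n_outlets number of outlets (>= 2).
#' @param outlet_width width of one outlet (m); must satisfy
#'   `n_outlets * outlet_width == width` (the outlets evenly split the
#'   channel width).
#' @return an object of class `rect_channel`.
#' @seealso [hydraulic_diameter()], [example_channel()]
#' @export
rect_channel <- function(width, height, spiral_radius,
                         n_loops = 10L, loop_spacing = um(300),
                         n_outlets = 5L, outlet_width = width / n_outlets) {
  for (nm in c("width", "height", "spiral_radius", "loop_spacing",
               "outlet_width")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid geometry: '", nm, "' must be a positive finite number",
           call. = FALSE)
    }
  }
  n_outlets <- as.integer(n_outlets)
  if (n_outlets < 2L) stop("invalid geometry: n_outlets must be >= 2",
                           call. = FALSE)
  if (abs(n_outlets * outlet_width - width) > 1e-9 * width) {
    stop("invalid geometry: n_outlets * outlet_width must equal width",
         call. = FALSE)
  }
  structure(list(width = width, height = height,
                 spiral_radius = spiral_radius,
                 n_loops = as.integer(n_loops), loop_spacing = loop_spacing,
                 n_outlets = n_outlets, outlet_width = outlet_width),
            class = "rect_channel")
}

#' @export
print.rect_channel <- function(x, ...) {
  cat(sprintf(
    "Rectangular spiral channel: w = %.1f um, h = %.1f um, R = %.2f mm\n",
    x$width * 1e6, x$height * 1e6, x$spiral_radius * 1e3))
  cat(sprintf("  %d loops (%.0f um spacing), %d outlets x %.0f um\n",
              x$n_loops, x$loop_spacing * 1e6, x$n_outlets,
              x$outlet_width * 1e6))
  cat(sprintf("  hydraulic diameter D = %.2f um\n",
              hydraulic_diameter(x) * 1e6))
  invisible(x)
}

#' Reference spiral device geometry
#'
#' The 10-loop rectangular spiral used in all worked examples: 500 um wide,
#' 220 um high, 300 um loop spacing, five 100 um outlets. The spiral radius
#' is not part of the published device description; the default of 5 mm is
#' a mid-spiral scale consistent with 10 loops at 300 um spacing, and every
#' Dean-number-dependent output carries the radius actually used.
#'
#' @param spiral_radius radius of curvature (m), default 5 mm.
#' @return a [rect_channel()] object.
#' @export
example_channel <- function(spiral_radius = mm(5)) {
  rect_channel(width = um(500), height = um(220),
               spiral_radius = spiral_radius,
               n_loops = 10L, loop_spacing = um(300),
               n_outlets = 5L, outlet_width = um(100))
}

#' Fluid properties
#'
#' @param density fluid density rho_f (kg/m^3).
#' @param viscosity dynamic viscosity mu (Pa.s).
#' @return an object of class `fluid`.
#' @export
fluid <- function(density, viscosity) {
  if (!is.numeric(density) || density <= 0 || !is.finite(density)) {
    stop("fluid density must be positive", call. = FALSE)
  }
  if (!is.numeric(viscosity) || viscosity <= 0 || !is.finite(viscosity)) {
    stop("fluid viscosity must be positive", call. = FALSE)
  }
  structure(list(density = density, viscosity = viscosity), class = "fluid")
}

#' Water at room temperature (rho = 1000 kg/m^3, mu = 1e-3 Pa.s)
#' @return a [fluid()] object.
#' @export
water <- function() fluid(density = 1000, viscosity = 1e-3)

#' Hydraulic diameter of a rectangular duct
#'
#' D = 2hw/(h + w), the harmonic-mean characteristic length of the
#' cross-section; always between min(w, h) and max(w, h).
#'
#' @param channel a [rect_channel()].
#' @return hydraulic diameter (m).
#' @export
hydraulic_diameter <- function(channel) {
  stopifnot(inherits(channel, "rect_channel"))
  2 * channel$height * channel$width / (channel$height + channel$width)
}

#' Mean cross-section velocity from a volumetric flow rate
#'
#' U = Q / (w h). The velocity entering the Reynolds number here is the
#' cross-section mean; the published operating point (1.7 ml/min in the
#' reference device) corresponds to 0.257 m/s under exactly this
#' convention.
#'
#' @param Q volumetric flow rate (m^3/s); use [ml_min()] to convert.
#' @param channel a [rect_channel()].
#' @return mean velocity (m/s).
#' @export
mean_velocity <- function(Q, channel) {
  stopifnot(inherits(channel, "rect_channel"))
  if (!is.numeric(Q) || any(Q < 0)) {
    stop("flow rate Q must be non-negative", call. = FALSE)
  }
  Q / (channel$width * channel$height)
}

#' Channel Reynolds number
#'
#' Re = rho_f U D / mu. Inertial focusing is effective roughly for
#' 1 < Re < 100.
#'
#' @param fluid a [fluid()].
#' @param U velocity (m/s).
#' @param D characteristic length, normally the hydraulic diameter (m).
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(fluid, U, D) {
  stopifnot(inherits(fluid, "fluid"))
  if (!is.numeric(D) || any(D <= 0)) stop("D must be positive",
                                          call. = FALSE)
  fluid$density * U * D / fluid$viscosity
}

#' Flow rate producing a target Reynolds number
#'
#' Inverse of [reynolds()] composed with [mean_velocity()]: returns the Q
#' such that `reynolds(fluid, mean_velocity(Q, channel), D) == Re_target`
#' with D the channel hydraulic diameter.
#'
#' @param Re_target target Reynolds number (> 0).
#' @param fluid a [fluid()].
#' @param channel a [rect_channel()].
#' @return flow rate (m^3/s).
#' @export
flow_rate_for_reynolds <- function(Re_target, fluid, channel) {
  if (!is.numeric(Re_target) || any(Re_target <= 0)) {
    stop("Re_target must be positive", call. = FALSE)
  }
  D <- hydraulic_diameter(channel)
  U <- Re_target * fluid$viscosity / (fluid$density * D)
  U * channel$width * channel$height
}

#' Dean number
#'
#' De = Re sqrt(D / 2R), the dimensionless strength of the secondary
#' (Dean) flow in a curved channel. De <= Re whenever D <= 2R.
#'
#' @param Re channel Reynolds number.
#' @param D hydraulic diameter (m).
#' @param R radius of curvature of the channel path (m).
#' @return dimensionless Dean number.
#' @export
dean_number <- function(Re, D, R) {
  if (!is.numeric(R) || any(R <= 0)) {
    stop("invalid geometry: radius of curvature R must be positive",
         call. = FALSE)
  }
  Re * sqrt(D / (2 * R))
}

#' Lateral Dean velocity
#'
#' Empirical correlation U_D = 1.8e-4 * De^1.63, with U_D in m/s and De
#' dimensionless; the secondary-flow speed at which unfocused particles are
#' carried back and forth across the channel width.
#'
#' @param De Dean number (>= 0).
#' @return Dean velocity (m/s).
#' @export
dean_velocity <- function(De) {
  if (!is.numeric(De) || any(De < 0)) stop("De must be non-negative",
                                           call. = FALSE)
  1.8e-4 * De^1.63
}

#' Bundle of flow quantities for a channel at a given flow rate
#'
#' @param Q flow rate (m^3/s).
#' @param channel a [rect_channel()].
#' @param fluid a [fluid()]; default water.
#' @return an object of class `flow_condition` with fields `flow_rate`,
#'   `velocity`, `reynolds`, `dean`, `dean_velocity`, `hydraulic_diameter`
#'   and `spiral_radius` (the R used for De).
#' @export
flow_condition <- function(Q, channel, fluid = water()) {
  U <- mean_velocity(Q, channel)
  D <- hydraulic_diameter(channel)
  Re <- reynolds(fluid, U, D)
  De <- dean_number(Re, D, channel$spiral_radius)
  structure(list(flow_rate = Q, velocity = U, reynolds = Re, dean = De,
                 dean_velocity = dean_velocity(De), hydraulic_diameter = D,
                 spiral_radius = channel$spiral_radius),
            class = "flow_condition")
}

#' @export
print.flow_condition <- function(x, ...) {
  cat(sprintf("Flow condition (R = %.2f mm used for De):\n",
              x$spiral_radius * 1e3))
  cat(sprintf("  Q   = %.4g ml/min\n", x$flow_rate / (1e-6 / 60)))
  cat(sprintf("  U   = %.4f m/s\n", x$velocity))
  cat(sprintf("  D   = %.2f um\n", x$hydraulic_diameter * 1e6))
  cat(sprintf("  Re  = %.2f\n", x$reynolds))
  cat(sprintf("  De  = %.2f\n", x$dean))
  cat(sprintf("  U_D = %.4g m/s\n", x$dean_velocity))
  invisible(x)
}
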