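# Forces on a suspended particle in a curved channel: inertial lift,
# Dean drag and the density-difference centrifugal force, plus the
# balance diagnostics used to reason about focusing.

#' Particle specification
#'
#' @param diameter particle diameter a (m); for irregular particles the
#'   circular-equivalent diameter (see [circular_diameter()]).
#' @param density particle density rho_p (kg/m^3); use [g_ml()].
#' @param circularity shape descriptor 4*pi*A/P^2 in (0, 1]; 1 for a
#'   sphere. Recorded for provenance; the current migration model does not
#'   use it (shape has only a small effect on inertial focusing unless
#'   asymmetry is large).
#' @param label free-text label, e.g. `"PS"`, `"iTalc"`.
#' @return an object of class `particle_spec`.
#' @export
particle_spec <- function(diameter, density, circularity = 1,
                          label = "particle") {
  if (!is.numeric(diameter) || diameter <= 0) {
    stop("particle diameter must be positive", call. = FALSE)
  }
  if (!is.numeric(density) || density <= 0) {
    stop("particle density must be positive", call. = FALSE)
  }
  if (!is.numeric(circularity) || circularity <= 0 || circularity > 1) {
    stop("circularity must lie in (0, 1]", call. = FALSE)
  }
  structure(list(diameter = diameter, density = density,
                 circularity = circularity, label = label),
            class = "particle_spec")
}

#' Context parameters for force evaluation
#'
#' The lift coefficient C_L is a function of particle position with no
#' closed form; it enters as an explicit parameter (default magnitude 0.5).
#' V is the particle's tangential velocity (defaulting to the mean flow
#' velocity at the call site) and r the radius of its trajectory
#' (defaulting to the channel spiral radius).
#'
#' @param lift_coefficient C_L, magnitude in (0, 1].
#' @param tangential_velocity V (m/s), >= 0.
#' @param trajectory_radius r (m), > 0.
#' @return an object of class `force_context`.
#' @export
force_context <- function(lift_coefficient = 0.5,
                          tangential_velocity = 0,
                          trajectory_radius = mm(5)) {
  if (abs(lift_coefficient) <= 0 || abs(lift_coefficient) > 1) {
    stop("lift coefficient magnitude must lie in (0, 1]", call. = FALSE)
  }
  if (tangential_velocity < 0) stop("tangential velocity must be >= 0",
                                    call. = FALSE)
  if (trajectory_radius <= 0) stop("trajectory radius must be positive",
                                   call. = FALSE)
  structure(list(lift_coefficient = lift_coefficient,
                 tangential_velocity = tangential_velocity,
                 trajectory_radius = trajectory_radius),
            class = "force_context")
}

#' Net inertial lift force
#'
#' F_L = C_L rho_f U^2 a^4 / D^2 — the resultant of the shear-gradient and
#' wall-induced lift forces, scaling with the fourth power of particle
#' diameter. The fluid-density factor makes the expression dimensionally a
#' force.
#'
#' @param ctx a [force_context()] supplying C_L.
#' @param fluid a [fluid()].
#' @param U velocity scale (m/s).
#' @param a particle diameter (m).
#' @param D hydraulic diameter (m).
#' @return lift force (N).
#' @export
lift_force <- function(ctx, fluid, U, a, D) {
  stopifnot(inherits(ctx, "force_context"), inherits(fluid, "fluid"))
  if (any(D <= 0)) stop("D must be positive", call. = FALSE)
  ctx$lift_coefficient * fluid$density * U^2 * a^4 / D^2
}

#' Dean drag force
#'
#' Stokes drag exerted by the secondary flow: F_D = 3 pi mu U_D a, linear
#' in particle diameter.
#'
#' @param fluid a [fluid()] supplying mu.
#' @param U_D Dean velocity (m/s), see [dean_velocity()].
#' @param a particle diameter (m).
#' @return drag force (N).
#' @export
dean_drag_force <- function(fluid, U_D, a) {
  stopifnot(inherits(fluid, "fluid"))
  if (any(U_D < 0)) stop("U_D must be non-negative", call. = FALSE)
  3 * pi * fluid$viscosity * U_D * a
}

#' Centrifugal force on a particle in the curved channel
#'
#' F_c = (rho_p - rho_f) pi V^2 a^3 / (6 r). Zero at neutral buoyancy,
#' negative for particles lighter than the fluid; non-negligible for dense
#' particles such as talc.
#'
#' @param particle a [particle_spec()].
#' @param fluid a [fluid()].
#' @param ctx a [force_context()] supplying V and r.
#' @return centrifugal force (N), signed.
#' @export
centrifugal_force <- function(particle, fluid, ctx) {
  stopifnot(inherits(particle, "particle_spec"), inherits(fluid, "fluid"),
            inherits(ctx, "force_context"))
  (particle$density - fluid$density) * pi * ctx$tangential_velocity^2 *
    particle$diameter^3 / (6 * ctx$trajectory_radius)
}

#' Lift-to-drag focusing ratio
#'
#' R_f = F_L / F_D; proportional to a^3 when both forces come from the
#' same particle. Particles focus where R_f is order one or larger.
#'
#' @param F_L lift force (N).
#' @param F_D drag force (N), strictly positive.
#' @return dimensionless ratio.
#' @export
focusing_ratio <- function(F_L, F_D) {
  if (any(F_D == 0)) {
    stop("focusing ratio undefined: Dean drag force is zero", call. = FALSE)
  }
  F_L / F_D
}

#' Lift force required to focus a particle against drag and centrifugal force
#'
#' For near-neutral particles focusing requires F_L = F_D; for denser
#' particles the centrifugal force opposes lift in the inner cross-section
#' and the requirement becomes F_L = F_D + F_c. Buoyant particles
#' (rho_p < rho_f) are not helped beyond the drag balance, so the
#' centrifugal contribution is floored at zero.
#'
#' @param particle a [particle_spec()].
#' @param fluid a [fluid()].
#' @param ctx a [force_context()].
#' @param U_D Dean velocity (m/s).
#' @return required lift force (N): `F_D + max(F_c, 0)`.
#' @export
required_lift_for_focus <- function(particle, fluid, ctx, U_D) {
  F_D <- dean_drag_force(fluid, U_D, particle$diameter)
  F_c <- centrifugal_force(particle, fluid, ctx)
  F_D + max(F_c, 0)
}
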