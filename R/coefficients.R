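#' Wind-tunnel air and flow conditions
#'
#' @param U free-stream speed (m/s).  The default 6 m/s together with
#'   the default air properties and an 0.08 m snout-vent length gives
#'   the model-scale Reynolds number of 32,000 used in the study.
#' @param rho air density (kg/m^3), default 1.204 (20 C).
#' @param nu kinematic viscosity of air (m^2/s), default 1.5e-5.
#' @return an object of class `"tunnel_conditions"`.
#' @export
tunnel_conditions <- function(U = 6, rho = 1.204, nu = 1.5e-5) {
  check_positive(c(U, rho, nu), "tunnel conditions")
  structure(list(U = U, rho = rho, nu = nu), class = "tunnel_conditions")
}

#' Model reference geometry
#'
#' @param S reference planform area (m^2).  By the package's reference
#'   policy this is the planform area of the four-winged sprawled
#'   baseline for every posture (see [reference_area_policy()]).
#' @param lambda snout-vent length (m), the moment reference length.
#' @param scale geometric scale factor, model length / full-scale length.
#' @return an object of class `"model_geometry"`.
#' @export
model_geometry <- function(S = 0.012, lambda = 0.08, scale = 0.2) {
  check_positive(c(S, lambda, scale), "geometry")
  structure(list(S = S, lambda = lambda, scale = scale),
            class = "model_geometry")
}

#' Full-scale body description
#'
#' Holds the quantities needed to project model coefficients to the
#' animal: weight, full-scale planform area and snout-vent length, and
#' a reference flight speed.
#'
#' @param weight full-scale body weight (N).  The study's mass estimate
#'   bracket is 1-1.4 kg; the default is the 1.2 kg midpoint times g.
#' @param area full-scale planform area (m^2).
#' @param length full-scale snout-vent length (m).
#' @param speed reference full-scale speed (m/s).
#' @return an object of class `"body_scale"`.
#' @export
body_scale <- function(weight = 1.2 * 9.81, area = 0.3, length = 0.4,
                       speed = 12) {
  check_positive(c(weight, area, length, speed), "body scale")
  structure(list(weight = weight, area = area, length = length,
                 speed = speed),
            class = "body_scale")
}

#' The six aerodynamic coefficients of one configuration
#'
#' Lift, drag and side-force coefficients \eqn{C_L, C_D, C_Y} and
#' roll/pitch/yaw moment coefficients \eqn{C_l, C_m, C_n}.  Forces are
#' normalized by dynamic pressure times reference area
#' (\eqn{F / (\tfrac12 \rho U^2 S)}); moments carry an extra factor of
#' the snout-vent length \eqn{\lambda}.
#'
#' @param CL,CD,CY,Cl,Cm,Cn the six coefficients (dimensionless).
#' @return an object of class `"aero_coefficients"`.
#' @export
aero_coefficients <- function(CL = 0, CD = 0, CY = 0, Cl = 0, Cm = 0, Cn = 0) {
  v <- c(CL = CL, CD = CD, CY = CY, Cl = Cl, Cm = Cm, Cn = Cn)
  check_finite(v, "aerodynamic coefficients")
  if (CD < 0)
    warning("negative drag coefficient: check frame convention or tare",
            call. = FALSE)
  structure(as.list(v), class = "aero_coefficients")
}

#' @export
print.aero_coefficients <- function(x, ...) {
  v <- unlist(x)
  cat("aerodynamic coefficients:\n")
  print(signif(v, 5))
  invisible(x)
}

#' Nondimensionalize a mean tunnel-frame wrench
#'
#' Converts a tunnel-frame mean wrench into the six aerodynamic
#' coefficients using the dynamic pressure \eqn{q = \tfrac12 \rho U^2},
#' the reference area \eqn{S} and (for moments) the snout-vent length
#' \eqn{\lambda}:
#' \deqn{C_L = L/(qS),\; C_D = D/(qS),\; C_Y = Y/(qS),\quad
#'       C_l = l/(qS\lambda),\; C_m = m/(qS\lambda),\; C_n = n/(qS\lambda).}
#'
#' @param w a tunnel-frame mean [wrench()].
#' @param conditions a [tunnel_conditions()].
#' @param geometry a [model_geometry()].
#' @return an [aero_coefficients()] object.
#' @export
nondimensionalize <- function(w, conditions, geometry) {
  stopifnot(inherits(w, "wrench"), inherits(conditions, "tunnel_conditions"),
            inherits(geometry, "model_geometry"))
  if (w$frame != "tunnel")
    stop_invalid("wrench must be in the tunnel frame; call to_tunnel_frame()")
  q <- 0.5 * conditions$rho * conditions$U^2
  if (q <= 0) stop_invalid("dynamic pressure must be positive")
  S <- geometry$S; lam <- geometry$lambda
  # tunnel frame: x upstream, y starboard, z down
  aero_coefficients(
    CL = -w$force[3] / (q * S),
    CD = -w$force[1] / (q * S),
    CY = w$force[2] / (q * S),
    Cl = w$moment[1] / (q * S * lam),
    Cm = w$moment[2] / (q * S * lam),
    Cn = w$moment[3] / (q * S * lam))
}

#' Project coefficients to full-scale forces and moments
#'
#' Inverts [nondimensionalize()] at full-scale area, length and speed:
#' dimensional loads on the animal at the reference flight speed.
#' `to_full_scale()` composed with `nondimensionalize()` at identical
#' conditions is the identity.
#'
#' @param a an [aero_coefficients()] object.
#' @param body a [body_scale()].
#' @param rho air density (kg/m^3).
#' @param speed optional speed override (m/s); defaults to `body$speed`.
#' @return a tunnel-frame [wrench()] of full-scale loads.
#' @export
to_full_scale <- function(a, body, rho = 1.204, speed = NULL) {
  stopifnot(inherits(a, "aero_coefficients"), inherits(body, "body_scale"))
  U <- speed %||% body$speed
  check_positive(c(rho, U), "full-scale conditions")
  q <- 0.5 * rho * U^2
  S <- body$area; lam <- body$length
  wrench(force = c(-a$CD * q * S, a$CY * q * S, -a$CL * q * S),
         moment = c(a$Cl, a$Cm, a$Cn) * q * S * lam,
         frame = "tunnel")
}

#' Reference-area policy across postures
#'
#' To compare absolute forces and moments across postures, all
#' coefficients are referenced to the planform area of a single
#' baseline configuration — the four-winged sprawled posture — rather
#' than to each posture's own area.  The per-posture alternative is
#' available as a documented override.
#'
#' @param posture_areas named numeric vector of planform areas (m^2),
#'   one per posture.
#' @param baseline name of the baseline posture whose area becomes the
#'   common reference (default `"sprawled"`).
#' @param per_posture if `TRUE`, each posture keeps its own area
#'   (non-default override).
#' @return named numeric vector of reference areas, one per posture.
#' @examples
#' reference_area_policy(c(sprawled = 0.012, tent = 0.010))
#' @export
reference_area_policy <- function(posture_areas, baseline = "sprawled",
                                  per_posture = FALSE) {
  check_positive(posture_areas, "posture areas")
  if (is.null(names(posture_areas)) || any(!nzchar(names(posture_areas))))
    stop_invalid("posture_areas must be a named vector")
  if (per_posture) return(posture_areas)
  if (!baseline %in% names(posture_areas)) {
    if (length(posture_areas) == 1L) return(posture_areas)
    stop_invalid("baseline posture '%s' missing from posture_areas", baseline)
  }
  ref <- rep(posture_areas[[baseline]], length(posture_areas))
  names(ref) <- names(posture_areas)
  ref
}
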