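#' Equilibrium glide from trim coefficients
#'
#' For a steady glide, the resultant aerodynamic force balances body
#' weight.  With trim coefficients \eqn{C_L, C_D} and resultant
#' \eqn{C_R = \sqrt{C_L^2 + C_D^2}}, the glide angle below horizontal
#' is \eqn{\gamma = \arctan(C_D / C_L)} and the equilibrium speed is
#' \deqn{V = \sqrt{2 W / (\rho S C_R)}.}
#' The resultant balance is the default because the high glide angles
#' studied are far from the small-angle regime; a pure-lift balance
#' \eqn{V = \sqrt{2 W \cos\gamma/(\rho S C_L)}} is available.  If
#' `fixed_speed` is given, the solution instead reports whether the
#' configuration can support the weight at that speed (the biplane
#' posture at the study's reference speed cannot).
#'
#' @param a an [aero_coefficients()] at the trim angle of attack.
#' @param body a [body_scale()].
#' @param rho air density (kg/m^3).
#' @param balance `"resultant"` (default) or `"lift"`.
#' @param fixed_speed optional imposed speed (m/s) for the feasibility
#'   check.
#' @param trim_alpha optional trim angle of attack (deg), carried
#'   through for reporting.
#' @return object of class `"glide_solution"`: list with `V` (m/s),
#'   `gamma` (deg below horizontal), `alpha` (deg or NA), `feasible`,
#'   `balance`, `CR`.
#' @export
equilibrium_glide <- function(a, body, rho = 1.204,
                              balance = c("resultant", "lift"),
                              fixed_speed = NULL, trim_alpha = NA_real_) {
  stopifnot(inherits(a, "aero_coefficients"), inherits(body, "body_scale"))
  balance <- match.arg(balance)
  check_positive(rho, "rho")
  CR <- sqrt(a$CL^2 + a$CD^2)
  if (CR <= 0) stop_invalid("resultant coefficient is zero: no glide solution")
  gamma <- rad2deg(atan2(a$CD, a$CL))
  W <- body$weight; S <- body$area
  V <- switch(balance,
              resultant = sqrt(2 * W / (rho * S * CR)),
              lift = sqrt(2 * W * cos(deg2rad(gamma)) / (rho * S * a$CL)))
  feasible <- TRUE
  if (!is.null(fixed_speed)) {
    check_positive(fixed_speed, "fixed_speed")
    feasible <- 0.5 * rho * fixed_speed^2 * S * CR >= W
    V <- fixed_speed
  }
  structure(list(V = V, gamma = gamma, alpha = trim_alpha,
                 feasible = feasible, balance = balance, CR = CR),
            class = "glide_solution")
}

#' @export
print.glide_solution <- function(x, ...) {
  cat(sprintf(paste0("equilibrium glide (%s balance): V = %.3g m/s, ",
                     "glide angle %.3g deg%s%s\n"),
              x$balance, x$V, x$gamma,
              if (is.na(x$alpha)) "" else sprintf(", alpha %.3g deg", x$alpha),
              if (x$feasible) "" else " [weight NOT supportable at this speed]"))
  invisible(x)
}

#' Comparative glide and parachuting performance metrics
#'
#' Computes the classic single-number performance metrics over a pitch
#' sweep, each annotated with whether its optimal angle of attack
#' coincides with a statically stable trim — in the study none of the
#' optima did, which is why these simplified metrics are reported only
#' for comparison with earlier literature.
#'
#' Metrics: maximum lift-to-drag ratio (optimizes steady glide
#' distance); minimum glide speed
#' \eqn{V_{min} = \sqrt{2W/(\rho S C_{R,max})}} (ease of initiating a
#' glide); full-scale parachuting drag at straight-down orientation
#' (\eqn{\alpha = 90^\circ}) and reference speed; the dimensionless
#' parachuting index \eqn{C_D(90^\circ)}; and terminal velocity
#' \eqn{V_t = \sqrt{2W/(\rho S C_D(90^\circ))}}.
#'
#' @param s a pitch [assemble_sweep()], spanning alpha = 90 deg if the
#'   parachuting metrics are wanted.
#' @param body a [body_scale()].
#' @param rho air density (kg/m^3).
#' @param trim optional [find_trim_points()] table for the same sweep,
#'   used for the stability annotations.
#' @param stable_within angular tolerance (deg) for "optimum coincides
#'   with a stable trim".
#' @return object of class `"performance_metrics"`: list of metrics
#'   with their optimal angles and `*_stable` flags.
#' @export
performance_metrics <- function(s, body, rho = 1.204, trim = NULL,
                                stable_within = 2.5) {
  stopifnot(inherits(s, "aero_sweep"), inherits(body, "body_scale"))
  if (s$var != "pitch")
    stop_invalid("performance metrics require a pitch (angle of attack) sweep")
  CL <- sweep_mean_curve(s, "CL")
  CD <- sweep_mean_curve(s, "CD")
  grid <- s$grid
  LD <- CL / CD
  i_ld <- which.max(LD)
  CR <- sqrt(CL^2 + CD^2)
  i_cr <- which.max(CR)
  W <- body$weight; S <- body$area
  stable_alphas <- if (!is.null(trim) && nrow(trim))
    trim$angle[trim$class == "stable"] else numeric(0)
  near_stable <- function(alpha) {
    length(stable_alphas) > 0 && any(abs(stable_alphas - alpha) <= stable_within)
  }
  out <- list(
    LD_max = LD[i_ld], LD_max_alpha = grid[i_ld],
    LD_max_stable = near_stable(grid[i_ld]),
    V_min = sqrt(2 * W / (rho * S * CR[i_cr])),
    V_min_alpha = grid[i_cr],
    V_min_stable = near_stable(grid[i_cr]))
  i90 <- which(grid == 90)
  if (length(i90) == 1L) {
    CD90 <- CD[i90]
    q_ref <- 0.5 * rho * body$speed^2
    out$parachute_drag <- q_ref * S * CD90
    out$parachute_index <- CD90
    out$terminal_velocity <- sqrt(2 * W / (rho * S * CD90))
    out$parachute_stable <- near_stable(90)
  } else {
    warning("sweep does not include alpha = 90 deg; parachuting metrics omitted",
            call. = FALSE)
  }
  structure(out, class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  flag <- function(f) if (isTRUE(f)) " (at stable trim)" else " (not stable)"
  cat(sprintf("max L/D        : %.3g at alpha %g deg%s\n",
              x$LD_max, x$LD_max_alpha, flag(x$LD_max_stable)))
  cat(sprintf("min glide speed: %.3g m/s at alpha %g deg%s\n",
              x$V_min, x$V_min_alpha, flag(x$V_min_stable)))
  if (!is.null(x$parachute_drag)) {
    cat(sprintf("parachuting    : drag %.3g N (index C_D = %.3g)%s\n",
                x$parachute_drag, x$parachute_index, flag(x$parachute_stable)))
    cat(sprintf("terminal speed : %.3g m/s\n", x$terminal_velocity))
  }
  invisible(x)
}

#' Banked and crabbed turning indices
#'
#' Simple maneuvering indices assuming a fixed bank (or crab) angle
#' \eqn{\theta}: for banked turns, part of the lift provides the
#' centripetal force, giving the dimensional index \eqn{L \sin\theta}
#' (N) and its weight-normalized form \eqn{L \sin\theta / W}; for
#' crabbed turns, the horizontal component of side force normalized by
#' weight, \eqn{Y \cos\theta / W}.  The \eqn{\theta = 60^\circ} default
#' follows earlier comparative work and is arbitrary; the horizontal
#' projection on the crabbed index can be disabled.
#'
#' @param a an [aero_coefficients()] object.
#' @param body a [body_scale()].
#' @param rho air density (kg/m^3).
#' @param theta_deg bank / turn angle (deg), in (0, 90).
#' @param speed optional speed override (m/s) for the dimensional lift
#'   and side force; defaults to `body$speed`.
#' @param crab_projection apply the \eqn{\cos\theta} horizontal
#'   projection to the crabbed index (default `TRUE`).
#' @return object of class `"turn_indices"`: list with
#'   `banked_dimensional` (N), `banked` (dimensionless), `crabbed`
#'   (dimensionless), `theta_deg`.
#' @export
turn_indices <- function(a, body, rho = 1.204, theta_deg = 60, speed = NULL,
                         crab_projection = TRUE) {
  stopifnot(inherits(a, "aero_coefficients"), inherits(body, "body_scale"))
  if (theta_deg <= 0 || theta_deg >= 90)
    stop_invalid("theta must lie in (0, 90) deg")
  w <- to_full_scale(a, body, rho = rho, speed = speed)
  L <- -w$force[3]
  Y <- w$force[2]
  th <- deg2rad(theta_deg)
  W <- body$weight
  structure(list(banked_dimensional = L * sin(th),
                 banked = L * sin(th) / W,
                 crabbed = Y * (if (crab_projection) cos(th) else 1) / W,
                 theta_deg = theta_deg),
            class = "turn_indices")
}

#' @export
print.turn_indices <- function(x, ...) {
  cat(sprintf(paste0("turn indices (theta = %g deg): banked %.3g N ",
                     "(%.3g x W), crabbed %.3g x W\n"),
              x$theta_deg, x$banked_dimensional, x$banked, x$crabbed))
  invisible(x)
}
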