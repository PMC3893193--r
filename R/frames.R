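#' Model orientation in the wind tunnel
#'
#' Bundles the three mounting angles of a model on the sting: roll
#' \eqn{\phi}, pitch / angle of attack \eqn{\alpha}, and yaw \eqn{\psi},
#' all in degrees.  The package uses one fixed axis convention
#' throughout (see [rotation_matrix()]): body x forward along the body
#' axis (upstream at zero orientation), y starboard, z completing the
#' right-handed triad (down).  Positive rotations are starboard-wing-down
#' roll, nose-up pitch, and nose-starboard yaw.
#'
#' @param roll,pitch,yaw angles in degrees.  `pitch` must lie in
#'   \[-90, 180\]; `roll` and `yaw` in \[-180, 180\].
#' @return an object of class `"orientation"`.
#' @examples
#' orientation(pitch = 35)
#' @export
orientation <- function(roll = 0, pitch = 0, yaw = 0) {
  check_finite(c(roll, pitch, yaw), "orientation angles")
  if (pitch < -90 || pitch > 180)
    stop_invalid("pitch must lie in [-90, 180] deg (got %g)", pitch)
  if (abs(roll) > 180 || abs(yaw) > 180)
    stop_invalid("roll and yaw must lie in [-180, 180] deg")
  structure(list(roll = roll, pitch = pitch, yaw = yaw),
            class = "orientation")
}

#' @export
print.orientation <- function(x, ...) {
  cat(sprintf("orientation: roll %g deg, pitch %g deg, yaw %g deg\n",
              x$roll, x$pitch, x$yaw))
  invisible(x)
}

#' Six-component force/torque measurement (wrench)
#'
#' A wrench is a force 3-vector (N) and moment 3-vector (N m) tagged
#' with the frame it is expressed in: `"sensor"` (fixed to the model)
#' or `"tunnel"` (aligned with the free stream).  In the tunnel frame
#' the components map onto the aerodynamic forces and moments as
#' drag \eqn{D = -F_x}, side force \eqn{Y = F_y}, lift \eqn{L = -F_z},
#' and roll/pitch/yaw moments \eqn{l = M_x}, \eqn{m = M_y},
#' \eqn{n = M_z} (z points down, so lift up is negative \eqn{F_z}).
#'
#' @param force numeric length-3 force vector (N).
#' @param moment numeric length-3 moment vector (N m).
#' @param frame `"sensor"` or `"tunnel"`.
#' @return an object of class `"wrench"`.
#' @export
wrench <- function(force, moment = c(0, 0, 0), frame = c("sensor", "tunnel")) {
  frame <- match.arg(frame)
  if (length(force) != 3L || length(moment) != 3L)
    stop_invalid("force and moment must each have 3 components")
  check_finite(force, "force")
  check_finite(moment, "moment")
  structure(list(force = as.numeric(force), moment = as.numeric(moment),
                 frame = frame),
            class = "wrench")
}

#' @export
print.wrench <- function(x, ...) {
  cat(sprintf("wrench [%s frame]\n  force  (N):   %s\n  moment (N m): %s\n",
              x$frame,
              paste(signif(x$force, 6), collapse = ", "),
              paste(signif(x$moment, 6), collapse = ", ")))
  invisible(x)
}

#' Euler rotation matrix for a model orientation
#'
#' Builds the direction-cosine matrix taking sensor (body) frame vectors
#' into the tunnel frame, as the composition
#' \eqn{R = R_z(\psi)\,R_y(\alpha)\,R_x(\phi)} — intrinsic
#' yaw-pitch-roll (aerospace Z-Y'-X'') with right-handed axes
#' (x forward, y starboard, z down).  This convention is a single fixed
#' constant of the package; all reductions and the simulator share it.
#'
#' @param o an [orientation()].
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @examples
#' rotation_matrix(orientation()) # identity
#' @export
rotation_matrix <- function(o) {
  stopifnot(inherits(o, "orientation"))
  phi <- deg2rad(o$roll); alpha <- deg2rad(o$pitch); psi <- deg2rad(o$yaw)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(phi), sin(phi),
                 0, -sin(phi), cos(phi)), 3, 3)
  Ry <- matrix(c(cos(alpha), 0, -sin(alpha),
                 0, 1, 0,
                 sin(alpha), 0, cos(alpha)), 3, 3)
  Rz <- matrix(c(cos(psi), sin(psi), 0,
                 -sin(psi), cos(psi), 0,
                 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotate a sensor-frame wrench into the tunnel frame
#'
#' Applies [rotation_matrix()] to both the force and the moment vector.
#' Rotation is an isometry: component norms are preserved.
#'
#' @param w a sensor-frame [wrench()].
#' @param o the model [orientation()] during the recording.
#' @return a tunnel-frame [wrench()].
#' @export
to_tunnel_frame <- function(w, o) {
  stopifnot(inherits(w, "wrench"))
  if (w$frame != "sensor")
    stop_invalid("wrench is already in the %s frame", w$frame)
  R <- rotation_matrix(o)
  wrench(drop(R %*% w$force), drop(R %*% w$moment), frame = "tunnel")
}

#' Rotate a tunnel-frame wrench back into the sensor frame
#'
#' Inverse of [to_tunnel_frame()]; used by the simulator to synthesize
#' raw sensor readings from tunnel-frame aerodynamic loads.
#'
#' @inheritParams to_tunnel_frame
#' @return a sensor-frame [wrench()].
#' @export
to_sensor_frame <- function(w, o) {
  stopifnot(inherits(w, "wrench"))
  if (w$frame != "tunnel")
    stop_invalid("wrench is already in the %s frame", w$frame)
  R <- rotation_matrix(o)
  wrench(drop(crossprod(R, w$force)), drop(crossprod(R, w$moment)),
         frame = "sensor")
}

#' Force-balance time-series recording
#'
#' @param samples data frame with numeric columns `Fx, Fy, Fz` (N) and
#'   `Mx, My, Mz` (N m), one row per sample.
#' @param rate sampling rate in Hz (the study hardware sampled at 1000 Hz).
#' @param frame frame tag for the samples, normally `"sensor"`.
#' @return an object of class `"recording"`.
#' @export
recording <- function(samples, rate = 1000, frame = "sensor") {
  cols <- c("Fx", "Fy", "Fz", "Mx", "My", "Mz")
  if (!all(cols %in% names(samples)))
    stop_invalid("samples must have columns %s", paste(cols, collapse = ", "))
  if (nrow(samples) < 1L) stop_invalid("recording must contain >= 1 sample")
  check_positive(rate, "sampling rate")
  structure(list(samples = as.data.frame(samples)[cols], rate = rate,
                 frame = frame, duration = nrow(samples) / rate),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d samples at %g Hz (%.3g s), %s frame\n",
              nrow(x$samples), x$rate, x$duration, x$frame))
  invisible(x)
}

#' Reduce a recording to its mean wrench and per-channel scatter
#'
#' Arithmetic mean per channel over the whole record, with the sample
#' (n-1) standard deviation per channel for replicate-level uncertainty
#' reporting.  With a single sample the sd is `NA`.
#'
#' @param r a [recording()].
#' @return list with elements `mean` (a [wrench()] in the recording's
#'   frame) and `sd` (named numeric, one value per channel).
#' @export
average_recording <- function(r) {
  stopifnot(inherits(r, "recording"))
  m <- vapply(r$samples, mean, numeric(1))
  s <- vapply(r$samples, stats::sd, numeric(1))
  list(mean = wrench(m[1:3], m[4:6], frame = r$frame), sd = s)
}

#' Reynolds number of a test condition
#'
#' \eqn{Re = U \lambda / \nu}: flow speed times reference length over
#' kinematic viscosity.  The study used snout-vent length as the
#' reference length; model tests ran near Re = 32,000 against an
#' estimated full-scale Re of about 200,000, with a 30,000-70,000 sweep
#' confirming coefficient insensitivity in this regime.
#'
#' @param conditions a [tunnel_conditions()].
#' @param length reference length in m (snout-vent length).
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds_number(tunnel_conditions(U = 6), length = 0.08) # 32,000
#' @export
reynolds_number <- function(conditions, length) {
  stopifnot(inherits(conditions, "tunnel_conditions"))
  check_positive(length, "reference length")
  conditions$U * length / conditions$nu
}
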