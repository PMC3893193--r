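# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# Quaternion rotation oracle for the intrinsic yaw-pitch-roll sequence.
quat_mul <- function(p, q) {
  c(p[1] * q[1] - sum(p[2:4] * q[2:4]),
    p[1] * q[2:4] + q[1] * p[2:4] +
      c(p[3] * q[4] - p[4] * q[3],
        p[4] * q[2] - p[2] * q[4],
        p[2] * q[3] - p[3] * q[2]))
}

quat_axis <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  c(cos(a / 2), sin(a / 2) * axis)
}

quat_rotate <- function(v, roll, pitch, yaw) {
  q <- quat_mul(quat_axis(c(0, 0, 1), yaw),
                quat_mul(quat_axis(c(0, 1, 0), pitch),
                         quat_axis(c(1, 0, 0), roll)))
  qc <- c(q[1], -q[2:4])
  out <- quat_mul(quat_mul(q, c(0, v)), qc)
  out[2:4]
}

# Closed-form pitch trims of a two-surface lift-lever model:
# Cm(alpha) = (A/2) * sum_i a_i x_i sin(2 (alpha + i_i)) is a single
# sinusoid R sin(2 alpha + phase), so its zeros sit 90 deg apart at
# alpha = -phase/2 + 90 k.  Returns all roots inside the interval.
two_surface_trim <- function(ax1, i1, ax2, i2, interval = c(-15, 90)) {
  s <- ax1 * sin(2 * i1 * pi / 180) + ax2 * sin(2 * i2 * pi / 180)
  c2 <- ax1 * cos(2 * i1 * pi / 180) + ax2 * cos(2 * i2 * pi / 180)
  base <- atan2(-s, c2) * 180 / pi / 2
  roots <- base + 90 * (-3:3)
  sort(roots[roots >= interval[1] & roots <= interval[2]])
}

# Minimal two-surface longitudinal config (no lateral offsets).
two_surface_config <- function(ax_fore = 0.1, i_fore = 0,
                               ax_aft = -0.16, i_aft = -5,
                               A = 2.2, ...) {
  glider_config(list(
    glider_surface("fore", area_frac = 0.5, x_arm = ax_fore / 0.5,
                   incidence = i_fore,
                   controls = list(tail_pitch = list(type = "incidence",
                                                     gain = -1))),
    glider_surface("aft", area_frac = 0.2, x_arm = ax_aft / 0.2,
                   incidence = i_aft)),
    A = A, ...)
}

# Build a tidy coefficient table directly from a deterministic
# coefficient function coef_fun(alpha, delta) -> named list/vector.
coef_table <- function(alphas, deltas = 0, replicates = 1,
                       coef_fun, posture = "tent", appendage = "none") {
  rows <- list()
  for (a in alphas) for (d in deltas) for (r in seq_len(replicates)) {
    co <- coef_fun(a, d)
    rows[[length(rows) + 1L]] <- data.frame(
      run_id = sprintf("r%03d", length(rows) + 1L), posture = posture,
      feathers = TRUE,
      appendage = if (d == 0) "none" else appendage,
      deflection_deg = d, roll_deg = 0, pitch_deg = a, yaw_deg = 0,
      replicate = r, U_ms = 6, Re = 32000,
      CL = co[["CL"]] %||% 0, CD = co[["CD"]] %||% 0.1,
      CY = co[["CY"]] %||% 0, Cl = co[["Cl"]] %||% 0,
      Cm = co[["Cm"]] %||% 0, Cn = co[["Cn"]] %||% 0)
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_equal_tol <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
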