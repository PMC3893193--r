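#' One aerodynamic surface of the synthetic glider
#'
#' The simulator represents the model as a set of thin surfaces (wing
#' pair, leg pair, tail, trunk), each characterized by its area as a
#' fraction of the reference planform area, its moment arms from the
#' center of mass in snout-vent-length units (x positive forward, y
#' positive starboard), an incidence offset relative to the body axis,
#' a side-area fraction (projected lateral area driving side force and
#' weathervane yaw), and a mapping from control channels to how a
#' deflection moves this surface.
#'
#' Control mapping entries are `list(type, gain)` with `type` one of:
#' `"incidence"` (deflection adds `gain * delta` to the surface's
#' pitch-plane local angle), `"side"` (adds to the lateral local
#' angle), `"dihedral"` (tilts the lift vector about the body x axis),
#' `"scale"` (multiplies area by `1 + gain * delta`, floored at 0).
#'
#' @param name surface label.
#' @param area_frac planform area fraction of the reference area S.
#' @param x_arm longitudinal moment arm (snout-vent lengths, + forward).
#' @param y_off lateral offset (snout-vent lengths, + starboard).
#' @param incidence incidence offset (deg) added to the body angle of
#'   attack.
#' @param side_frac lateral projected-area fraction (drives side force
#'   and directional stability).
#' @param dihedral resting dihedral angle (deg, tip-up positive).
#' @param present logical; absent surfaces (feathers removed)
#'   contribute zero force.
#' @param controls named list of control-channel mappings (see above).
#' @return an object of class `"glider_surface"`.
#' @export
glider_surface <- function(name, area_frac, x_arm, y_off = 0, incidence = 0,
                           side_frac = 0, dihedral = 0, present = TRUE,
                           controls = list()) {
  if (area_frac < 0 || side_frac < 0)
    stop_invalid("area fractions must be >= 0")
  structure(list(name = name, area_frac = area_frac, x_arm = x_arm,
                 y_off = y_off, incidence = incidence,
                 side_frac = side_frac, dihedral = dihedral,
                 present = isTRUE(present), controls = controls),
            class = "glider_surface")
}

#' Parametric quasi-steady glider configuration
#'
#' Quasi-steady flat-plate closure: each surface produces a normal
#' force coefficient \eqn{C_N = A \sin\alpha_{loc}} decomposed into
#' lift \eqn{a\,A\sin\alpha_{loc}\cos\alpha_{loc}} and drag
#' \eqn{a\,(C_{D0} + B\sin^2\alpha_{loc})}; side force follows the same
#' law in the lateral plane scaled by the side-area fraction and
#' attenuated by \eqn{\cos\alpha} (at straight-down parachuting the
#' yaw plane is symmetric).  Moments are forces times moment arms
#' (z-offsets are zero): \eqn{C_l = -\sum y_i\,lift_i},
#' \eqn{C_m = \sum x_i\,lift_i}, \eqn{C_n = \sum (y_i\,drag_i + x_i\,C_{Y,i})}.
#' This regime choice (no stall hysteresis, no unsteady terms) matches
#' high-angle-of-attack bluff-body-like flow.
#'
#' The acquisition noise model is additive white Gaussian noise per
#' sensor channel plus a small random mounting misalignment: one
#' orientation offset per run, emulating replicate-to-replicate
#' variation in placing the model on the sting.
#'
#' @param surfaces list of [glider_surface()] objects.
#' @param A flat-plate lift amplitude (default 2.2; peak lift
#'   coefficient A/2 at 45 deg).
#' @param B drag amplitude (default 1.4; drag coefficient at 90 deg is
#'   about CD0 + B).
#' @param CD0 parasitic drag coefficient per unit area fraction.
#' @param roll_stiffness restoring roll moment per sin(roll), default 0
#'   (neutral roll stability by symmetry).
#' @param noise_force_sd per-sample force noise sd (N).
#' @param noise_moment_sd per-sample moment noise sd (N m).
#' @param misalign_sd mounting misalignment sd per run (deg, applied to
#'   all three angles independently).
#' @param rate sampling rate (Hz).
#' @param label configuration label (posture name).
#' @return an object of class `"glider_config"`.
#' @export
glider_config <- function(surfaces, A = 2.2, B = 1.4, CD0 = 0.1,
                          roll_stiffness = 0,
                          noise_force_sd = 5e-3, noise_moment_sd = 2e-4,
                          misalign_sd = 0.25, rate = 1000,
                          label = "custom") {
  stopifnot(all(vapply(surfaces, inherits, logical(1), "glider_surface")))
  if (CD0 < 0 || noise_force_sd < 0 || noise_moment_sd < 0 || misalign_sd < 0)
    stop_invalid("CD0 and noise parameters must be >= 0")
  if (is.null(names(surfaces)))
    names(surfaces) <- vapply(surfaces, `[[`, character(1), "name")
  structure(list(surfaces = surfaces, A = A, B = B, CD0 = CD0,
                 roll_stiffness = roll_stiffness,
                 noise_force_sd = noise_force_sd,
                 noise_moment_sd = noise_moment_sd,
                 misalign_sd = misalign_sd, rate = rate, label = label),
            class = "glider_config")
}

#' @export
print.glider_config <- function(x, ...) {
  cat(sprintf("glider config '%s': %d surfaces (A=%g, B=%g, CD0=%g)\n",
              x$label, length(x$surfaces), x$A, x$B, x$CD0))
  for (s in x$surfaces)
    cat(sprintf("  %-10s a=%.3g x=%+.3g y=%+.3g i=%+.3g%s\n",
                s$name, s$area_frac, s$x_arm, s$y_off, s$incidence,
                if (s$present) "" else " [absent]"))
  invisible(x)
}

# resolve a surface's effective local state under a deflection set
surface_state <- function(surf, deflections) {
  d_inc <- 0; d_side <- 0; d_dih <- 0; scale <- 1
  for (ch in names(surf$controls)) {
    delta <- deflections[ch]
    if (is.na(delta)) next
    ctl <- surf$controls[[ch]]
    g <- ctl$gain
    switch(ctl$type,
           incidence = { d_inc <- d_inc + g * delta },
           side = { d_side <- d_side + g * delta },
           dihedral = { d_dih <- d_dih + g * delta },
           scale = { scale <- scale * max(0, 1 + g * delta) },
           stop_invalid("unknown control type '%s'", ctl$type))
  }
  list(d_inc = d_inc, d_side = d_side, d_dih = d_dih, scale = scale)
}

#' Per-surface coefficient contributions of the quasi-steady closure
#'
#' Evaluates the flat-plate law for one surface at the given body
#' orientation and deflection set.  Used by [body_coefficients()] and
#' exposed for lever-arm checks.
#'
#' @param surf a [glider_surface()].
#' @param cfg a [glider_config()].
#' @param alpha,psi body angle of attack and yaw angle (deg).
#' @param deflections named numeric vector of channel deflections (deg).
#' @return named numeric vector `CL, CD, CY, Cl, Cm, Cn` (contribution
#'   in reference-coefficient units).
#' @export
surface_coefficients <- function(surf, cfg, alpha, psi = 0,
                                 deflections = numeric(0)) {
  stopifnot(inherits(surf, "glider_surface"), inherits(cfg, "glider_config"))
  zero <- c(CL = 0, CD = 0, CY = 0, Cl = 0, Cm = 0, Cn = 0)
  if (!surf$present) return(zero)
  st <- surface_state(surf, deflections)
  a <- surf$area_frac * st$scale
  s <- surf$side_frac * st$scale
  th <- deg2rad(alpha + surf$incidence + st$d_inc)
  ps <- deg2rad(psi + st$d_side)
  dh <- deg2rad(surf$dihedral + st$d_dih)
  lift_raw <- a * cfg$A * sin(th) * cos(th)
  lift <- lift_raw * cos(dh)
  drag <- a * (cfg$CD0 + cfg$B * sin(th)^2)
  cy <- -sign(surf$y_off) * lift_raw * sin(dh) +
    s * cfg$A * sin(ps) * cos(ps) * cos(deg2rad(alpha))
  c(CL = lift, CD = drag, CY = cy,
    Cl = -surf$y_off * lift,
    Cm = surf$x_arm * lift,
    Cn = surf$y_off * drag + surf$x_arm * cy)
}

#' Noise-free body coefficients of a synthetic glider
#'
#' Sums the surface contributions of the quasi-steady closure; this is
#' the analytic ground truth against which the reduction pipeline is
#' tested.  A left-right symmetric configuration at zero yaw with
#' symmetric deflections has exactly zero side force and lateral
#' moments.
#'
#' @param cfg a [glider_config()].
#' @param o an [orientation()] (roll enters only through the optional
#'   `roll_stiffness` restoring term).
#' @param deflections named numeric vector of channel deflections (deg).
#' @return an [aero_coefficients()] object.
#' @export
body_coefficients <- function(cfg, o, deflections = numeric(0)) {
  stopifnot(inherits(cfg, "glider_config"), inherits(o, "orientation"))
  tot <- c(CL = 0, CD = 0, CY = 0, Cl = 0, Cm = 0, Cn = 0)
  for (surf in cfg$surfaces)
    tot <- tot + surface_coefficients(surf, cfg, o$pitch, o$yaw, deflections)
  tot["Cl"] <- tot["Cl"] -
    cfg$roll_stiffness * sin(deg2rad(o$roll)) * cos(deg2rad(o$pitch))
  do.call(aero_coefficients, as.list(tot))
}

#' Analytic pitch trim of a synthetic glider
#'
#' Finds angles of attack where the noise-free pitching moment of the
#' generating model crosses zero, by sign-scanning on a fine grid and
#' root polishing with [stats::uniroot()]; each root carries the
#' analytic local slope and its stability class.  This is the ground
#' truth used to validate [find_trim_points()].
#'
#' @param cfg a [glider_config()].
#' @param deflections named deflection vector (deg).
#' @param interval angle-of-attack search interval (deg).
#' @param tol marginal-stability band for classification (per deg).
#' @return data frame with columns `alpha`, `slope` (per deg), `class`.
#' @export
analytic_pitch_trim <- function(cfg, deflections = numeric(0),
                                interval = c(-15, 90), tol = 1e-3) {
  f <- function(a) body_coefficients(cfg, orientation(pitch = a),
                                     deflections)$Cm
  grid <- seq(interval[1], interval[2], by = 0.5)
  vals <- vapply(grid, f, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1L)) {
    if (vals[i] == 0 && grid[i] > interval[1]) roots <- c(roots, grid[i])
    else if (sign(vals[i]) * sign(vals[i + 1L]) < 0)
      roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1L]),
                                       tol = 1e-10)$root)
  }
  roots <- unique(round(roots, 8))
  slope <- vapply(roots, function(a) analytic_pitch_slope(cfg, a, deflections),
                  numeric(1))
  data.frame(alpha = roots, slope = slope,
             class = if (length(roots)) classify_stability(slope, tol)
             else character(0))
}

#' Analytic static stability slopes of the generating model
#'
#' Closed-form derivatives of the quasi-steady closure: the pitch slope
#' \eqn{dC_m/d\alpha = \sum x_i a_i A \cos(2\theta_i)\cos(d_i)} and yaw
#' slope \eqn{dC_n/d\psi = \sum x_i s_i A \cos(2\psi_i)\cos\alpha},
#' both converted to per-degree.
#'
#' @param cfg a [glider_config()].
#' @param alpha angle of attack (deg).
#' @param deflections named deflection vector (deg).
#' @param psi yaw angle (deg).
#' @return slope in coefficient units per degree.
#' @export
analytic_pitch_slope <- function(cfg, alpha, deflections = numeric(0)) {
  tot <- 0
  for (surf in cfg$surfaces) {
    if (!surf$present) next
    st <- surface_state(surf, deflections)
    a <- surf$area_frac * st$scale
    th <- deg2rad(alpha + surf$incidence + st$d_inc)
    dh <- deg2rad(surf$dihedral + st$d_dih)
    tot <- tot + surf$x_arm * a * cfg$A * cos(2 * th) * cos(dh)
  }
  tot * pi / 180
}

#' @rdname analytic_pitch_slope
#' @export
analytic_yaw_slope <- function(cfg, alpha, psi = 0,
                               deflections = numeric(0)) {
  tot <- 0
  for (surf in cfg$surfaces) {
    if (!surf$present) next
    st <- surface_state(surf, deflections)
    s <- surf$side_frac * st$scale
    ps <- deg2rad(psi + st$d_side)
    tot <- tot + surf$x_arm * s * cfg$A * cos(2 * ps) * cos(deg2rad(alpha))
  }
  tot * pi / 180
}

#' Analytic control-effectiveness derivative of the generating model
#'
#' Closed-form \eqn{\partial C/\partial\delta} at a given operating
#' point, obtained by differentiating the flat-plate closure through
#' each surface's control mapping (incidence, side, dihedral and scale
#' channels).  Ground truth for [control_derivative()] recovery tests.
#'
#' @param cfg a [glider_config()].
#' @param channel control channel name.
#' @param alpha angle of attack (deg).
#' @param axis `"pitch"`, `"yaw"` or `"roll"`.
#' @param psi yaw angle (deg).
#' @param deflections operating-point deflections (deg).
#' @return derivative in coefficient units per degree of deflection.
#' @export
analytic_control_derivative <- function(cfg, channel, alpha,
                                        axis = c("pitch", "yaw", "roll"),
                                        psi = 0, deflections = numeric(0)) {
  axis <- match.arg(axis)
  r <- pi / 180
  tot <- 0
  for (surf in cfg$surfaces) {
    if (!surf$present || !channel %in% names(surf$controls)) next
    st <- surface_state(surf, deflections)
    ctl <- surf$controls[[channel]]
    g <- ctl$gain
    a0 <- surf$area_frac; s0 <- surf$side_frac
    a <- a0 * st$scale; s <- s0 * st$scale
    th <- deg2rad(alpha + surf$incidence + st$d_inc)
    ps <- deg2rad(psi + st$d_side)
    dh <- deg2rad(surf$dihedral + st$d_dih)
    lift_raw <- a * cfg$A * sin(th) * cos(th)
    # per-delta derivatives of the surface's primitive quantities
    da <- 0; dth <- 0; dps <- 0; ddh <- 0
    switch(ctl$type,
           incidence = { dth <- g * r },
           side = { dps <- g * r },
           dihedral = { ddh <- g * r },
           scale = { da <- a0 * g })
    d_lift_raw <- da * cfg$A * sin(th) * cos(th) + a * cfg$A * cos(2 * th) * dth
    d_lift <- d_lift_raw * cos(dh) - lift_raw * sin(dh) * ddh
    d_drag <- da * (cfg$CD0 + cfg$B * sin(th)^2) +
      a * cfg$B * sin(2 * th) * dth
    ds <- if (a0 > 0) s0 * da / a0 else 0  # side area scales with planform
    d_cy <- -sign(surf$y_off) *
      (d_lift_raw * sin(dh) + lift_raw * cos(dh) * ddh) +
      (ds * cfg$A * sin(ps) * cos(ps) + s * cfg$A * cos(2 * ps) * dps) *
      cos(deg2rad(alpha))
    tot <- tot + switch(axis,
                        pitch = surf$x_arm * d_lift,
                        roll = -surf$y_off * d_lift,
                        yaw = surf$y_off * d_drag + surf$x_arm * d_cy)
  }
  tot
}

#' Built-in posture configurations of the synthetic glider
#'
#' Four-surface reconstructions emulating the study's posture set:
#' `"sprawled"` (fore/aft area balanced; marginally stable in pitch),
#' `"tent"` (legs extended caudad as a hindwing; stable pitch trim near
#' 27 deg), `"biplane"` (legs tucked under the wings; stable trim near
#' 16 deg), and `"down"` (legs hanging; center of pressure ahead of the
#' center of mass, never stable).  `feathers = FALSE` removes the leg
#' and tail surfaces, which eliminates both their stability
#' contribution and their control effectiveness.
#'
#' @param posture one of `"sprawled"`, `"tent"`, `"biplane"`, `"down"`.
#' @param feathers leg/tail feathers present?
#' @param ... overrides passed on to [glider_config()].
#' @return a [glider_config()].
#' @export
preset_config <- function(posture = c("sprawled", "tent", "biplane", "down"),
                          feathers = TRUE, ...) {
  posture <- match.arg(posture)
  wing_ctl <- function(side) {
    # side: +1 starboard, -1 port; asymmetric channels act in opposition
    list(wing_pronation_sym = list(type = "incidence", gain = 1),
         wing_pronation_asym = list(type = "incidence", gain = -side),
         wing_sweep_sym = list(type = "incidence", gain = 0.3),
         wing_sweep_asym = list(type = "incidence", gain = -0.3 * side),
         wing_tuck = if (side < 0)
           list(type = "scale", gain = -1 / 90) else NULL)
  }
  wing_ctl_clean <- function(side) Filter(Negate(is.null), wing_ctl(side))
  leg_ctl <- function(side) {
    Filter(Negate(is.null), list(
      legs_pitch = list(type = "incidence", gain = -1),
      leg_dihedral = if (side > 0) list(type = "dihedral", gain = 1) else NULL,
      leg_down = if (side < 0) list(type = "incidence", gain = 1) else NULL))
  }
  tail_ctl <- list(tail_pitch = list(type = "incidence", gain = -1),
                   tail_lateral = list(type = "side", gain = 1))
  wings <- function(x, a) list(
    glider_surface("wing_port", a / 2, x, y_off = -0.5, side_frac = 0.03,
                   controls = wing_ctl_clean(-1)),
    glider_surface("wing_stbd", a / 2, x, y_off = +0.5, side_frac = 0.03,
                   controls = wing_ctl_clean(+1)))
  legs <- function(x, a, inc = 0, y = 0.3) list(
    glider_surface("leg_port", a / 2, x, y_off = -y, incidence = inc,
                   present = feathers, controls = leg_ctl(-1)),
    glider_surface("leg_stbd", a / 2, x, y_off = +y, incidence = inc,
                   present = feathers, controls = leg_ctl(+1)))
  tail <- function(x, a, inc, s = 0.1)
    glider_surface("tail", a, x, incidence = inc, side_frac = s,
                   present = feathers, controls = tail_ctl)
  body <- glider_surface("body", 0.08, 0, side_frac = 0.02)

  surfaces <- switch(
    posture,
    sprawled = c(wings(0.5, 0.5), legs(-0.5, 0.3), list(tail(-1.0, 0.12, 0)),
                 list(body)),
    tent = c(wings(0.3, 0.5), legs(-0.25, 0.3),
             list(tail(-1.05, 0.12, -12.6)), list(body)),
    biplane = c(wings(0.28, 0.5), legs(0.1, 0.25, y = 0.3),
                list(tail(-1.2, 0.18, -4.05)), list(body)),
    down = c(wings(0.3, 0.5), legs(-0.3, 0.15, inc = -90, y = 0.1),
             list(tail(-1.0, 0.12, 8)), list(body)))
  glider_config(surfaces, label = posture, ...)
}

#' Simulate one wind-tunnel recording
#'
#' Generates a raw sensor-frame force/torque time series for one run:
#' the noise-free truth coefficients are evaluated at the model's
#' actual orientation — the nominal mounting orientation plus a random
#' misalignment drawn once per run — converted to a dimensional
#' tunnel-frame wrench at the tunnel's dynamic pressure, rotated into
#' the sensor frame at that actual orientation, and sampled with
#' additive Gaussian channel noise.  Fully reproducible for a given
#' seed.
#'
#' @param cfg a [glider_config()].
#' @param o nominal mounting [orientation()] (recorded in metadata; the
#'   analyst rotates by this).
#' @param conditions a [tunnel_conditions()].
#' @param geometry a [model_geometry()].
#' @param deflections named deflection vector (deg).
#' @param duration recording length (s); the study recorded one minute.
#' @param seed integer seed for this run.
#' @param meta optional extra metadata fields (run_id, posture,
#'   replicate, ...).
#' @return a `"raw_run"` object: list with `samples` (data frame
#'   `Fx..Mz`), `rate`, and `meta` (including nominal orientation and
#'   tunnel conditions).
#' @export
generate_run <- function(cfg, o, conditions, geometry,
                         deflections = numeric(0), duration = 60,
                         seed = 1L, meta = list()) {
  stopifnot(inherits(cfg, "glider_config"), inherits(o, "orientation"),
            inherits(conditions, "tunnel_conditions"),
            inherits(geometry, "model_geometry"))
  set.seed(seed)
  mis <- stats::rnorm(3, 0, cfg$misalign_sd)
  actual <- orientation(roll = o$roll + mis[1],
                        pitch = o$pitch + mis[2],
                        yaw = o$yaw + mis[3])
  truth <- body_coefficients(cfg, actual, deflections)
  q <- 0.5 * conditions$rho * conditions$U^2
  S <- geometry$S; lam <- geometry$lambda
  w_tunnel <- wrench(
    force = c(-truth$CD, truth$CY, -truth$CL) * q * S,
    moment = c(truth$Cl, truth$Cm, truth$Cn) * q * S * lam,
    frame = "tunnel")
  w_sensor <- to_sensor_frame(w_tunnel, actual)
  n <- max(1L, round(duration * cfg$rate))
  noise_sd <- c(rep(cfg$noise_force_sd, 3), rep(cfg$noise_moment_sd, 3))
  base <- c(w_sensor$force, w_sensor$moment)
  m <- vapply(seq_len(6), function(j) base[j] + stats::rnorm(n, 0, noise_sd[j]),
              numeric(n))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  samples <- as.data.frame(m)
  names(samples) <- c("Fx", "Fy", "Fz", "Mx", "My", "Mz")
  structure(list(samples = samples, rate = cfg$rate,
                 meta = utils::modifyList(list(
                   posture = cfg$label, feathers = TRUE, appendage = "none",
                   deflection_deg = 0, roll_deg = o$roll, pitch_deg = o$pitch,
                   yaw_deg = o$yaw, U_ms = conditions$U,
                   rho = conditions$rho, nu = conditions$nu,
                   replicate = 1L, seed = seed), meta)),
            class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  cat(sprintf(
    "raw run: %d samples at %g Hz; posture %s, alpha %g deg, yaw %g deg\n",
    nrow(x$samples), x$rate, x$meta$posture, x$meta$pitch_deg,
    x$meta$yaw_deg))
  invisible(x)
}

#' Simulate a full factorial wind-tunnel study
#'
#' Generates the cross of configurations x swept angles x deflection
#' levels x replicates, with one derived seed per run, and a manifest
#' recording each run's design point together with the generating
#' model's noise-free truth coefficients (for recovery testing).  When
#' `dir` is given the runs, manifest and dataset configuration are
#' written to disk in the package's CSV contracts (see
#' [read_dataset()]); otherwise everything is returned in memory.
#'
#' @param configs list of [glider_config()] objects (e.g. from
#'   [preset_config()]).
#' @param alpha_grid angle-of-attack grid (deg); the study swept -15 to
#'   90 in 5 deg steps.
#' @param yaw_grid optional yaw grid (deg; the study used -30..30 in 10
#'   deg steps), crossed with `yaw_alphas`.
#' @param yaw_alphas angles of attack at which yaw sweeps are run.
#' @param deflections named list of deflection grids, e.g.
#'   `list(tail_pitch = c(-5, 0, 5))`, crossed with
#'   `deflection_alphas`.
#' @param deflection_alphas angles of attack for the deflection runs
#'   (default: `alpha_grid`).
#' @param replicates replicate runs per treatment (the study used >= 5).
#' @param conditions a [tunnel_conditions()].
#' @param geometry a [model_geometry()].
#' @param duration per-run recording length (s).
#' @param seed base seed; per-run seeds are derived deterministically.
#' @param feathers_off if `TRUE`, each posture is additionally run with
#'   leg/tail surfaces absent.
#' @param dir optional output directory.
#' @return invisibly, a list with `runs` (list of `"raw_run"`),
#'   `manifest` (data frame incl. truth coefficient columns
#'   `true_CL..true_Cn`), `conditions`, `geometry`, `configs` and `dir`.
#' @export
generate_study <- function(configs, alpha_grid = seq(-15, 90, by = 5),
                           yaw_grid = NULL, yaw_alphas = c(5, 90),
                           deflections = list(),
                           deflection_alphas = NULL,
                           replicates = 5,
                           conditions = tunnel_conditions(),
                           geometry = model_geometry(),
                           duration = 60, seed = 1L,
                           feathers_off = FALSE, dir = NULL) {
  if (inherits(configs, "glider_config")) configs <- list(configs)
  design <- list()
  add <- function(cfg, pitch, yaw, appendage, delta) {
    design[[length(design) + 1L]] <<- list(cfg = cfg, pitch = pitch,
                                           yaw = yaw, appendage = appendage,
                                           delta = delta)
  }
  variants <- list()
  for (cfg in configs) {
    variants[[length(variants) + 1L]] <- list(cfg = cfg, feathers = TRUE)
    if (feathers_off) {
      off <- cfg
      for (i in seq_along(off$surfaces))
        if (grepl("^(leg|tail)", off$surfaces[[i]]$name))
          off$surfaces[[i]]$present <- FALSE
      variants[[length(variants) + 1L]] <- list(cfg = off, feathers = FALSE)
    }
  }
  for (v in variants) {
    for (a in alpha_grid) add(v, a, 0, "none", 0)
    if (!is.null(yaw_grid))
      for (a in yaw_alphas)
        for (ps in setdiff(yaw_grid, 0)) add(v, a, ps, "none", 0)
    das <- deflection_alphas %||% alpha_grid
    for (ch in names(deflections))
      for (a in das)
        for (dl in setdiff(deflections[[ch]], 0)) add(v, a, 0, ch, dl)
  }
  runs <- vector("list", length(design) * replicates)
  man <- vector("list", length(runs))
  k <- 0L
  for (pt in design) {
    cfg <- pt$cfg$cfg
    defl <- if (pt$appendage == "none") numeric(0) else
      stats::setNames(pt$delta, pt$appendage)
    o <- orientation(pitch = pt$pitch, yaw = pt$yaw)
    truth <- body_coefficients(cfg, o, defl)
    for (r in seq_len(replicates)) {
      k <- k + 1L
      run_seed <- derive_seed(seed, k)
      run <- generate_run(cfg, o, conditions, geometry, defl, duration,
                          seed = run_seed,
                          meta = list(run_id = sprintf("run%05d", k),
                                      feathers = pt$cfg$feathers,
                                      appendage = pt$appendage,
                                      deflection_deg = pt$delta,
                                      replicate = r))
      runs[[k]] <- run
      man[[k]] <- data.frame(
        run_id = run$meta$run_id, file = sprintf("run%05d.csv", k),
        posture = cfg$label, feathers = pt$cfg$feathers,
        appendage = pt$appendage, deflection_deg = pt$delta,
        roll_deg = 0, pitch_deg = pt$pitch, yaw_deg = pt$yaw,
        U_ms = conditions$U, rho = conditions$rho, nu = conditions$nu,
        replicate = r, seed = run_seed,
        true_CL = truth$CL, true_CD = truth$CD, true_CY = truth$CY,
        true_Cl = truth$Cl, true_Cm = truth$Cm, true_Cn = truth$Cn)
    }
  }
  manifest <- do.call(rbind, man)
  out <- list(runs = runs, manifest = manifest, conditions = conditions,
              geometry = geometry, configs = configs, dir = dir)
  class(out) <- "synthetic_study"
  if (!is.null(dir)) write_study(out, dir)
  invisible(out)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d runs, %d postures\n",
              nrow(x$manifest), length(unique(x$manifest$posture))))
  invisible(x)
}
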