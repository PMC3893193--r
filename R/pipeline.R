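# Study-level reports: loop the per-sweep analyses over every
# configuration present in a reduced coefficient table.

config_split <- function(tbl) {
  key <- interaction(tbl$posture, tbl$feathers, drop = TRUE)
  split(tbl, key)
}

#' Pitch stability and trim report for every configuration
#'
#' For each (posture, feathers) configuration in a reduced coefficient
#' table, assembles the neutral-deflection pitch sweep, computes the
#' central-difference pitching stability curve, and locates and
#' classifies all pitching-moment trim points.
#'
#' @param tbl reduced coefficient table (see [reduce_runs()]).
#' @param tol marginal-stability band (per deg).
#' @return data frame: one row per trim point, with columns `posture`,
#'   `feathers`, `alpha_trim`, `nearest_grid_alpha`, `slope`, `class`;
#'   configurations with no trim contribute a row with `NA` angles and
#'   class `"none"`.
#' @export
pitch_stability_report <- function(tbl, tol = 1e-3) {
  base <- tbl[tbl$appendage == "none" & tbl$deflection_deg == 0 &
                tbl$yaw_deg == 0, , drop = FALSE]
  out <- lapply(config_split(base), function(sub) {
    s <- assemble_sweep(sub, var = "pitch")
    tr <- find_trim_points(s, coef = "Cm", tol = tol)
    if (nrow(tr) == 0L)
      return(data.frame(posture = sub$posture[1], feathers = sub$feathers[1],
                        alpha_trim = NA_real_, nearest_grid_alpha = NA_real_,
                        slope = NA_real_, class = "none"))
    data.frame(posture = sub$posture[1], feathers = sub$feathers[1],
               alpha_trim = tr$angle, nearest_grid_alpha = tr$nearest_grid_angle,
               slope = tr$slope, class = tr$class)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Directional (yaw) stability report across angle of attack
#'
#' For each configuration and each angle of attack at which a yaw
#' sweep exists, reports the yaw stability coefficient (slope of the
#' yawing-moment coefficient at zero yaw) and its class.  Flat curves
#' at straight-down orientations come out marginal, the symmetry
#' signature of parachuting.
#'
#' @inheritParams pitch_stability_report
#' @return data frame with columns `posture`, `feathers`, `alpha`,
#'   `slope` (per deg), `class`.
#' @export
yaw_stability_report <- function(tbl, tol = 1e-3) {
  base <- tbl[tbl$appendage == "none" & tbl$deflection_deg == 0, ,
              drop = FALSE]
  rows <- list()
  for (sub in config_split(base)) {
    alphas <- sort(unique(sub$pitch_deg[sub$yaw_deg != 0]))
    for (a in alphas) {
      swp <- sub[sub$pitch_deg == a, , drop = FALSE]
      if (length(unique(swp$yaw_deg)) < 3L) next
      s <- assemble_sweep(swp, var = "yaw")
      curve <- central_difference_slopes(s, coef = "Cn")
      i0 <- which.min(abs(curve$angle))
      rows[[length(rows) + 1L]] <- data.frame(
        posture = sub$posture[1], feathers = sub$feathers[1], alpha = a,
        slope = curve$slope[i0],
        class = classify_stability(curve$slope[i0], tol))
    }
  }
  if (!length(rows))
    return(data.frame(posture = character(0), feathers = logical(0),
                      alpha = numeric(0), slope = numeric(0),
                      class = character(0)))
  do.call(rbind, rows)
}

#' Control-effectiveness report for every deflection family
#'
#' For each appendage channel present in the table (per posture),
#' computes the pitch, yaw and roll control derivatives across angle
#' of attack, flags control reversal, and classifies roll/yaw
#' dominance.
#'
#' @inheritParams pitch_stability_report
#' @param ratio roll/yaw dominance threshold for
#'   [axis_shift_profile()].
#' @return data frame with one row per (posture, appendage, alpha):
#'   derivatives on the three axes, `sd` columns, `reversal` flag (a
#'   reversal crossing lies within the adjacent grid interval) and
#'   `dominance`.
#' @export
control_report <- function(tbl, tol = 1e-3, ratio = 2) {
  rows <- list()
  for (posture in unique(tbl$posture)) {
    sub <- tbl[tbl$posture == posture & tbl$feathers, , drop = FALSE]
    channels <- setdiff(unique(sub$appendage), "none")
    for (ch in channels) {
      fam <- deflection_family(sub, ch)
      dm <- control_derivative(fam, axis = "pitch")
      dn <- control_derivative(fam, axis = "yaw")
      dl <- control_derivative(fam, axis = "roll")
      rev_m <- detect_reversal(dm, tol = tol)
      dom <- axis_shift_profile(fam, ratio = ratio)
      near_rev <- vapply(dm$alpha, function(a) {
        nrow(rev_m) > 0 &&
          any(rev_m$alpha_lo <= a & a <= rev_m$alpha_hi)
      }, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        posture = posture, appendage = ch, alpha = dm$alpha,
        dCm_ddelta = dm$derivative, sd_pitch = dm$sd,
        dCn_ddelta = dn$derivative, sd_yaw = dn$sd,
        dCl_ddelta = dl$derivative, sd_roll = dl$sd,
        n = dm$n, reversal = near_rev, dominance = dom$dominance)
    }
  }
  if (!length(rows))
    stop_invalid("no deflection families in table")
  do.call(rbind, rows)
}

#' Replicate-mean coefficients interpolated at one angle of attack
#'
#' Linearly interpolates the neutral-deflection replicate-mean
#' coefficient curves of a reduced table at an arbitrary angle of
#' attack — typically a trim angle lying between grid points.
#'
#' @param tbl reduced coefficient table (see [reduce_runs()]).
#' @param alpha angle of attack (deg).
#' @return an [aero_coefficients()] object.
#' @export
interp_coefficients <- function(tbl, alpha) {
  base <- tbl[tbl$appendage == "none" & tbl$deflection_deg == 0 &
                tbl$yaw_deg == 0, , drop = FALSE]
  grid <- sort(unique(base$pitch_deg))
  at <- function(coef) {
    m <- vapply(grid, function(g) mean(base[[coef]][base$pitch_deg == g]),
                numeric(1))
    stats::approx(grid, m, xout = alpha, rule = 2)$y
  }
  aero_coefficients(CL = at("CL"), CD = at("CD"), CY = at("CY"),
                    Cl = at("Cl"), Cm = at("Cm"), Cn = at("Cn"))
}

#' Glide and performance report per configuration
#'
#' Combines the trim table with the coefficient sweeps: for each
#' configuration, evaluates the equilibrium glide at its stable trim
#' (if any), the feasibility of gliding at the reference speed, the
#' simple performance metrics, and the turning indices at the trim
#' coefficients.
#'
#' @inheritParams pitch_stability_report
#' @param trims output of [pitch_stability_report()] (recomputed when
#'   `NULL`).
#' @param body a [body_scale()].
#' @param rho air density (kg/m^3).
#' @param theta_deg bank/crab angle for [turn_indices()].
#' @param balance passed to [equilibrium_glide()].
#' @return data frame: one row per configuration with trim angle and
#'   class, glide speed and angle, feasibility at the reference speed,
#'   `LD_max`, `V_min`, parachuting metrics and turn indices.
#' @export
glide_report <- function(tbl, trims = NULL, body = body_scale(),
                         rho = 1.204, theta_deg = 60,
                         balance = c("resultant", "lift")) {
  balance <- match.arg(balance)
  trims <- trims %||% pitch_stability_report(tbl)
  base <- tbl[tbl$appendage == "none" & tbl$deflection_deg == 0 &
                tbl$yaw_deg == 0, , drop = FALSE]
  out <- lapply(config_split(base), function(sub) {
    posture <- sub$posture[1]; feathers <- sub$feathers[1]
    s <- assemble_sweep(sub, var = "pitch")
    tt <- trims[trims$posture == posture & trims$feathers == feathers, ,
                drop = FALSE]
    tr_cls <- structure(tt, class = "data.frame")
    names(tr_cls)[names(tr_cls) == "alpha_trim"] <- "angle"
    tr_cls <- tr_cls[!is.na(tr_cls$angle), , drop = FALSE]
    pm <- suppressWarnings(performance_metrics(s, body, rho = rho,
                                               trim = tr_cls))
    stable <- tt[!is.na(tt$alpha_trim) & tt$class == "stable", , drop = FALSE]
    if (nrow(stable)) {
      a_trim <- stable$alpha_trim[1]
      co <- interp_coefficients(sub, a_trim)
      gl <- equilibrium_glide(co, body, rho = rho, balance = balance,
                              trim_alpha = a_trim)
      feas <- equilibrium_glide(co, body, rho = rho,
                                fixed_speed = body$speed)$feasible
      ti <- turn_indices(co, body, rho = rho, theta_deg = theta_deg)
      data.frame(posture = posture, feathers = feathers,
                 alpha_trim = a_trim, trim_class = stable$class[1],
                 glide_speed = gl$V, glide_angle = gl$gamma,
                 feasible_at_ref_speed = feas,
                 LD_max = pm$LD_max, V_min = pm$V_min,
                 parachute_index = pm$parachute_index %||% NA_real_,
                 terminal_velocity = pm$terminal_velocity %||% NA_real_,
                 banked_index = ti$banked, crabbed_index = ti$crabbed)
    } else {
      cls <- if (nrow(tt) && any(!is.na(tt$alpha_trim)))
        paste(unique(tt$class), collapse = "/") else "none"
      data.frame(posture = posture, feathers = feathers,
                 alpha_trim = NA_real_, trim_class = cls,
                 glide_speed = NA_real_, glide_angle = NA_real_,
                 feasible_at_ref_speed = NA,
                 LD_max = pm$LD_max, V_min = pm$V_min,
                 parachute_index = pm$parachute_index %||% NA_real_,
                 terminal_velocity = pm$terminal_velocity %||% NA_real_,
                 banked_index = NA_real_, crabbed_index = NA_real_)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
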