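#' Appendage deflection channels
#'
#' The control channels the package recognizes, with their sign
#' conventions.  Positive deflection is up (dorsal) for pitch-plane
#' movements, forward for sweep/protraction, and left (port) for
#' lateral movements; symmetric channels move both sides together,
#' asymmetric channels move the two sides in opposition or one side
#' only.
#'
#' @return character vector of channel names.
#' @export
deflection_channels <- function() {
  c("tail_pitch", "tail_lateral", "legs_pitch", "leg_dihedral",
    "wing_sweep_sym", "wing_sweep_asym", "wing_pronation_sym",
    "wing_pronation_asym", "wing_tuck", "leg_down")
}

#' Assemble a deflection family from a coefficient table
#'
#' A deflection family collects, for one appendage channel and one
#' posture, the measured coefficients over a grid of deflection angles
#' \eqn{\delta} crossed with angle of attack \eqn{\alpha}, with
#' replicates.  The \eqn{\delta} grid must contain the neutral 0 and at
#' least two distinct values.
#'
#' @param tbl tidy coefficient table (see [assemble_sweep()] for
#'   required columns; `appendage` and `deflection_deg` are used here).
#' @param appendage channel name (one of [deflection_channels()], or
#'   any label present in the table).
#' @param config optional named list filter, as in [assemble_sweep()].
#'   Rows with `deflection_deg == 0` and a different appendage label
#'   (e.g. `"none"`) are accepted as the shared neutral baseline.
#' @return an object of class `"deflection_family"`.
#' @export
deflection_family <- function(tbl, appendage, config = list()) {
  for (nm in names(config)) {
    if (!nm %in% names(tbl))
      stop_invalid("config filter names unknown column '%s'", nm)
    tbl <- tbl[tbl[[nm]] %in% config[[nm]], , drop = FALSE]
  }
  keep <- tbl$appendage == appendage |
    (tbl$deflection_deg == 0 & tbl$appendage %in% c("none", appendage))
  tbl <- tbl[keep, , drop = FALSE]
  if (nrow(tbl) == 0L)
    stop_invalid("no rows for appendage '%s' after filtering", appendage)
  deltas <- sort(unique(tbl$deflection_deg))
  if (length(deltas) < 2L)
    stop_invalid("deflection grid needs >= 2 distinct values (got %d)",
                 length(deltas))
  if (!any(deltas == 0))
    stop_invalid("deflection grid must contain the neutral 0 deg")
  alphas <- sort(unique(tbl$pitch_deg))
  structure(list(appendage = appendage, deltas = deltas, alphas = alphas,
                 data = tbl),
            class = "deflection_family")
}

#' @export
print.deflection_family <- function(x, ...) {
  cat(sprintf(
    "deflection family '%s': delta grid {%s} deg x %d angles of attack\n",
    x$appendage, paste(x$deltas, collapse = ", "), length(x$alphas)))
  invisible(x)
}

# least-squares slope and intercept of y on x (2 points -> secant)
ls_slope <- function(x, y) {
  if (length(unique(x)) < 2L) return(c(slope = NA_real_, int = NA_real_))
  f <- stats::lm.fit(cbind(1, x), y)
  c(slope = unname(f$coefficients[2]), int = unname(f$coefficients[1]))
}

#' Control effectiveness of an appendage deflection
#'
#' Control effectiveness is the partial derivative of a moment
#' coefficient with respect to the deflection angle of a control
#' surface, \eqn{\partial C_m/\partial\delta},
#' \eqn{\partial C_n/\partial\delta} or
#' \eqn{\partial C_l/\partial\delta}: a large derivative means a small
#' movement generates a large moment.  At each angle of attack the
#' derivative is estimated per replicate as the least-squares slope of
#' the moment coefficient against \eqn{\delta} over the full deflection
#' grid (reducing to a finite difference for two levels), then averaged
#' across replicates; the intercept is retained as the neutral moment.
#' A secant between the extreme deflections is available via
#' `mode = "secant"`.
#'
#' @param f a [deflection_family()].
#' @param axis `"pitch"` (Cm), `"yaw"` (Cn) or `"roll"` (Cl).
#' @param mode `"grid"` least squares (default) or `"secant"` between
#'   extreme deflections.
#' @return object of class `"control_effectiveness"`: data frame with
#'   columns `alpha`, `derivative` (per deg), `sd`, `n`, `neutral`
#'   (moment at delta = 0 from the fit).
#' @export
control_derivative <- function(f, axis = c("pitch", "yaw", "roll"),
                               mode = c("grid", "secant")) {
  stopifnot(inherits(f, "deflection_family"))
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  coef <- switch(axis, pitch = "Cm", yaw = "Cn", roll = "Cl")
  rows <- lapply(f$alphas, function(a) {
    sub <- f$data[f$data$pitch_deg == a, , drop = FALSE]
    deltas <- sort(unique(sub$deflection_deg))
    if (length(deltas) < 2L)
      stop_invalid("only one deflection value at alpha = %g deg", a)
    if (mode == "secant")
      sub <- sub[sub$deflection_deg %in% range(deltas), , drop = FALSE]
    reps <- sort(unique(sub$replicate))
    fits <- vapply(reps, function(r) {
      rs <- sub[sub$replicate == r, , drop = FALSE]
      ls_slope(rs$deflection_deg, rs[[coef]])
    }, numeric(2))
    sl <- fits["slope", ]
    data.frame(alpha = a,
               derivative = mean(sl, na.rm = TRUE),
               sd = stats::sd(sl, na.rm = TRUE),
               n = sum(!is.na(sl)),
               neutral = mean(fits["int", ], na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("control_effectiveness", "data.frame"),
            axis = axis, coef = coef, appendage = f$appendage, mode = mode)
}

#' @export
print.control_effectiveness <- function(x, ...) {
  cat(sprintf("control effectiveness d%s/ddelta for '%s' (%s fit):\n",
              attr(x, "coef"), attr(x, "appendage"), attr(x, "mode")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.control_effectiveness <- function(x, ...) {
  graphics::plot(x$alpha, x$derivative, type = "b", pch = 16,
                 xlab = "angle of attack (deg)",
                 ylab = sprintf("d%s/ddelta (1/deg)", attr(x, "coef")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Detect control reversal across angle of attack
#'
#' Control reversal is a sign change of the control-effectiveness
#' derivative with flight condition, so that the same control input
#' produces the opposite moment (e.g. tail-down producing nose-up at
#' high angle of attack).  Sign changes between adjacent angle-of-attack
#' grid points are located by linear interpolation.  Derivatives whose
#' magnitude is below `tol` are sign-indeterminate: they break a
#' crossing rather than anchoring one, and a curve entirely inside the
#' band returns an empty result flagged `indeterminate`.
#'
#' @param e a [control_derivative()] result.
#' @param tol indeterminacy band for the derivative (per deg).
#' @return data frame with columns `alpha_cross` (interpolated crossing
#'   angle, deg), `alpha_lo`, `alpha_hi`, `sign_from`, `sign_to`;
#'   attribute `indeterminate` is `TRUE` when every derivative is
#'   inside the band.
#' @export
detect_reversal <- function(e, tol = 1e-3) {
  stopifnot(inherits(e, "control_effectiveness"))
  if (nrow(e) < 2L)
    stop_invalid("reversal detection needs the derivative at >= 2 angles")
  d <- e$derivative
  a <- e$alpha
  determinate <- which(abs(d) > tol)
  out <- data.frame(alpha_cross = numeric(0), alpha_lo = numeric(0),
                    alpha_hi = numeric(0), sign_from = numeric(0),
                    sign_to = numeric(0))
  if (length(determinate) >= 2L) {
    for (k in seq_len(length(determinate) - 1L)) {
      i <- determinate[k]; j <- determinate[k + 1L]
      if (sign(d[i]) * sign(d[j]) < 0) {
        cross <- a[i] + (0 - d[i]) / (d[j] - d[i]) * (a[j] - a[i])
        out[nrow(out) + 1L, ] <- c(cross, a[i], a[j], sign(d[i]), sign(d[j]))
      }
    }
  }
  attr(out, "indeterminate") <- length(determinate) == 0L
  out
}

#' Roll/yaw dominance of an appendage across angle of attack
#'
#' Some appendages change function with flight condition: a movement
#' that rolls the body at low angle of attack can instead yaw it at
#' high angle of attack.  At each angle of attack the roll and yaw
#' control derivatives are compared: the channel is roll-dominant where
#' \eqn{|\partial C_l/\partial\delta| / |\partial C_n/\partial\delta| > r},
#' yaw-dominant where the ratio is below \eqn{1/r}, and mixed between.
#'
#' @param f a [deflection_family()].
#' @param ratio dominance threshold \eqn{r} (default 2).
#' @param mode passed to [control_derivative()].
#' @return data frame with columns `alpha`, `d_roll`, `d_yaw`, `ratio`
#'   and `dominance` in `{"roll", "mixed", "yaw"}`.
#' @export
axis_shift_profile <- function(f, ratio = 2, mode = c("grid", "secant")) {
  stopifnot(inherits(f, "deflection_family"))
  check_positive(ratio, "dominance ratio")
  mode <- match.arg(mode)
  dr <- control_derivative(f, axis = "roll", mode = mode)
  dy <- control_derivative(f, axis = "yaw", mode = mode)
  r <- abs(dr$derivative) / abs(dy$derivative)
  dom <- ifelse(r > ratio, "roll", ifelse(r < 1 / ratio, "yaw", "mixed"))
  data.frame(alpha = dr$alpha, d_roll = dr$derivative,
             d_yaw = dy$derivative, ratio = r, dominance = dom)
}
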