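#' Assemble an angle sweep from a tidy coefficient table
#'
#' Groups the rows of a reduced coefficient table (one row per
#' replicate run, as produced by [reduce_runs()]) into an ordered sweep
#' over a single varied angle for a single configuration.  The sweep is
#' the unit on which stability slopes and trim points are computed.
#'
#' @param tbl data frame with columns `posture`, `feathers`,
#'   `appendage`, `deflection_deg`, `roll_deg`, `pitch_deg`, `yaw_deg`,
#'   `replicate` and the six coefficient columns
#'   `CL, CD, CY, Cl, Cm, Cn`.
#' @param var which angle is swept: `"pitch"` (angle of attack),
#'   `"roll"` or `"yaw"`.
#' @param config optional named list used to filter `tbl`
#'   (e.g. `list(posture = "tent", deflection_deg = 0)`).  After
#'   filtering, all non-swept metadata must be single-valued.
#' @return an object of class `"aero_sweep"`: list with the sorted
#'   angle grid, the per-replicate coefficient rows, replicate counts
#'   and the configuration labels.
#' @export
assemble_sweep <- function(tbl, var = c("pitch", "roll", "yaw"),
                           config = list()) {
  var <- match.arg(var)
  angle_col <- paste0(var, "_deg")
  need <- c("posture", "replicate", angle_col, "CL", "CD", "CY",
            "Cl", "Cm", "Cn")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop_invalid("coefficient table lacks columns: %s",
                 paste(miss, collapse = ", "))
  for (nm in names(config)) {
    if (!nm %in% names(tbl))
      stop_invalid("config filter names unknown column '%s'", nm)
    tbl <- tbl[tbl[[nm]] %in% config[[nm]], , drop = FALSE]
  }
  if (nrow(tbl) == 0L) stop_invalid("no rows left after config filter")
  meta_cols <- intersect(c("posture", "feathers", "appendage",
                           "deflection_deg"), names(tbl))
  other_angles <- setdiff(c("roll_deg", "pitch_deg", "yaw_deg"), angle_col)
  meta_cols <- c(meta_cols, intersect(other_angles, names(tbl)))
  for (nm in meta_cols) {
    if (length(unique(tbl[[nm]])) > 1L)
      stop_invalid("sweep mixes configurations: column '%s' has values %s",
                   nm, paste(unique(tbl[[nm]]), collapse = ", "))
  }
  grid <- sort(unique(tbl[[angle_col]]))
  if (length(grid) < 3L)
    stop_invalid("sweep needs >= 3 grid angles for slope estimation (got %d)",
                 length(grid))
  tbl <- tbl[order(tbl[[angle_col]], tbl$replicate), , drop = FALSE]
  n_rep <- vapply(grid, function(g) sum(tbl[[angle_col]] == g), integer(1))
  structure(list(var = var, angle_col = angle_col, grid = grid,
                 data = tbl, n_rep = stats::setNames(n_rep, grid),
                 config = lapply(tbl[1, meta_cols, drop = FALSE], identity)),
            class = "aero_sweep")
}

#' @export
print.aero_sweep <- function(x, ...) {
  cat(sprintf("aero_sweep over %s: %d angles (%g..%g deg), %g replicates/angle\n",
              x$var, length(x$grid), min(x$grid), max(x$grid),
              stats::median(x$n_rep)))
  cfg <- x$config[!vapply(x$config, is.null, logical(1))]
  if (length(cfg))
    cat("  config:", paste(names(cfg), unlist(lapply(cfg, format)),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# replicate-mean coefficient curve over the sweep grid
sweep_mean_curve <- function(s, coef) {
  vapply(s$grid, function(g) {
    mean(s$data[[coef]][s$data[[s$angle_col]] == g])
  }, numeric(1))
}

#' Static stability slopes by per-replicate central differences
#'
#' Estimates the static stability coefficient — the local slope of a
#' moment coefficient with respect to its perturbation angle
#' (\eqn{C_{m\alpha}}, \eqn{C_{l\phi}} or \eqn{C_{n\psi}}) — by central
#' differences at each interior grid angle.  Slopes are computed for
#' each replicate run separately and then averaged across replicates
#' (the `"means"` order, differencing replicate means first, is
#' available as an option).  Endpoints use one-sided first-order
#' differences and are flagged.  Non-uniform grids are supported: the
#' central difference is \eqn{(C(\theta_+)-C(\theta_-))/(\theta_+-\theta_-)}.
#'
#' A negative slope means the moment opposes the perturbation
#' (statically stable); positive means non-restoring (unstable).
#'
#' @param s an [assemble_sweep()] result.
#' @param coef which moment coefficient to difference: `"Cm"`, `"Cl"`
#'   or `"Cn"` (any coefficient column is accepted).
#' @param order `"replicates"` (default: slope per replicate, then
#'   average) or `"means"` (difference the replicate-mean curve).
#' @return an object of class `"stability_curve"`: data frame with
#'   columns `angle`, `slope` (per degree), `slope_per_rad`, `sd`, `n`
#'   and `endpoint` (logical flag for one-sided estimates).
#' @export
central_difference_slopes <- function(s, coef = "Cm",
                                      order = c("replicates", "means")) {
  stopifnot(inherits(s, "aero_sweep"))
  order <- match.arg(order)
  if (!coef %in% names(s$data))
    stop_invalid("unknown coefficient column '%s'", coef)
  grid <- s$grid
  if (is.unsorted(grid, strictly = TRUE))
    stop_invalid("sweep grid must be strictly increasing")
  k <- length(grid)
  lo <- c(1L, seq_len(k - 2L), k - 1L)      # left neighbour index
  hi <- c(2L, seq_len(k - 2L) + 2L, k)      # right neighbour index
  endpoint <- c(TRUE, rep(FALSE, k - 2L), TRUE)

  value_at <- function(angle, rep_id) {
    rows <- s$data[[s$angle_col]] == angle & s$data$replicate == rep_id
    if (!any(rows)) return(NA_real_)
    mean(s$data[[coef]][rows])
  }

  if (order == "replicates") {
    reps <- sort(unique(s$data$replicate))
    per_rep <- vapply(reps, function(r) {
      vals <- vapply(grid, value_at, numeric(1), rep_id = r)
      (vals[hi] - vals[lo]) / (grid[hi] - grid[lo])
    }, numeric(k))
    per_rep <- matrix(per_rep, nrow = k)
    slope <- rowMeans(per_rep, na.rm = TRUE)
    sdv <- apply(per_rep, 1, stats::sd, na.rm = TRUE)
    n <- rowSums(!is.na(per_rep))
  } else {
    vals <- sweep_mean_curve(s, coef)
    slope <- (vals[hi] - vals[lo]) / (grid[hi] - grid[lo])
    sdv <- rep(NA_real_, k)
    n <- s$n_rep
  }
  out <- data.frame(angle = grid, slope = slope,
                    slope_per_rad = slope * 180 / pi,
                    sd = sdv, n = as.integer(n), endpoint = endpoint)
  structure(out, class = c("stability_curve", "data.frame"),
            coef = coef, var = s$var, config = s$config)
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("stability curve: d%s/d%s (per deg), %d angles\n",
              attr(x, "coef"), attr(x, "var"), nrow(x)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Classify static stability from a moment-curve slope
#'
#' Negative slope: restoring torque, statically stable.  Positive:
#' unstable.  Slopes within `tol` of zero are marginally stable.  The
#' band is symmetric, so classification is monotone in the slope.
#'
#' @param slope moment-coefficient slope, per degree.
#' @param tol half-width of the marginal band (per degree).  The
#'   default 0.001/deg is small relative to typical measured slopes.
#' @return character vector in `{"stable", "marginal", "unstable"}`.
#' @export
classify_stability <- function(slope, tol = 1e-3) {
  check_finite(slope, "slope")
  check_positive(tol, "tol")
  ifelse(slope < -tol, "stable", ifelse(slope > tol, "unstable", "marginal"))
}

#' Locate and classify trim points on a moment sweep
#'
#' A trim point is an angle at which the replicate-mean moment
#' coefficient crosses zero: an equilibrium of the quasi-static
#' rotational dynamics.  Crossings are localized by linear
#' interpolation between adjacent grid angles (the grid is coarse;
#' higher-order interpolation would invent structure), the slope at the
#' crossing is interpolated from the central-difference stability
#' curve, and each trim is classified with [classify_stability()].
#' Grid points with \eqn{|C| <} `zero_tol` count as on-grid trims.
#'
#' @param s an [assemble_sweep()] result.
#' @param coef moment coefficient to analyse (default `"Cm"`).
#' @param tol marginal-stability half band for classification, per deg.
#' @param zero_tol treat `|C| < zero_tol` at a grid point as a crossing.
#' @param order passed to [central_difference_slopes()].
#' @return object of class `"trim_points"`: data frame with columns
#'   `angle` (interpolated crossing, deg), `nearest_grid_angle`,
#'   `slope` (per deg), `class`, `bracket_lo`, `bracket_hi`.  Zero rows
#'   if the curve never crosses zero.
#' @export
find_trim_points <- function(s, coef = "Cm", tol = 1e-3, zero_tol = 1e-9,
                             order = c("replicates", "means")) {
  stopifnot(inherits(s, "aero_sweep"))
  order <- match.arg(order)
  curve <- central_difference_slopes(s, coef = coef, order = order)
  grid <- s$grid
  vals <- sweep_mean_curve(s, coef)
  slope_at <- function(theta) {
    stats::approx(curve$angle, curve$slope, xout = theta, rule = 2)$y
  }
  res <- list()
  on_grid <- which(abs(vals) < zero_tol)
  for (i in on_grid) {
    res[[length(res) + 1L]] <- data.frame(
      angle = grid[i], nearest_grid_angle = grid[i],
      slope = slope_at(grid[i]),
      bracket_lo = grid[max(1L, i - 1L)],
      bracket_hi = grid[min(length(grid), i + 1L)])
  }
  for (i in seq_len(length(grid) - 1L)) {
    v0 <- vals[i]; v1 <- vals[i + 1L]
    if (abs(v0) < zero_tol || abs(v1) < zero_tol) next  # handled on grid
    if (sign(v0) * sign(v1) < 0) {
      theta <- grid[i] + (0 - v0) / (v1 - v0) * (grid[i + 1L] - grid[i])
      nearest <- if (abs(theta - grid[i]) <= abs(grid[i + 1L] - theta))
        grid[i] else grid[i + 1L]
      res[[length(res) + 1L]] <- data.frame(
        angle = theta, nearest_grid_angle = nearest,
        slope = slope_at(theta),
        bracket_lo = grid[i], bracket_hi = grid[i + 1L])
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(angle = numeric(0), nearest_grid_angle = numeric(0),
               slope = numeric(0), bracket_lo = numeric(0),
               bracket_hi = numeric(0))
  out$class <- if (nrow(out)) classify_stability(out$slope, tol) else
    character(0)
  out <- out[order(out$angle),
             c("angle", "nearest_grid_angle", "slope", "class",
               "bracket_lo", "bracket_hi")]
  rownames(out) <- NULL
  structure(out, class = c("trim_points", "data.frame"),
            coef = coef, var = s$var, config = s$config)
}

#' @export
print.trim_points <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat(sprintf("no %s = 0 trim points on this sweep\n", attr(x, "coef")))
  } else {
    cat(sprintf("trim points (%s = 0, swept %s):\n",
                attr(x, "coef"), attr(x, "var")))
    print.data.frame(x, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.aero_sweep <- function(x, coef = "Cm", ...) {
  m <- sweep_mean_curve(x, coef)
  graphics::plot(x$grid, m, type = "b", pch = 16,
                 xlab = sprintf("%s angle (deg)", x$var),
                 ylab = coef, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
plot.stability_curve <- function(x, ...) {
  graphics::plot(x$angle, x$slope, type = "b", pch = 16,
                 xlab = sprintf("%s angle (deg)", attr(x, "var")),
                 ylab = sprintf("d%s/d%s (1/deg)", attr(x, "coef"),
                                attr(x, "var")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
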