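#' Body segment for mass / center-of-mass estimation
#'
#' One body segment (head, neck, wing, leg, trunk, tail, ...) with its
#' mass, longitudinal center-of-mass position measured along the body
#' axis from the snout, and the reference length at which those values
#' were measured.
#'
#' @param name segment label.
#' @param mass segment mass (kg), non-negative.
#' @param x longitudinal CoM position (m, from snout, + aft).
#' @param ref_length reference body length (m) of the source animal.
#' @return an object of class `"body_segment"`.
#' @export
body_segment <- function(name, mass, x, ref_length) {
  check_finite(c(mass, x), "segment mass/position")
  if (mass < 0) stop_invalid("segment mass must be >= 0")
  check_positive(ref_length, "reference length")
  structure(list(name = as.character(name), mass = mass, x = x,
                 ref_length = ref_length),
            class = "body_segment")
}

#' Scale a body segment to a target body length
#'
#' Default is isometric scaling: mass scales with the cube of the
#' length ratio (geometry-preserving density x volume), positions
#' scale linearly.  An allometric mass exponent can be supplied to
#' represent long-bone regression estimates from the literature; the
#' exponent/coefficient values themselves are user input, not package
#' constants.
#'
#' @param seg a [body_segment()].
#' @param target_length target body length (m).
#' @param mass_exponent exponent on the length ratio for mass
#'   (default 3, isometry).
#' @param mass_coefficient multiplier applied to the scaled mass
#'   (default 1), for allometric tables expressed as coefficient x
#'   ratio^exponent.
#' @return the scaled [body_segment()] with `ref_length = target_length`.
#' @export
scale_segment <- function(seg, target_length, mass_exponent = 3,
                          mass_coefficient = 1) {
  stopifnot(inherits(seg, "body_segment"))
  check_positive(target_length, "target length")
  r <- target_length / seg$ref_length
  body_segment(seg$name,
               mass = mass_coefficient * seg$mass * r^mass_exponent,
               x = seg$x * r,
               ref_length = target_length)
}

#' Total mass and center of mass of a segment set
#'
#' Sums segment masses and mass moments: total \eqn{M = \sum m_i},
#' center of mass \eqn{x_{cm} = \sum m_i x_i / M} — the standard
#' weights-and-centers bookkeeping.
#'
#' @param segments a list of [body_segment()] objects, or a data frame
#'   with columns `name`, `mass_kg`, `x_m` (and optionally
#'   `ref_length_m`).
#' @return object of class `"mass_model"`: list with `total_mass` (kg),
#'   `com` (m from snout) and the segment table.
#' @export
total_mass_and_com <- function(segments) {
  if (is.data.frame(segments)) {
    need <- c("name", "mass_kg", "x_m")
    miss <- setdiff(need, names(segments))
    if (length(miss))
      stop_invalid("segment table lacks columns: %s",
                   paste(miss, collapse = ", "))
    tab <- data.frame(name = segments$name, mass = segments$mass_kg,
                      x = segments$x_m)
  } else {
    stopifnot(all(vapply(segments, inherits, logical(1), "body_segment")))
    tab <- data.frame(name = vapply(segments, `[[`, character(1), "name"),
                      mass = vapply(segments, `[[`, numeric(1), "mass"),
                      x = vapply(segments, `[[`, numeric(1), "x"))
  }
  if (nrow(tab) == 0L) stop_invalid("need at least one segment")
  total <- sum(tab$mass)
  if (total <= 0) stop_invalid("total mass must be positive")
  structure(list(total_mass = total,
                 com = sum(tab$mass * tab$x) / total,
                 segments = tab),
            class = "mass_model")
}

#' @export
print.mass_model <- function(x, ...) {
  cat(sprintf("mass model: %d segments, total %.4g kg, CoM at %.4g m from snout\n",
              nrow(x$segments), x$total_mass, x$com))
  invisible(x)
}
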