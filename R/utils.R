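# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid("%s must be finite numeric (got %s)", what,
                 paste(utils::head(x, 3), collapse = ", "))
  }
  invisible(x)
}

check_positive <- function(x, what) {
  check_finite(x, what)
  if (any(x <= 0)) stop_invalid("%s must be strictly positive", what)
  invisible(x)
}

# Deterministic per-run seed stream derived from one base seed.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(base, i) {
  as.integer((as.double(base) * 48271 + as.double(i) * 69621) %% 2147483399) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
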