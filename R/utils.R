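# Internal helpers shared across modules.

# Orientation similarity under the doubled-angle convention.
#
# Preferred orientations are stored as true orientations in radians (period
# pi). All von Mises comparisons double the angular difference so that a 90
# degree (pi/2) orientation difference maps to cos = -1, i.e. maximal
# penalty for orthogonal tuning.
von_mises_ori <- function(theta_a, theta_b, kappa) {
  exp(kappa * cos(2 * (theta_a - theta_b)))
}

# Wrap an angle (in doubled-angle radians) into [-pi, pi).
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

# Wrap a true orientation into [0, pi).
wrap_ori <- function(x) {
  x %% pi
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` must be finite (got NA/NaN/Inf).", what))
  }
  invisible(x)
}

stopifnot_scalar_in <- function(x, lo, hi, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g].", what, lo, hi))
  }
  invisible(x)
}

# Normalise a non-negative vector to sum to one; the probability contract
# used by all connectivity rules.
normalise_prob <- function(p) {
  stopifnot_finite(p, "probability weights")
  if (any(p < 0)) abort("Probability weights must be non-negative.")
  total <- sum(p)
  if (total <= 0) abort("Probability weights sum to zero; cannot normalise.")
  p / total
}
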