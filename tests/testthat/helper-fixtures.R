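# Shared fixtures built in code.

# A small deterministic layout on a 600 x 600 um torus.
tiny_layout <- function(n = 60, seed = 101, side = 600) {
  place_population(n, torus_geometry(side, side), seed = seed)
}

# A hand-built layout with prescribed positions/orientations, excitatory
# unless stated. Used where tests need exact control.
manual_layout <- function(x, y, ori, inhibitory = NULL, side = 1000,
                          sigma_d = 75, sigma_a = 290) {
  n <- length(x)
  inhibitory <- inhibitory %||% rep(FALSE, n)
  layout <- tibble::tibble(
    neuron = seq_len(n), x = x, y = y, inhibitory = inhibitory,
    ori = ifelse(inhibitory, NA_real_, ori), kappa_input = 4,
    sigma_d = sigma_d, sigma_a = sigma_a,
    synapse_budget = ifelse(inhibitory, 8566, 8142))
  class(layout) <- c("population_layout", class(layout))
  attr(layout, "geometry") <- torus_geometry(side, side)
  layout
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Angle helpers independent of the package internals.
wrap_angle_oracle <- function(x) ((x + pi) %% (2 * pi)) - pi

# True-orientation difference mapped to [-pi/2, pi/2).
plaidnet_ori_diff <- function(a, b) wrap_angle_oracle(2 * (a - b)) / 2

# Random stable small network model for oracle-equivalence tests.
random_stable_model <- function(n, seed, spectral_target = 0.7) {
  set.seed(seed)
  W <- matrix(rnorm(n * n, 0, 1 / sqrt(n)), n, n)
  W <- W * spectral_target / max(Mod(eigen(W, only.values = TRUE)$values))
  network_model(W, tau = 10)
}
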