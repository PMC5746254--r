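#' Torus geometry
#'
#' The simulated patch of cortex is a flat torus (periodic boundaries in
#' both dimensions), default 2.2 x 2.2 mm.
#'
#' @param width,height Dimensions in micrometres.
#' @return A `torus_geometry` list.
#' @export
torus_geometry <- function(width = 2200, height = 2200) {
  if (width <= 0 || height <= 0) abort("Torus dimensions must be positive.")
  structure(list(width = width, height = height), class = "torus_geometry")
}

#' @export
print.torus_geometry <- function(x, ...) {
  cat(sprintf("<torus_geometry> %g x %g um\n", x$width, x$height))
  invisible(x)
}

#' Minimal-image distance on a torus
#'
#' Euclidean distance between positions computed over the torus surface
#' (shortest wraparound image in each dimension).
#'
#' @param u,v Positions: numeric vectors `c(x, y)` or two-column matrices.
#' @param geometry A [torus_geometry()].
#' @return Numeric vector of distances, micrometres.
#' @export
torus_distance <- function(u, v, geometry = torus_geometry()) {
  u <- rbind(u); v <- rbind(v)
  dx <- abs(u[, 1] - v[, 1]) %% geometry$width
  dy <- abs(u[, 2] - v[, 2]) %% geometry$height
  dx <- pmin(dx, geometry$width - dx)
  dy <- pmin(dy, geometry$height - dy)
  unname(sqrt(dx^2 + dy^2))
}

#' Place a model population on the torus
#'
#' Assigns uniform random positions, Bernoulli inhibitory labels, uniform
#' random preferred orientations (excitatory neurons only; a salt-and-pepper
#' map), and per-neuron anatomical parameters: dendritic and axonal Gaussian
#' field dispersions and output synapse budgets.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param geometry A [torus_geometry()]. Default 2200 x 2200 um.
#' @param prop_inhibitory Probability a neuron is inhibitory (default 0.18).
#' @param kappa_input Input orientation tuning width parameter (default 4).
#' @param sigma_d Dendritic field dispersion, um (default 75).
#' @param sigma_a_exc,sigma_a_inh Axonal field dispersions, um (defaults 290
#'   excitatory, 100 inhibitory).
#' @param synapses_exc,synapses_inh Nominal output synapse budgets at full
#'   cortical density (defaults 8142 and 8566).
#' @param seed Optional integer seed; the same seed reproduces the layout.
#'
#' @return A `population_layout` tibble with columns `neuron`, `x`, `y`,
#'   `inhibitory`, `ori` (preferred orientation, radians in `[0, pi)`; `NA`
#'   for inhibitory neurons), `kappa_input`, `sigma_d`, `sigma_a`,
#'   `synapse_budget`. The geometry is attached as attribute `"geometry"`.
#' @export
place_population <- function(n_neurons, geometry = torus_geometry(),
                             prop_inhibitory = 0.18, kappa_input = 4,
                             sigma_d = 75, sigma_a_exc = 290,
                             sigma_a_inh = 100, synapses_exc = 8142,
                             synapses_inh = 8566, seed = NULL) {
  if (n_neurons < 1) abort("`n_neurons` must be >= 1.")
  stopifnot_scalar_in(prop_inhibitory, 0, 1, "prop_inhibitory")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  inhibitory <- runif(n_neurons) < prop_inhibitory
  layout <- tibble(
    neuron = seq_len(n_neurons),
    x = runif(n_neurons, 0, geometry$width),
    y = runif(n_neurons, 0, geometry$height),
    inhibitory = inhibitory,
    ori = ifelse(inhibitory, NA_real_, runif(n_neurons, 0, pi)),
    kappa_input = kappa_input,
    sigma_d = sigma_d,
    sigma_a = ifelse(inhibitory, sigma_a_inh, sigma_a_exc),
    synapse_budget = ifelse(inhibitory, synapses_inh, synapses_exc)
  )
  class(layout) <- c("population_layout", class(layout))
  attr(layout, "geometry") <- geometry
  layout
}

layout_geometry <- function(layout) {
  geom <- attr(layout, "geometry")
  if (is.null(geom)) abort("Layout has no torus geometry attribute.")
  geom
}

#' Scaled-down population consistent with cortical density
#'
#' Convenience wrapper around [place_population()] that shrinks the torus so
#' that neuron density matches the reference configuration (80,000 neurons
#' on 2.2 x 2.2 mm, itself 10% of cortical density). Synapse budgets and all
#' field dispersions are kept at their nominal values.
#'
#' @param n_neurons Number of neurons in the reduced model.
#' @param reference_n,reference_size Reference count and torus side, um.
#' @param ... Passed to [place_population()].
#' @return A `population_layout`.
#' @export
place_population_scaled <- function(n_neurons, reference_n = 80000,
                                    reference_size = 2200, ...) {
  side <- reference_size * sqrt(n_neurons / reference_n)
  place_population(n_neurons, geometry = torus_geometry(side, side), ...)
}
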