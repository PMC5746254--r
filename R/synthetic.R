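# Synthetic trial-structured datasets with known ground truth: populations
# obeying a component rule, a feature-binding rule, or no rule, plus a
# neuropil sample distribution. These stand in for recordings so that
# every analysis stage can be tested end to end.

#' Synthetic dataset configuration
#'
#' @param n_neurons Number of neurons (>= 2).
#' @param rule Ground-truth plaid rule: `"component"` (plaid mean is the
#'   average of the two component-grating means, identical rule for every
#'   neuron), `"feature_binding"` (each neuron belongs to a subnetwork
#'   pairing two orientations; its matched plaid is facilitated above the
#'   best grating response, other plaids attenuated), or `"random"` (plaid
#'   tuning independent of grating tuning).
#' @param protocol Protocol name for [build_stimulus_protocol()] (default
#'   `"oscillating5_plaids"`).
#' @param kappa_tuning Median von Mises tuning width (default 4); per-neuron
#'   widths are log-normal around it with spread `kappa_spread` (log-sd,
#'   default 0.4), which produces a spread of OSI values.
#' @param baseline Untuned response offset as a fraction of the tuned
#'   amplitude (default 0.1); larger baselines lower OSI.
#' @param facilitation_gain Feature-binding rule only: matched-plaid mean
#'   is `facilitation_gain` times the larger component mean (default 1.5,
#'   i.e. clear facilitation, MI = 0.2 at the ground-truth means).
#' @param attenuation Multiplier on non-matched plaid means under the
#'   feature-binding rule (default 0.7).
#' @param noise_sigma Normalised trial noise `sigma_hat` (default 0.3).
#' @param n_trials Trials per stimulus (default 12).
#' @param n_neuropil Neuropil samples to generate (default 2000).
#' @param n_subnetworks Feature-binding rule only (default 6).
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_neurons = 300,
                             rule = c("component", "feature_binding",
                                      "random"),
                             protocol = "oscillating5_plaids",
                             kappa_tuning = 4, kappa_spread = 0.4,
                             baseline = 0.1, facilitation_gain = 1.5,
                             attenuation = 0.7, noise_sigma = 0.3,
                             n_trials = 12, n_neuropil = 2000,
                             n_subnetworks = 6, seed = 1) {
  rule <- match.arg(rule)
  if (n_neurons < 2) abort("`n_neurons` must be >= 2.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  structure(
    list(n_neurons = n_neurons, rule = rule, protocol = protocol,
         kappa_tuning = kappa_tuning, kappa_spread = kappa_spread,
         baseline = baseline, facilitation_gain = facilitation_gain,
         attenuation = attenuation, noise_sigma = noise_sigma,
         n_trials = n_trials, n_neuropil = n_neuropil,
         n_subnetworks = n_subnetworks, seed = seed),
    class = "synthetic_config")
}

# circular distance between two orientations in doubled-angle space
ori_distance <- function(a, b) {
  abs(wrap_angle(2 * (a - b)))
}

#' Ground-truth mean responses for a synthetic population
#'
#' Builds per-neuron mean grating responses from von Mises tuning curves
#' (uniform random preferred orientations) and derives plaid means
#' according to the configured ground-truth rule. Under
#' `"feature_binding"`, subnetworks pair two orientations from the
#' protocol's grating set; each neuron is assigned a subnetwork, its
#' preferred orientation is one of the pair, and its matched plaid (the
#' plaid composed of the subnetwork's pair) is facilitated while all other
#' plaids are attenuated. Under `"random"`, each neuron's component-rule
#' plaid means are randomly permuted across plaid stimuli, destroying the
#' grating-plaid relationship while preserving response scales.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_population`: tibble `neuron`, `stimulus_id`,
#'   `response` (ground-truth means) with attributes `stimuli` and
#'   `labels` (per-neuron tibble: `neuron`, `ori`, `kappa`, `amplitude`,
#'   `subnetwork`, matched pair orientations where applicable).
#' @export
make_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  st <- build_stimulus_protocol(config$protocol)
  grat <- filter(st, .data$kind == "grating")
  plaid <- filter(st, .data$kind == "plaid")
  n <- config$n_neurons
  kappa <- exp(rnorm(n, log(config$kappa_tuning), config$kappa_spread))
  amplitude <- exp(rnorm(n, 0, 0.3))
  subnetwork <- rep(NA_integer_, n)
  pair1 <- rep(NA_real_, n); pair2 <- rep(NA_real_, n)
  if (config$rule == "feature_binding") {
    # subnetworks pair two distinct orientations of the grating set
    pairs <- matrix(NA_real_, config$n_subnetworks, 2)
    for (k in seq_len(config$n_subnetworks)) {
      pairs[k, ] <- sort(sample(grat$ori1, 2))
    }
    subnetwork <- sample.int(config$n_subnetworks, n, replace = TRUE)
    pick <- sample.int(2, n, replace = TRUE)
    pair1 <- pairs[subnetwork, 1]; pair2 <- pairs[subnetwork, 2]
    ori <- ifelse(pick == 1, pair1, pair2) + rnorm(n, 0, 5 * pi / 180)
    ori <- wrap_ori(ori)
  } else {
    ori <- runif(n, 0, pi)
  }
  # tuned grating means, normalised so the peak of the tuning curve is
  # `amplitude` and an untuned baseline raises the floor
  grating_mean <- function(theta_g) {
    tuned <- von_mises_ori(theta_g, ori, kappa) / exp(kappa)
    amplitude * (config$baseline + (1 - config$baseline) * tuned)
  }
  G <- vapply(grat$ori1, grating_mean, numeric(n))  # n x n_gratings
  colnames(G) <- grat$stimulus_id
  P <- matrix(NA_real_, n, nrow(plaid), dimnames = list(NULL, plaid$stimulus_id))
  for (p in seq_len(nrow(plaid))) {
    g1 <- G[, match_ori_column(grat, plaid$ori1[p])]
    g2 <- G[, match_ori_column(grat, plaid$ori2[p])]
    P[, p] <- (g1 + g2) / 2
  }
  if (config$rule == "feature_binding") {
    for (i in seq_len(n)) {
      d <- ori_distance(plaid$ori1, pair1[i]) + ori_distance(plaid$ori2, pair2[i])
      d_swap <- ori_distance(plaid$ori1, pair2[i]) + ori_distance(plaid$ori2, pair1[i])
      matched <- which.min(pmin(d, d_swap))
      g_best <- max(G[i, match_ori_column(grat, plaid$ori1[matched])],
                    G[i, match_ori_column(grat, plaid$ori2[matched])])
      P[i, ] <- P[i, ] * config$attenuation
      P[i, matched] <- config$facilitation_gain * g_best
    }
  } else if (config$rule == "random") {
    for (i in seq_len(n)) P[i, ] <- P[i, sample.int(ncol(P))]
  }
  means <- bind_rows(
    tibble(neuron = rep(seq_len(n), ncol(G)),
           stimulus_id = rep(colnames(G), each = n),
           response = as.vector(G)),
    tibble(neuron = rep(seq_len(n), ncol(P)),
           stimulus_id = rep(colnames(P), each = n),
           response = as.vector(P))) |>
    arrange(.data$neuron, .data$stimulus_id)
  labels <- tibble(neuron = seq_len(n), ori = ori, kappa = kappa,
                   amplitude = amplitude, subnetwork = subnetwork,
                   pair_ori1 = pair1, pair_ori2 = pair2)
  class(means) <- c("synthetic_population", class(means))
  attr(means, "stimuli") <- st
  attr(means, "labels") <- labels
  attr(means, "config") <- config
  means
}

match_ori_column <- function(gratings, ori) {
  d <- ori_distance(gratings$ori1, ori)
  if (min(d) > 1e-6) abort("Plaid component does not match any grating.")
  gratings$stimulus_id[which.min(d)]
}

#' Synthetic trial-structured dataset
#'
#' Adds Gaussian trial noise to a ground-truth population via
#' [generate_trials()] and draws neuropil samples from a zero-mean
#' Gaussian scaled to the population's noise level
#' (`sigma * median(r_max)`).
#'
#' @param population A [make_population()] result.
#' @param noise_sigma,n_trials,n_neuropil,seed Override the corresponding
#'   config fields (defaults from the population's config).
#' @return A `synthetic_dataset`: list with `table` (a
#'   [response_table()]), `means`, `labels`, `neuropil` and the config.
#' @export
make_dataset <- function(population, noise_sigma = NULL, n_trials = NULL,
                         n_neuropil = NULL, seed = NULL) {
  stopifnot(inherits(population, "synthetic_population"))
  config <- attr(population, "config")
  noise_sigma <- noise_sigma %||% config$noise_sigma
  n_trials <- n_trials %||% config$n_trials
  n_neuropil <- n_neuropil %||% config$n_neuropil
  seed <- seed %||% (config$seed + 1L)
  table <- generate_trials(population, noise_sigma, n_trials, seed = seed)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed + 1L)
  r_max_med <- population |> group_by(.data$neuron) |>
    summarise(r_max = max(.data$response), .groups = "drop") |>
    pull(.data$r_max) |> median()
  neuropil <- rnorm(n_neuropil, 0, max(noise_sigma, 1e-12) * r_max_med)
  structure(
    list(table = table, means = population,
         labels = attr(population, "labels"), neuropil = neuropil,
         config = config),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d neurons, rule %s, sigma = %g, %d trials\n",
              x$config$n_neurons, x$config$rule, x$config$noise_sigma,
              x$config$n_trials))
  invisible(x)
}
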