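# High-level experiment: the grating/plaid decorrelation contrast across
# connectivity rules in the large-scale model.

#' Default experimental-level trial noise
#'
#' The normalised trial-to-trial variability `sigma_hat` assumed when
#' mimicking calcium-imaging measurement conditions on model output:
#' single-trial responses scatter around the mean with a standard
#' deviation of half the neuron's peak response (`sigma_hat = 0.5`), a
#' realistic level for bulk-loaded population calcium imaging.
#'
#' @return The default `sigma_hat` (0.5).
#' @export
default_trial_noise <- function() 0.5

#' Grating/plaid response decorrelation across connectivity rules
#'
#' Runs the full modelling chain for one or more connectivity rules:
#' build a population at cortical density, generate the synapse matrix
#' under the rule, drive the network with a grating/plaid protocol to
#' steady state, overlay calcium-imaging-like trial noise, apply the
#' responsivity and orientation-selectivity filters, and measure the R
#' squared between pairwise grating correlations and plaid correlations.
#' Under a like-to-like (or random) rule grating similarity predicts plaid
#' similarity (high R squared); feature-binding connectivity decorrelates
#' the two (low R squared).
#'
#' @param rules Character vector of [connectivity_spec()] presets.
#' @param n_neurons Network size (default 8000 at cortical density on a
#'   proportionally shrunken torus; the published scale of 80,000 is
#'   supported but slow).
#' @param seed Integer seed; all stages derive their seeds from it.
#' @param sigma_hat Trial noise level (default [default_trial_noise()]).
#' @param n_trials Generated trials per stimulus (default 12).
#' @param protocol Protocol name (default `"oscillating5_plaids"`).
#' @param osi_threshold OSI filter for pair inclusion (default 0.3).
#' @param max_pairs Cap on analysed pairs (memory guard; default 2e5).
#' @param alpha Responsivity filter exceedance level (default 0.01).
#' @param n_neuropil Stand-in neuropil sample count (default 2000).
#' @param keep_pairs Also return the per-rule pair tibbles (default FALSE).
#' @return A tibble with one row per rule: `rule`, `r2`, `n_included`,
#'   `n_pairs`, `all_converged`. With `keep_pairs`, the pair tibbles are
#'   attached as attribute `"pairs"`.
#' @export
decorrelation_experiment <- function(rules = c("random", "like_to_like",
                                               "feature_binding"),
                                     n_neurons = 8000, seed = 1,
                                     sigma_hat = default_trial_noise(),
                                     n_trials = 12,
                                     protocol = "oscillating5_plaids",
                                     osi_threshold = 0.3, max_pairs = 2e5,
                                     alpha = 0.01, n_neuropil = 2000,
                                     keep_pairs = FALSE) {
  proto <- build_stimulus_protocol(protocol)
  rows <- vector("list", length(rules))
  pair_list <- list()
  for (k in seq_along(rules)) {
    rule <- rules[k]
    rule_seed <- seed + 1000L * k
    layout <- place_population_scaled(n_neurons, seed = rule_seed)
    net <- build_v1_network(layout, connectivity_spec(rule),
                            seed = rule_seed + 1L)
    means <- suppressWarnings(simulate_protocol(net, proto))
    conv <- all(attr(means, "converged")$converged)
    table <- generate_trials(means, sigma_hat, n_trials,
                             seed = rule_seed + 2L)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(rule_seed + 3L)
    r_max <- means |> group_by(.data$neuron) |>
      summarise(r = max(.data$response), .groups = "drop")
    np_scale <- sigma_hat * median(r_max$r[r_max$r > 0])
    neuropil <- rnorm(n_neuropil, 0, max(np_scale, 1e-12))
    filt <- responsivity_filter(table, neuropil, alpha = alpha)
    keep <- filt$neuron[filt$included & !layout$inhibitory[filt$neuron]]
    pairs <- pairwise_correlations(table, neurons = keep,
                                   max_pairs = max_pairs,
                                   seed = rule_seed + 4L)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    r2 <- grating_plaid_r2(pairs, osi_threshold)
    n_pairs <- nrow(filter(pairs, .data$osi_a > osi_threshold,
                           .data$osi_b > osi_threshold))
    if (keep_pairs) pair_list[[rule]] <- pairs
    rows[[k]] <- tibble(rule = rule, r2 = r2, n_included = length(keep),
                        n_pairs = n_pairs, all_converged = conv)
  }
  out <- list_rbind(rows)
  if (keep_pairs) attr(out, "pairs") <- pair_list
  out
}
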