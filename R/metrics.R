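# Response metrics: selectivity and modulation indices, pairwise signal
# correlations, responsivity filtering, receptive-field centres.

#' Orientation selectivity index
#'
#' `OSI = (max(R_g) - min(R_g)) / sum(R_g)` over a neuron's trial-averaged
#' grating responses. 1 means the neuron responds to a single grating of
#' the set; 0 means equal responses to all.
#'
#' @param grating_responses Numeric vector (>= 2 entries, non-negative).
#' @return OSI in `[0, 1]`; `NA` for an all-zero responder.
#' @export
osi <- function(grating_responses) {
  r <- grating_responses
  if (length(r) < 2L) abort("Need responses to at least 2 grating stimuli.")
  stopifnot_finite(r, "grating_responses")
  if (any(r < 0)) abort("Responses must be non-negative.")
  if (sum(r) == 0) return(NA_real_)
  (max(r) - min(r)) / sum(r)
}

#' Plaid selectivity index
#'
#' `PSI = 1 - (-1 + sum(R_p)/max(R_p)) / (#(R_p) - 1)` over a neuron's
#' trial-averaged plaid responses. 1 means a single-plaid responder, 0
#' means equal responses to all plaids.
#'
#' @param plaid_responses Numeric vector (>= 2 entries, non-negative).
#' @return PSI in `[0, 1]`; `NA` for an all-zero responder.
#' @export
psi <- function(plaid_responses) {
  r <- plaid_responses
  if (length(r) < 2L) abort("Need responses to at least 2 plaid stimuli.")
  stopifnot_finite(r, "plaid_responses")
  if (any(r < 0)) abort("Responses must be non-negative.")
  if (max(r) == 0) return(NA_real_)
  1 - (-1 + sum(r) / max(r)) / (length(r) - 1)
}

#' Plaid modulation index
#'
#' `MI = (max(R_p) - max(R_g)) / (max(R_p) + max(R_g))`: positive values
#' indicate facilitation by plaid stimuli, negative values suppression.
#'
#' @param grating_responses,plaid_responses Numeric response vectors.
#' @return MI in `[-1, 1]`; `NA` when both maxima are zero.
#' @export
modulation_index <- function(grating_responses, plaid_responses) {
  stopifnot_finite(grating_responses, "grating_responses")
  stopifnot_finite(plaid_responses, "plaid_responses")
  mg <- max(grating_responses)
  mp <- max(plaid_responses)
  if (mg + mp <= 0) return(NA_real_)
  (mp - mg) / (mp + mg)
}

#' Per-neuron selectivity and modulation summary
#'
#' Computes OSI (over gratings), PSI (over plaids) and MI for every neuron
#' of a response table (or trial-means tibble). Noisy trial-averaged
#' responses may be negative (dF/F-like units are not clipped at trial
#' generation); the selectivity indices are defined on non-negative
#' responses, so trial means are rectified at zero before the indices are
#' taken.
#'
#' @param table A [response_table()] or [trial_means()] result.
#' @return Tibble `neuron`, `osi`, `psi`, `mi`, `r_max`.
#' @export
response_metrics <- function(table) {
  st <- response_stimuli(table)
  means <- if ("trial" %in% names(table)) trial_means(table) else table
  means <- left_join(means, select(st, "stimulus_id", "kind"),
                     by = "stimulus_id")
  means |>
    group_by(.data$neuron) |>
    summarise(
      osi = osi(pmax(0, .data$response[.data$kind == "grating"])),
      psi = psi(pmax(0, .data$response[.data$kind == "plaid"])),
      mi = modulation_index(pmax(0, .data$response[.data$kind == "grating"]),
                            pmax(0, .data$response[.data$kind == "plaid"])),
      r_max = max(.data$response),
      .groups = "drop")
}

#' Pairwise grating and plaid signal correlations
#'
#' For every unordered pair of neurons, the Pearson correlation between
#' their trial-averaged grating tuning vectors (`rho_g`) and between their
#' plaid tuning vectors (`rho_p`). Neurons whose grating or plaid vector
#' has zero variance cannot be correlated and are excluded (recorded in
#' the `"excluded"` attribute with a reason). Each neuron's OSI is
#' attached to the pair rows for downstream filtering.
#'
#' @param table A [response_table()] or [trial_means()] tibble.
#' @param neurons Optional subset of neuron ids to consider.
#' @param max_pairs Optional cap: a seeded subsample of pairs when the
#'   number of pairs exceeds it (keeps memory bounded for large models).
#' @param seed Seed used only when subsampling pairs.
#' @return A `pair_correlations` tibble: `neuron_a`, `neuron_b`, `rho_g`,
#'   `rho_p`, `osi_a`, `osi_b`.
#' @export
pairwise_correlations <- function(table, neurons = NULL, max_pairs = NULL,
                                  seed = NULL) {
  st <- response_stimuli(table)
  if (sum(st$kind == "grating") < 2L || sum(st$kind == "plaid") < 2L) {
    abort("Need at least 2 grating and 2 plaid stimuli.")
  }
  means <- if ("trial" %in% names(table)) trial_means(table) else table
  if (!is.null(neurons)) means <- filter(means, .data$neuron %in% neurons)
  wide <- means |>
    select("neuron", "stimulus_id", "response") |>
    pivot_wider(names_from = "stimulus_id", values_from = "response")
  ids <- wide$neuron
  gcols <- st$stimulus_id[st$kind == "grating"]
  pcols <- st$stimulus_id[st$kind == "plaid"]
  G <- as.matrix(wide[gcols])
  P <- as.matrix(wide[pcols])
  sd_g <- apply(G, 1, sd)
  sd_p <- apply(P, 1, sd)
  ok <- sd_g > 0 & sd_p > 0
  excluded <- tibble(
    neuron = ids[!ok],
    reason = ifelse(sd_g[!ok] == 0, "zero-variance grating vector",
                    "zero-variance plaid vector"))
  ids <- ids[ok]; G <- G[ok, , drop = FALSE]; P <- P[ok, , drop = FALSE]
  n <- length(ids)
  if (n < 2L) abort("Fewer than 2 neurons with non-degenerate tuning vectors.")
  osi_vec <- apply(pmax(G, 0), 1, osi)  # indices defined on rectified means
  rg <- cor(t(G))
  rp <- cor(t(P))
  idx <- which(upper.tri(rg), arr.ind = TRUE)
  if (!is.null(max_pairs) && nrow(idx) > max_pairs) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    idx <- idx[sample.int(nrow(idx), max_pairs), , drop = FALSE]
  }
  out <- tibble(
    neuron_a = ids[idx[, 1]], neuron_b = ids[idx[, 2]],
    rho_g = rg[idx], rho_p = rp[idx],
    osi_a = osi_vec[idx[, 1]], osi_b = osi_vec[idx[, 2]])
  class(out) <- c("pair_correlations", class(out))
  attr(out, "excluded") <- excluded
  out
}

#' Grating-versus-plaid correlation R squared
#'
#' Restricts pairs to those where both neurons exceed the OSI threshold and
#' returns the squared Pearson correlation between `rho_g` and `rho_p`
#' across pairs: the package's summary of how well grating response
#' similarity predicts plaid response similarity.
#'
#' @param pairs A [pairwise_correlations()] tibble.
#' @param osi_threshold Minimum OSI for both pair members (default 0.3).
#' @return R squared (scalar in `[0, 1]`).
#' @export
grating_plaid_r2 <- function(pairs, osi_threshold = 0.3) {
  keep <- filter(pairs, .data$osi_a > osi_threshold,
                 .data$osi_b > osi_threshold,
                 is.finite(.data$rho_g), is.finite(.data$rho_p))
  if (nrow(keep) < 3L) {
    abort(sprintf("Only %d pairs survive the OSI filter; need >= 3.",
                  nrow(keep)))
  }
  cor(keep$rho_g, keep$rho_p)^2
}

#' @rdname pairwise_correlations
#' @param object A `pair_correlations` tibble.
#' @param osi_threshold OSI filter applied before plotting (default 0.3).
#' @param ... Unused.
#' @export
autoplot.pair_correlations <- function(object, osi_threshold = 0.3, ...) {
  keep <- filter(as_tibble(object), .data$osi_a > osi_threshold,
                 .data$osi_b > osi_threshold)
  ggplot2::ggplot(keep, ggplot2::aes(x = .data$rho_g, y = .data$rho_p)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = expression(rho[g]), y = expression(rho[p])) +
    ggplot2::theme_minimal()
}

#' Classify neurons as facilitating, suppressing or non-modulated
#'
#' @param mi Vector of modulation indices (NA entries dropped).
#' @param threshold Facilitation/suppression cut (default 0.05): MI above
#'   `threshold` facilitating, below `-threshold` suppressing.
#' @return A `modulation_summary` tibble with one row per class and counts.
#' @export
classify_modulation <- function(mi, threshold = 0.05) {
  if (length(mi) == 0) abort("`mi` must be non-empty.")
  mi <- mi[is.finite(mi)]
  out <- tibble(
    class = c("facilitating", "suppressing", "non_modulated"),
    count = c(sum(mi > threshold), sum(mi < -threshold),
              sum(abs(mi) <= threshold))
  )
  class(out) <- c("modulation_summary", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Compare facilitation/suppression splits between two populations
#'
#' Arranges two [classify_modulation()] summaries into a 2 x 3 contingency
#' table and applies a two-tailed Fisher's exact test.
#'
#' @param summary_a,summary_b `modulation_summary` tibbles.
#' @return Tibble with `p_value` and the flattened contingency counts.
#' @export
fisher_compare <- function(summary_a, summary_b) {
  tab <- rbind(summary_a$count, summary_b$count)
  if (any(colSums(tab) == 0)) tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0)) {
    return(tibble(p_value = NA_real_, degenerate = TRUE))
  }
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  tibble(p_value = p, degenerate = FALSE)
}

#' Responsivity filter against a neuropil distribution
#'
#' Mirrors the imaging inclusion criterion: a response threshold `z_trial`
#' is the `1 - alpha` quantile of single-presentation neuropil responses,
#' and `z_max` the `1 - alpha` quantile of the maximum trial-averaged
#' response of neuropil-like pseudo-neurons (obtained by resampling the
#' neuropil samples into the table's stimulus-by-trial design). A neuron
#' is included iff its maximum trial-averaged response exceeds `z_max` and
#' more than half of its trials at that best stimulus exceed `z_trial`.
#'
#' @param table A [response_table()].
#' @param neuropil_samples Numeric vector of neuropil single-presentation
#'   responses (same units as the table).
#' @param alpha Exceedance level (default 0.01).
#' @param n_null Number of resampled pseudo-neurons used for the `z_max`
#'   quantile (default 2000; draws from the current RNG stream).
#' @return Tibble `neuron`, `included`, `best_response`, `n_trials_above`;
#'   thresholds in attributes `z_trial`, `z_max`.
#' @export
responsivity_filter <- function(table, neuropil_samples, alpha = 0.01,
                                n_null = 2000) {
  if (length(neuropil_samples) == 0) abort("`neuropil_samples` is empty.")
  stopifnot_scalar_in(alpha, 0, 1, "alpha")
  counts <- table |> group_by(.data$neuron, .data$stimulus_id) |>
    summarise(n = n(), .groups = "drop")
  n_trials <- max(counts$n)
  if (n_trials < 2L) abort("Need at least 2 trials per stimulus.")
  n_stimuli <- length(unique(table$stimulus_id))
  z_trial <- quantile(neuropil_samples, 1 - alpha, names = FALSE,
                      type = 7)
  null_max <- replicate(n_null, {
    m <- matrix(sample(neuropil_samples, n_stimuli * n_trials,
                       replace = TRUE), n_stimuli, n_trials)
    max(rowMeans(m))
  })
  z_max <- quantile(null_max, 1 - alpha, names = FALSE, type = 7)
  out <- table |>
    group_by(.data$neuron, .data$stimulus_id) |>
    summarise(mean_response = mean(.data$response),
              n_above = sum(.data$response > z_trial),
              n_trials = n(), .groups = "drop") |>
    group_by(.data$neuron) |>
    summarise(
      best_response = max(.data$mean_response),
      n_trials_above = .data$n_above[which.max(.data$mean_response)],
      n_trials_best = .data$n_trials[which.max(.data$mean_response)],
      .groups = "drop") |>
    mutate(included = .data$best_response > z_max &
             .data$n_trials_above > .data$n_trials_best / 2) |>
    select("neuron", "included", "best_response", "n_trials_above")
  attr(out, "z_trial") <- z_trial
  attr(out, "z_max") <- z_max
  out
}

#' Receptive-field centre from a response grid
#'
#' Estimates a receptive-field centre as the peak of a Gaussian mixture:
#' circularly symmetric Gaussians (dispersion `sigma`, visual degrees)
#' placed at each stimulus-grid location and weighted by the response
#' there, evaluated over a dense grid.
#'
#' @param grid_responses Tibble/data frame with columns `x`, `y` (stimulus
#'   locations, visual degrees) and `response` (>= 0; at least one
#'   positive), or a matrix of responses (locations inferred from
#'   `spacing`).
#' @param sigma Gaussian dispersion, visual degrees (default 7.5).
#' @param spacing Grid spacing in visual degrees when `grid_responses` is a
#'   matrix (default 9).
#' @param resolution Evaluation-grid step, visual degrees (default 0.1).
#' @return Tibble with the centre `x`, `y` and the mixture `height` there.
#' @export
estimate_rf_centre <- function(grid_responses, sigma = 7.5, spacing = 9,
                               resolution = 0.1) {
  if (is.matrix(grid_responses)) {
    locs <- expand.grid(
      x = (seq_len(ncol(grid_responses)) - 1) * spacing,
      y = (seq_len(nrow(grid_responses)) - 1) * spacing)
    grid_responses <- tibble(x = locs$x, y = locs$y,
                             response = as.vector(t(grid_responses)))
  }
  r <- grid_responses$response
  if (all(r <= 0)) abort("Need at least one positive response.")
  pad <- 2 * sigma
  xs <- seq(min(grid_responses$x) - pad, max(grid_responses$x) + pad,
            by = resolution)
  ys <- seq(min(grid_responses$y) - pad, max(grid_responses$y) + pad,
            by = resolution)
  height <- matrix(0, length(ys), length(xs))
  for (k in seq_along(r)) {
    if (r[k] <= 0) next
    gx <- exp(-(xs - grid_responses$x[k])^2 / (2 * sigma^2))
    gy <- exp(-(ys - grid_responses$y[k])^2 / (2 * sigma^2))
    height <- height + r[k] * outer(gy, gx)
  }
  peak <- which(height == max(height), arr.ind = TRUE)[1, ]
  tibble(x = xs[peak[2]], y = ys[peak[1]], height = max(height))
}

#' Signal correlation between trial-averaged movie traces
#'
#' Pearson correlation between two trial-averaged response traces after
#' excluding an onset window following each movie-segment start (transient
#' suppression of stimulus-onset artefacts).
#'
#' @param trace_a,trace_b Equal-length numeric traces.
#' @param times Sample times (same length, seconds).
#' @param segment_onsets Movie segment onset times, seconds.
#' @param exclusion Length of the excluded window after each onset,
#'   seconds (default 1).
#' @return Pearson correlation over the retained samples.
#' @export
movie_signal_correlation <- function(trace_a, trace_b, times,
                                     segment_onsets, exclusion = 1) {
  if (length(trace_a) != length(trace_b) ||
      length(trace_a) != length(times)) {
    abort("`trace_a`, `trace_b` and `times` must have equal length.")
  }
  keep <- rep(TRUE, length(times))
  for (t0 in segment_onsets) {
    keep <- keep & !(times >= t0 & times < t0 + exclusion)
  }
  if (sum(keep) < 3L) abort("Fewer than 3 samples retained.")
  cor(trace_a[keep], trace_b[keep])
}
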