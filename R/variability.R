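# Experimental-variability model: estimate the trial-noise parameter
# sigma-hat, generate noisy trials from model means, and the bootstrap
# component-response control.

#' Estimate trial-to-trial variability
#'
#' Per neuron, the standard deviation of single-trial responses normalised
#' by the neuron's maximum trial-averaged response `r_max`; the population
#' estimate `sigma_hat` is the median over neurons. Two conventions are
#' offered:
#'
#' * `"pooled"` (the printed definition): the standard deviation of the
#'   pooled single-trial responses over all stimuli, `sd(union(S_i)/r_max)`.
#'   This conflates stimulus tuning variance with trial noise.
#' * `"residual"`: the standard deviation of residuals about each
#'   stimulus's trial mean (with the per-stimulus mean-removal degrees of
#'   freedom correction), which recovers the generative trial noise.
#'
#' Neurons with `r_max <= 0` are excluded from the median.
#'
#' @param table A [response_table()] with >= 2 trials per stimulus.
#' @param method `"pooled"` (default) or `"residual"`.
#' @return A `variability_estimate`: list with per-neuron tibble `sigma`
#'   and the population `sigma_hat`.
#' @export
estimate_variability <- function(table, method = c("pooled", "residual")) {
  method <- match.arg(method)
  n_trials <- table |> group_by(.data$neuron, .data$stimulus_id) |>
    summarise(n = n(), .groups = "drop")
  if (min(n_trials$n) < 2L) abort("Need at least 2 trials per stimulus.")
  per_neuron <- table |>
    group_by(.data$neuron, .data$stimulus_id) |>
    mutate(stim_mean = mean(.data$response)) |>
    group_by(.data$neuron) |>
    summarise(
      r_max = max(.data$stim_mean),
      sigma = if (method[1] == "pooled") sd(.data$response) else {
        sqrt(sum((.data$response - .data$stim_mean)^2) /
               (n() - dplyr::n_distinct(.data$stimulus_id)))
      },
      .groups = "drop") |>
    mutate(sigma = .data$sigma / .data$r_max)
  usable <- filter(per_neuron, .data$r_max > 0, is.finite(.data$sigma))
  structure(
    list(sigma = select(per_neuron, "neuron", "sigma", "r_max"),
         sigma_hat = median(usable$sigma),
         method = method, n_neurons = nrow(usable)),
    class = "variability_estimate"
  )
}

#' @export
print.variability_estimate <- function(x, ...) {
  cat(sprintf("<variability_estimate> sigma_hat = %.4f (%s method, %d neurons)\n",
              x$sigma_hat, x$method, x$n_neurons))
  invisible(x)
}

#' @rdname estimate_variability
#' @param x A `variability_estimate`.
#' @param ... Unused.
#' @export
tidy.variability_estimate <- function(x, ...) x$sigma

#' @rdname estimate_variability
#' @export
glance.variability_estimate <- function(x, ...) {
  tibble(sigma_hat = x$sigma_hat, method = x$method,
         n_neurons = x$n_neurons)
}

#' Generate noisy single trials from mean responses
#'
#' Single-trial responses are drawn as
#' `r_ij = mean_i + N(0, sigma_hat * r_max)` per neuron: Gaussian trial
#' noise whose scale follows the neuron's maximum mean response. Trials
#' are not clipped at zero (dF/F-like responses may be negative).
#'
#' @param mean_responses Tibble `neuron`, `stimulus_id`, `response` with
#'   stimulus metadata attached (e.g. [simulate_protocol()] output).
#' @param sigma_hat Normalised trial noise level (>= 0).
#' @param n_trials Trials per stimulus (default 12).
#' @param seed Optional integer seed.
#' @return A [response_table()].
#' @export
generate_trials <- function(mean_responses, sigma_hat, n_trials = 12,
                            seed = NULL) {
  if (sigma_hat < 0) abort("`sigma_hat` must be >= 0.")
  st <- response_stimuli(mean_responses)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  means <- mean_responses |>
    group_by(.data$neuron) |>
    mutate(r_max = max(.data$response)) |>
    ungroup()
  trials <- tidyr::uncount(means, n_trials, .id = "trial") |>
    mutate(response = .data$response +
             rnorm(n(), 0, sigma_hat * .data$r_max)) |>
    select("neuron", "stimulus_id", "trial", "response")
  response_table(trials, st)
}

#' Bootstrap component-model control
#'
#' Generates synthetic plaid responses under the null hypothesis that every
#' neuron combines its grating-component responses by one fixed rule: for
#' each neuron, plaid and trial, a random single-trial response is drawn
#' for each of the plaid's two grating components and combined (sum by
#' default). Each bootstrap sample matches the source population in neuron
#' and trial counts; [grating_plaid_r2()] is computed per sample. A high
#' control R squared against a low observed R squared indicates response
#' decorrelation beyond what a single component rule plus trial noise can
#' produce.
#'
#' @param grating_trials A [response_table()] containing grating responses
#'   (plaid rows, if present, are ignored).
#' @param plaid_definitions Tibble `stimulus_id`, `ori1`, `ori2` defining
#'   the plaids to synthesise; defaults to the plaid rows of the table's
#'   stimulus metadata.
#' @param n_boot Number of bootstrap samples (default 100).
#' @param combine `"sum"` (default) or `"average"` of the two component
#'   trials.
#' @param osi_threshold Passed to [grating_plaid_r2()].
#' @param max_pairs,seed Passed to [pairwise_correlations()] / RNG.
#' @return A `bootstrap_control` tibble `sample`, `r2`; [glance()] gives
#'   the median and 95% percentile interval.
#' @export
bootstrap_component_control <- function(grating_trials,
                                        plaid_definitions = NULL,
                                        n_boot = 100,
                                        combine = c("sum", "average"),
                                        osi_threshold = 0.3,
                                        max_pairs = NULL, seed = NULL) {
  combine <- match.arg(combine)
  st <- response_stimuli(grating_trials)
  grat_ids <- st$stimulus_id[st$kind == "grating"]
  plaid_definitions <- plaid_definitions %||%
    filter(st, .data$kind == "plaid")
  if (nrow(plaid_definitions) == 0) abort("No plaid definitions available.")
  gratings <- filter(grating_trials, .data$stimulus_id %in% grat_ids)
  # match each plaid component to the grating with the same orientation
  match_grating <- function(ori) {
    d <- abs(wrap_angle(2 * (st$ori1[st$kind == "grating"] - ori)))
    id <- grat_ids[which.min(d)]
    if (min(d) > 1e-6) {
      abort(sprintf("Plaid component orientation %.3f rad has no matching grating stimulus.", ori))
    }
    id
  }
  comp1 <- vapply(plaid_definitions$ori1, match_grating, character(1))
  comp2 <- vapply(plaid_definitions$ori2, match_grating, character(1))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  # wide array: neuron x grating x trial
  neurons <- sort(unique(gratings$neuron))
  trials <- sort(unique(gratings$trial))
  arr <- array(NA_real_,
               c(length(neurons), length(grat_ids), length(trials)),
               dimnames = list(NULL, grat_ids, NULL))
  arr[cbind(match(gratings$neuron, neurons),
            match(gratings$stimulus_id, grat_ids),
            match(gratings$trial, trials))] <- gratings$response
  n_n <- length(neurons); n_t <- length(trials)
  scale_fac <- if (combine == "sum") 1 else 0.5
  stim_all <- bind_rows(
    filter(st, .data$kind == "grating"),
    mutate(plaid_definitions, kind = "plaid"))
  r2s <- vapply(seq_len(n_boot), function(b) {
    plaid_rows <- list_rbind(map(seq_len(nrow(plaid_definitions)), function(p) {
      t1 <- matrix(sample.int(n_t, n_n * n_t, replace = TRUE), n_n, n_t)
      t2 <- matrix(sample.int(n_t, n_n * n_t, replace = TRUE), n_n, n_t)
      g1 <- arr[, comp1[p], ]; g2 <- arr[, comp2[p], ]
      rowi <- rep(seq_len(n_n), n_t)
      synth <- (g1[cbind(rowi, as.vector(t1))] +
                  g2[cbind(rowi, as.vector(t2))]) * scale_fac
      tibble(neuron = neurons[rowi],
             stimulus_id = plaid_definitions$stimulus_id[p],
             trial = rep(trials, each = n_n),
             response = synth)
    }))
    tbl <- response_table(bind_rows(as_tibble(gratings), plaid_rows),
                          stim_all)
    pairs <- pairwise_correlations(tbl, max_pairs = max_pairs)
    grating_plaid_r2(pairs, osi_threshold)
  }, numeric(1))
  out <- tibble(sample = seq_len(n_boot), r2 = r2s)
  class(out) <- c("bootstrap_control", class(out))
  out
}

#' @rdname bootstrap_component_control
#' @param x A `bootstrap_control` tibble.
#' @param ... Unused.
#' @export
glance.bootstrap_control <- function(x, ...) {
  tibble(median_r2 = median(x$r2),
         ci_lower = quantile(x$r2, 0.025, names = FALSE),
         ci_upper = quantile(x$r2, 0.975, names = FALSE),
         n_boot = nrow(x))
}
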