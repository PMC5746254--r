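# Trial-structured response tables: the tidy exchange format between the
# simulator, the variability model and the response metrics.

#' Construct a response table
#'
#' A response table is a tidy tibble of scalar responses with columns
#' `neuron`, `stimulus_id`, `trial`, `response`, carrying its stimulus
#' metadata (a [build_stimulus_protocol()] tibble) as attribute
#' `"stimuli"`. Responses are in arbitrary response units (steady-state Hz
#' for model output, dF/F-like units for synthetic data).
#'
#' @param responses Tibble/data frame with columns `neuron`, `stimulus_id`,
#'   `trial`, `response`.
#' @param stimuli The stimulus metadata tibble.
#' @return A `response_table`.
#' @export
response_table <- function(responses, stimuli) {
  need <- c("neuron", "stimulus_id", "trial", "response")
  if (!all(need %in% names(responses))) {
    abort("`responses` needs columns neuron, stimulus_id, trial, response.")
  }
  if (!all(responses$stimulus_id %in% stimuli$stimulus_id)) {
    abort("All stimulus_id values must appear in `stimuli`.")
  }
  out <- as_tibble(responses)[need]
  class(out) <- c("response_table", class(out))
  attr(out, "stimuli") <- stimuli
  out
}

response_stimuli <- function(table) {
  st <- attr(table, "stimuli")
  if (is.null(st)) abort("Response table has no stimulus metadata.")
  st
}

#' Trial-averaged responses
#'
#' Collapses a response table over trials: one row per neuron and stimulus
#' with the trial mean, plus each neuron's maximum trial-averaged response
#' `r_max` over the full stimulus set.
#'
#' @param table A [response_table()].
#' @return A tibble `neuron`, `stimulus_id`, `response`, `r_max`, with the
#'   stimulus metadata preserved.
#' @export
trial_means <- function(table) {
  st <- response_stimuli(table)
  out <- table |>
    group_by(.data$neuron, .data$stimulus_id) |>
    summarise(response = mean(.data$response), .groups = "drop_last") |>
    mutate(r_max = max(.data$response)) |>
    ungroup()
  attr(out, "stimuli") <- st
  out
}

#' Read/write response tables as CSV
#'
#' The response rows go to `<path>.csv` and the stimulus metadata to
#' `<path>_stimuli.csv`.
#'
#' @param table A [response_table()].
#' @param path File stem (no extension).
#' @export
write_response_table <- function(table, path) {
  utils::write.csv(as_tibble(table), paste0(path, ".csv"),
                   row.names = FALSE)
  utils::write.csv(as_tibble(response_stimuli(table)),
                   paste0(path, "_stimuli.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  responses <- utils::read.csv(paste0(path, ".csv"))
  stimuli <- as_tibble(utils::read.csv(paste0(path, "_stimuli.csv")))
  response_table(responses, stimuli)
}

#' Default stimulus amplitude for a network size
#'
#' The total injected current (pA) used when a protocol does not fix one:
#' 5 pA per network neuron. With the nominal tuning width and cortical
#' gains this drives peak steady-state single-neuron rates into a
#' physiological 1-50 Hz band across the connectivity rules.
#'
#' @param n_neurons Network size.
#' @return Amplitude in pA.
#' @export
default_stimulus_amplitude <- function(n_neurons) {
  5 * n_neurons
}

#' Steady-state responses to a stimulus protocol
#'
#' Runs every stimulus of a protocol through a network model: builds the
#' per-neuron input currents, solves the noise-free fixed point, and
#' records each neuron's steady-state firing rate as its mean response to
#' that stimulus.
#'
#' @param network A [build_v1_network()] result, or a list with elements
#'   `model` ([network_model()]) and `layout` ([place_population()]).
#' @param protocol A [build_stimulus_protocol()] stimulus set.
#' @param amplitude Total injected current per stimulus, pA; default
#'   [default_stimulus_amplitude()] for the network size, overridden by
#'   per-stimulus amplitudes in the protocol where set.
#' @param tolerance Fixed-point residual tolerance, pA; default scales with
#'   the peak input current.
#' @param max_iterations Fixed-point iteration cap per stimulus.
#' @param average_iterations For stimuli that have not converged after
#'   `max_iterations` (e.g. oscillatory winner-take-all competition), the
#'   iteration continues for this many further steps and the reported
#'   response is the mean rate over that window - the discrete analogue of
#'   averaging the tail of a simulated stimulus presentation. Default 500.
#' @param warn_nonconverged Emit a warning listing stimuli whose fixed
#'   point did not converge (their responses are reported as tail
#'   averages).
#' @return A tibble `neuron`, `stimulus_id`, `response` (Hz) of class
#'   `response_means`, with `stimuli` and a per-stimulus `converged` tibble
#'   as attributes.
#' @export
simulate_protocol <- function(network, protocol, amplitude = NULL,
                              tolerance = NULL, max_iterations = 5000,
                              average_iterations = 500,
                              warn_nonconverged = TRUE) {
  model <- network$model
  layout <- network$layout
  stopifnot(inherits(model, "network_model"))
  n <- model$n_neurons
  amplitude <- amplitude %||% default_stimulus_amplitude(n)
  rho <- spectral_radius_estimate(model$weights)
  damping <- min(0.5, 1.5 / (2 + rho))
  # all stimuli are iterated together: one sparse matrix product per
  # damped fixed-point step covers the whole battery
  inputs <- vapply(seq_len(nrow(protocol)), function(k) {
    stim <- protocol[k, ]
    A <- if (is.finite(stim$amplitude)) stim$amplitude else amplitude
    stimulus_input(layout, stim, amplitude = A)
  }, numeric(n))
  tol <- tolerance %||% (1e-6 * max(abs(inputs), 1))
  n_stim <- ncol(inputs)
  X <- matrix(0, n, n_stim)
  active <- rep(TRUE, n_stim)
  conv <- rep(FALSE, n_stim)
  beta <- model$beta
  cap <- 1e6
  for (iter in seq_len(max_iterations)) {
    idx <- which(active)
    R <- X[, idx, drop = FALSE] - beta
    R[R < 0] <- 0
    resid <- as.matrix(model$weights %*% R) + inputs[, idx, drop = FALSE] -
      X[, idx, drop = FALSE]
    rmax <- apply(abs(resid), 2, max)
    done <- rmax <= tol
    conv[idx[done]] <- TRUE
    X[, idx, drop = FALSE] -> Xa
    Xa <- Xa + damping * resid
    X[, idx] <- Xa
    active[idx] <- !done & apply(abs(Xa), 2, max) <= cap
    if (!any(active)) break
  }
  rates <- X - beta
  rates[rates < 0] <- 0
  rates <- model$alpha * rates
  if (any(!conv) && average_iterations > 0) {
    # oscillatory stimuli: report tail-averaged rates instead
    idx <- which(!conv)
    Xa <- X[, idx, drop = FALSE]
    acc <- 0 * Xa
    for (iter in seq_len(average_iterations)) {
      R <- Xa - beta
      R[R < 0] <- 0
      resid <- as.matrix(model$weights %*% R) + inputs[, idx, drop = FALSE] - Xa
      Xa <- Xa + damping * resid
      Xa[Xa > 1e6] <- 1e6; Xa[Xa < -1e6] <- -1e6
      Ra <- Xa - beta
      Ra[Ra < 0] <- 0
      acc <- acc + Ra
    }
    rates[, idx] <- model$alpha * acc / average_iterations
  }
  if (warn_nonconverged && any(!conv)) {
    warn(sprintf("Fixed point did not converge for %d/%d stimuli (%s); tail-averaged rates reported.",
                 sum(!conv), length(conv),
                 paste(protocol$stimulus_id[!conv], collapse = ", ")))
  }
  out <- tibble(
    neuron = rep(seq_len(n), n_stim),
    stimulus_id = rep(protocol$stimulus_id, each = n),
    response = as.vector(rates))
  class(out) <- c("response_means", class(out))
  attr(out, "stimuli") <- protocol
  attr(out, "converged") <- tibble(stimulus_id = protocol$stimulus_id,
                                   converged = conv)
  out
}
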