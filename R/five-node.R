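#' Configuration of the five-node analytical model
#'
#' The analytical model has four excitatory neurons split into two
#' subnetworks of two, plus one inhibitory neuron that pools all excitatory
#' activity. A proportion `s` of each excitatory neuron's output synapses is
#' reserved for its own subnetwork; connections to and from the inhibitory
#' node are non-specific.
#'
#' The default total output weights are derived from nominal cortical
#' anatomy and physiology: each excitatory neuron makes 8142 local synapses
#' at 0.01 pA/Hz with an I-F gain of 0.066 Hz/pA, giving
#' `w_E = 8142 * 0.01 * 0.066 ~= 5.37`; each inhibitory neuron makes 8566
#' synapses ten times stronger, giving `w_I = 8566 * 0.1 * 0.066 ~= 56.5`.
#'
#' @param s Proportion of subnetwork-specific excitatory synapses, in `[0, 1]`.
#' @param w_E Total excitatory output weight (unitless). Default the nominal
#'   cortical derivation above.
#' @param w_I Total inhibitory output weight (unitless).
#' @param f_I Proportion of inhibitory neurons (default 1/5, i.e. one of the
#'   five nodes).
#' @param tau Time constant, ms.
#' @param iota Stimulus input current, pA (default 1).
#'
#' @return A `five_node_config`.
#' @export
five_node_config <- function(s = 0,
                             w_E = 8142 * 0.01 * 0.066,
                             w_I = 8566 * 0.1 * 0.066,
                             f_I = 1 / 5, tau = 10, iota = 1) {
  stopifnot_scalar_in(s, 0, 1, "s")
  stopifnot_scalar_in(f_I, 1e-9, 1 - 1e-9, "f_I")
  if (w_E < 0 || w_I < 0) abort("`w_E` and `w_I` must be non-negative.")
  if (tau <= 0) abort("`tau` must be positive.")
  structure(list(s = s, w_E = w_E, w_I = w_I, f_I = f_I, tau = tau,
                 iota = iota),
            class = "five_node_config")
}

#' @export
print.five_node_config <- function(x, ...) {
  cat(sprintf("<five_node_config> s = %g, w_E = %.3f, w_I = %.3f, f_I = %g, tau = %g ms, iota = %g pA\n",
              x$s, x$w_E, x$w_I, x$f_I, x$tau, x$iota))
  invisible(x)
}

#' Five-node weight matrix
#'
#' Builds the 5 x 5 weight matrix of the analytical model. Within-subnetwork
#' excitatory entries (including the diagonal) are `a = w_S/2 + w_N/4`,
#' across-subnetwork entries are `b = w_N/4`, the inhibitory column carries
#' `-w_ie` for excitatory rows and `-w_I * f_I` at the inhibitory diagonal,
#' and the inhibitory row carries `w_ei` for excitatory columns, where
#' `w_S = w_E (1 - f_I) s`, `w_N = w_E (1 - f_I)(1 - s)`,
#' `w_ie = w_I (1 - f_I)/4` and `w_ei = w_E f_I`.
#'
#' Neurons 1-2 form subnetwork 1, neurons 3-4 subnetwork 2, neuron 5 is
#' inhibitory.
#'
#' @param config A [five_node_config()].
#' @return A 5 x 5 numeric matrix.
#' @export
build_five_node_weights <- function(config) {
  stopifnot(inherits(config, "five_node_config"))
  w_S <- config$w_E * (1 - config$f_I) * config$s
  w_N <- config$w_E * (1 - config$f_I) * (1 - config$s)
  a <- w_S / 2 + w_N / 4
  b <- w_N / 4
  w_ie <- config$w_I * (1 - config$f_I) / 4
  w_ei <- config$w_E * config$f_I
  W <- matrix(0, 5, 5)
  W[1:2, 1:2] <- a
  W[3:4, 3:4] <- a
  W[1:2, 3:4] <- b
  W[3:4, 1:2] <- b
  W[1:4, 5] <- -w_ie
  W[5, 1:4] <- w_ei
  W[5, 5] <- -config$w_I * config$f_I
  W
}

five_node_model <- function(config) {
  network_model(build_five_node_weights(config), tau = config$tau,
                is_inhibitory = c(rep(FALSE, 4), TRUE))
}

#' Jacobian stability classification
#'
#' Computes the Jacobian `J = (W - I) / T` of the rate dynamics linearised
#' around the all-active fixed point, where `T` holds the post-synaptic time
#' constant of each row. The network is stable iff all eigenvalue real parts
#' and the trace of `J` are non-positive. The regime label is:
#'
#' * `"AS"` - intrinsically stable: stable, and still stable with all
#'   inhibitory connections removed;
#' * `"ISN"` - inhibition-stabilised: stable, but the excitatory-only
#'   network (inhibitory outputs zeroed) is unstable;
#' * `"Exp"` - unstable with a real dominant eigenvalue (runaway activity);
#' * `"IO"` - unstable with a complex dominant pair (inhibition-driven
#'   oscillation).
#'
#' The weight structure of the five-node model is rank-deficient in a way
#' that makes the Jacobian spectrum purely real, so `"IO"` can never arise
#' from the eigenvalue rule there. Strong inhibition does, however,
#' produce sustained oscillation through the firing threshold (a nonlinear
#' limit cycle invisible to linearisation). With
#' `check_oscillation = TRUE`, a network classified stable by eigenvalues
#' is additionally simulated under a sustained single-neuron input; if the
#' trajectory has not settled by the end of the window the regime is
#' relabelled `"IO"`.
#'
#' @param W Square weight matrix. Columns flagged by `inhibitory` are zeroed
#'   for the excitatory-only test.
#' @param tau Per-neuron time constants (scalar or vector), ms.
#' @param inhibitory Logical vector marking inhibitory neurons; by default,
#'   neurons with any negative outgoing weight.
#' @param check_oscillation Also detect threshold-induced oscillation by
#'   simulation (default FALSE: pure eigenvalue classification).
#' @param probe_input Input vector for the oscillation probe; default
#'   1 pA into the first neuron.
#' @param probe_duration Probe simulation length, ms (default 2000; the
#'   final 10% is tested for settling).
#' @return A `stability_report`: eigenvalues of `J` and of the
#'   inhibition-removed `J_E`, traces, `stable` flag and `regime` label.
#' @export
classify_stability <- function(W, tau = 10, inhibitory = NULL,
                               check_oscillation = FALSE,
                               probe_input = NULL,
                               probe_duration = 2000) {
  if (is.null(dim(W)) || nrow(W) != ncol(W)) abort("`W` must be square.")
  W <- as.matrix(W)
  n <- nrow(W)
  if (length(tau) == 1L) tau <- rep(tau, n)
  stopifnot(length(tau) == n, all(tau > 0))
  if (is.null(inhibitory)) {
    inhibitory <- apply(W, 2, function(col) any(col < 0))
  }
  J <- (W - diag(n)) / tau  # row i divided by tau_i
  ev <- eigen(J, only.values = TRUE)$values
  tr <- sum(diag(J))
  tol <- 1e-12
  stable <- all(Re(ev) <= tol) && tr <= tol
  W_E <- W
  W_E[, inhibitory] <- 0
  J_E <- (W_E - diag(n)) / tau
  ev_E <- eigen(J_E, only.values = TRUE)$values
  tr_E <- sum(diag(J_E))
  exc_unstable <- max(Re(ev_E)) > tol || tr_E > tol
  regime <- if (stable) {
    if (exc_unstable) "ISN" else "AS"
  } else {
    dominant <- ev[which.max(Re(ev))]
    if (abs(Im(dominant)) > 1e-9) "IO" else "Exp"
  }
  if (stable && check_oscillation) {
    model <- network_model(W, tau = tau)
    probe_input <- probe_input %||% c(1, rep(0, n - 1))
    dt <- min(tau) / 10
    trj <- simulate_network(model, probe_input, probe_duration, dt = dt,
                            x0 = probe_input + 0.1)
    n_t <- nrow(trj$activations)
    tail_idx <- seq.int(max(1L, floor(0.9 * n_t)), n_t)
    settle <- max(apply(trj$activations[tail_idx, , drop = FALSE], 2, sd))
    if (trj$diverged || settle > 1e-4) {
      regime <- "IO"
      stable <- FALSE
    }
  }
  structure(
    list(eigenvalues = ev, trace = tr, eigenvalues_exc = ev_E,
         trace_exc = tr_E, stable = stable, regime = regime),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> regime %s (%s); max Re(eig) = %.4g, Tr(J) = %.4g\n",
              x$regime, if (x$stable) "stable" else "unstable",
              max(Re(x$eigenvalues)), x$trace))
  invisible(x)
}

#' @rdname classify_stability
#' @param x A `stability_report`.
#' @param ... Unused.
#' @export
glance.stability_report <- function(x, ...) {
  tibble(regime = x$regime, stable = x$stable,
         max_re_eigenvalue = max(Re(x$eigenvalues)), trace = x$trace,
         max_re_eigenvalue_exc = max(Re(x$eigenvalues_exc)),
         trace_exc = x$trace_exc)
}

#' @rdname classify_stability
#' @export
tidy.stability_report <- function(x, ...) {
  tibble(eigenvalue = x$eigenvalues,
         re = Re(x$eigenvalues), im = Im(x$eigenvalues),
         system = "full") |>
    bind_rows(tibble(eigenvalue = x$eigenvalues_exc,
                     re = Re(x$eigenvalues_exc), im = Im(x$eigenvalues_exc),
                     system = "excitatory_only"))
}

#' Net recurrent current into the opposite subnetwork
#'
#' Injects `iota` into a single excitatory neuron of subnetwork 1, solves the
#' noise-free fixed point, and returns the total recurrent synaptic current
#' (excitatory plus inhibitory, excluding leak and stimulus) received by an
#' excitatory neuron of subnetwork 2. Negative values indicate competition
#' between subnetworks.
#'
#' @param config A [five_node_config()].
#' @param ... Passed to [fixed_point()] (e.g. `tolerance`).
#' @return Net recurrent current, pA (scalar).
#' @export
competition_current <- function(config, ...) {
  stopifnot(inherits(config, "five_node_config"))
  model <- five_node_model(config)
  if (config$w_E == 0 && config$w_I == 0) return(0)
  ss <- fixed_point(model, c(config$iota, 0, 0, 0, 0), ...)
  if (!ss$converged) {
    report <- classify_stability(model$weights, config$tau)
    abort(sprintf(
      "Fixed point did not converge (regime %s); competition is undefined here.",
      report$regime))
  }
  drive <- recurrent_drive(model, ss$activations)
  drive[3]
}

#' Stability/competition phase diagram
#'
#' Classifies the network regime (and, where stable, the competition
#' current) over a grid of parameter values, sweeping any two fields of a
#' [five_node_config()] - typically total inhibitory weight `w_I` against
#' total excitatory weight `w_E`, or specificity `s` against `w_E`.
#'
#' @param x_values,y_values Grid values for the two swept parameters.
#' @param x_param,y_param Names of the swept config fields
#'   (`"w_E"`, `"w_I"` or `"s"`).
#' @param config Template [five_node_config()] supplying the fixed fields.
#' @param competition Also compute [competition_current()] where stable
#'   (default TRUE).
#' @param check_oscillation Detect threshold-induced oscillation (regime
#'   `"IO"`) by simulation in cells classified stable by eigenvalues
#'   (default TRUE; see [classify_stability()]).
#' @return A `phase_diagram` tibble with one row per grid cell: the swept
#'   values, `regime`, `stable` and `competition` (NA where unstable or not
#'   requested).
#' @export
phase_diagram <- function(x_values, y_values, x_param = "w_I",
                          y_param = "w_E", config = five_node_config(),
                          competition = TRUE, check_oscillation = TRUE) {
  stopifnot(inherits(config, "five_node_config"))
  ok <- c("w_E", "w_I", "s")
  if (!x_param %in% ok || !y_param %in% ok || x_param == y_param) {
    abort("`x_param` and `y_param` must be distinct fields among w_E, w_I, s.")
  }
  if (length(x_values) == 0 || length(y_values) == 0) {
    abort("Grid must be non-empty.")
  }
  grid <- crossing(.x = x_values, .y = y_values)
  rows <- pmap(list(grid$.x, grid$.y), function(xv, yv) {
    cfg <- config
    cfg[[x_param]] <- xv
    cfg[[y_param]] <- yv
    report <- classify_stability(build_five_node_weights(cfg), cfg$tau,
                                 check_oscillation = check_oscillation)
    comp <- NA_real_
    if (competition && report$stable) {
      comp <- tryCatch(competition_current(cfg), error = function(e) NA_real_)
    }
    tibble(!!x_param := xv, !!y_param := yv, regime = report$regime,
           stable = report$stable, competition = comp)
  })
  out <- list_rbind(rows)
  class(out) <- c("phase_diagram", class(out))
  attr(out, "params") <- c(x = x_param, y = y_param)
  out
}

#' @rdname phase_diagram
#' @param object A `phase_diagram`.
#' @param ... Unused.
#' @export
autoplot.phase_diagram <- function(object, ...) {
  params <- attr(object, "params")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[params[["x"]]]], y = .data[[params[["y"]]]],
    fill = .data$regime)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = params[["x"]], y = params[["y"]],
                  title = "Network stability regimes") +
    ggplot2::theme_minimal()
}

#' Graduated stimulus-mixture experiment
#'
#' Presents a linear graduated mixture between the ideal stimuli of the two
#' excitatory subnetworks: at mixture level `m` percent, subnetwork-1
#' neurons receive `(1 - m/100) * iota` and subnetwork-2 neurons
#' `m/100 * iota`. Steady-state rates are recorded at each level, together
#' with the winning subnetwork (larger mean excitatory rate; `"tie"` when
#' the difference is below `1e-6` Hz). A reference response is also
#' computed: the mean subnetwork-1 rate when only subnetwork 1 is driven at
#' half input, mimicking a single grating component of a plaid.
#'
#' @param config A [five_node_config()].
#' @param mixture_levels Mixture percentages in `[0, 100]`.
#' @param ... Passed to [fixed_point()].
#' @return A `mixture_result` tibble: `mixture`, per-neuron rates
#'   (`rate_e1`..`rate_i`), mean subnetwork rates, `winner`, `converged`.
#'   The single-component reference rate is attached as attribute
#'   `"reference"` and reported by [glance()].
#' @export
mixture_experiment <- function(config, mixture_levels = seq(0, 100, by = 5),
                               ...) {
  stopifnot(inherits(config, "five_node_config"))
  if (any(mixture_levels < 0 | mixture_levels > 100)) {
    abort("`mixture_levels` must lie in [0, 100].")
  }
  mixture_levels <- sort(mixture_levels)
  model <- five_node_model(config)
  iota <- config$iota
  solve_level <- function(m) {
    frac <- m / 100
    I <- c(rep((1 - frac) * iota, 2), rep(frac * iota, 2), 0)
    ss <- fixed_point(model, I, ...)
    r <- ss$rates
    sn1 <- mean(r[1:2]); sn2 <- mean(r[3:4])
    winner <- if (!ss$converged) NA_character_
      else if (abs(sn1 - sn2) < 1e-6) "tie"
      else if (sn1 > sn2) "SN1" else "SN2"
    tibble(mixture = m, rate_e1 = r[1], rate_e2 = r[2], rate_e3 = r[3],
           rate_e4 = r[4], rate_i = r[5], rate_sn1 = sn1, rate_sn2 = sn2,
           winner = winner, converged = ss$converged)
  }
  out <- list_rbind(map(mixture_levels, solve_level))
  ref_ss <- fixed_point(model, c(rep(iota / 2, 2), 0, 0, 0), ...)
  reference <- if (ref_ss$converged) mean(ref_ss$rates[1:2]) else NA_real_
  class(out) <- c("mixture_result", class(out))
  attr(out, "reference") <- reference
  attr(out, "config") <- config
  out
}

#' @rdname mixture_experiment
#' @param x A `mixture_result`.
#' @export
glance.mixture_result <- function(x, ...) {
  tibble(
    reference_rate = attr(x, "reference"),
    peak_rate_sn1 = max(x$rate_sn1, na.rm = TRUE),
    peak_rate_sn2 = max(x$rate_sn2, na.rm = TRUE),
    n_levels = nrow(x),
    all_converged = all(x$converged)
  )
}

#' @rdname mixture_experiment
#' @param object A `mixture_result`.
#' @param ... Unused.
#' @export
autoplot.mixture_result <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("rate_sn1", "rate_sn2"),
                              names_to = "subnetwork", values_to = "rate")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mixture, y = .data$rate,
                                          colour = .data$subnetwork)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Mixture (% subnetwork 2 input)", y = "Rate (Hz)",
                  title = "Graduated stimulus mixture") +
    ggplot2::theme_minimal()
  ref <- attr(object, "reference")
  if (is.finite(ref)) {
    p <- p + ggplot2::geom_hline(yintercept = ref, linetype = "dashed")
  }
  p
}
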