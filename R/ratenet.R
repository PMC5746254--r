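#' Linear-threshold current-to-rate transfer function
#'
#' Converts an activation current into a firing rate under the
#' linear-threshold I-F relationship `rate = alpha * max(0, x - beta)`.
#'
#' @param activation Activation current(s), in pA.
#' @param alpha I-F gain in Hz/pA (default 0.066, the nominal cortical value).
#' @param beta Activation threshold in pA (default 0).
#'
#' @return Firing rate(s) in Hz; never negative.
#' @examples
#' firing_rate(2, alpha = 0.066)   # 0.132 Hz
#' firing_rate(-1, alpha = 0.066)  # clamps to 0
#' @export
firing_rate <- function(activation, alpha = 0.066, beta = 0) {
  stopifnot_finite(activation, "activation")
  stopifnot_finite(alpha, "alpha")
  stopifnot_finite(beta, "beta")
  alpha * pmax(0, activation - beta)
}

#' Construct a rate-network model
#'
#' Bundles a square matrix of unitless synaptic gains `w[i, j]` (effect of
#' neuron `j` on the activation of neuron `i`; inhibitory columns negative)
#' with per-neuron linear-threshold parameters. The dynamics integrated by
#' [simulate_network()] are
#' `tau * dx_i/dt = -x_i + sum_j w_ij * max(0, x_j - beta_j) + I_i(t) + noise`,
#' with firing rates `r_i = alpha_i * max(0, x_i - beta_i)`.
#'
#' @param weights Square numeric matrix (dense or `Matrix` sparse) of unitless
#'   gains. Entry `(i, j)` is the gain from presynaptic neuron `j` onto
#'   postsynaptic neuron `i` and already folds in the presynaptic I-F gain
#'   (`w_ij = g_j * n_ij * alpha_j`).
#' @param tau Per-neuron time constant(s), ms. Default 10 ms.
#' @param alpha Per-neuron I-F gain(s), Hz/pA. Default 0.066.
#' @param beta Per-neuron threshold(s), pA. Default 0.
#' @param sigma_noise Per-neuron Wiener-noise standard deviation after 1 s, pA.
#'   Default 0 (deterministic dynamics).
#' @param is_inhibitory Optional logical vector of neuron class labels (kept
#'   as metadata; the sign convention lives in `weights`).
#'
#' @return An object of class `network_model`.
#' @export
network_model <- function(weights, tau = 10, alpha = 0.066, beta = 0,
                          sigma_noise = 0, is_inhibitory = NULL) {
  if (is.null(dim(weights)) || nrow(weights) != ncol(weights)) {
    abort("`weights` must be a square matrix.")
  }
  n <- nrow(weights)
  if (inherits(weights, "sparseMatrix")) {
    if (!all(is.finite(weights@x))) abort("`weights` must be finite.")
  } else {
    weights <- as.matrix(weights)
    stopifnot_finite(weights, "weights")
  }
  rep_n <- function(x, what) {
    stopifnot_finite(x, what)
    if (length(x) == 1L) rep(x, n) else if (length(x) == n) x else
      abort(sprintf("`%s` must have length 1 or %d.", what, n))
  }
  tau <- rep_n(tau, "tau")
  if (any(tau <= 0)) abort("`tau` must be positive.")
  alpha <- rep_n(alpha, "alpha")
  if (any(alpha < 0)) abort("`alpha` must be non-negative.")
  beta <- rep_n(beta, "beta")
  sigma_noise <- rep_n(sigma_noise, "sigma_noise")
  if (any(sigma_noise < 0)) abort("`sigma_noise` must be non-negative.")
  if (!is.null(is_inhibitory)) {
    stopifnot(is.logical(is_inhibitory), length(is_inhibitory) == n)
  }
  structure(
    list(weights = weights, tau = tau, alpha = alpha, beta = beta,
         sigma_noise = sigma_noise, is_inhibitory = is_inhibitory,
         n_neurons = n),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d neurons", x$n_neurons))
  if (!is.null(x$is_inhibitory)) {
    cat(sprintf(" (%d inhibitory)", sum(x$is_inhibitory)))
  }
  cat(sprintf("; tau %g ms; %s weights\n", x$tau[1],
              if (inherits(x$weights, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

# Recurrent drive W %*% max(0, x - beta); returns a plain numeric vector.
recurrent_drive <- function(model, x) {
  as.numeric(model$weights %*% pmax(0, x - model$beta))
}

# Crude largest-|eigenvalue| estimate of the weight matrix by power
# iteration, used to pick a stable damping factor for fixed-point iteration.
spectral_radius_estimate <- function(W, iterations = 30) {
  n <- nrow(W)
  v <- rep(1, n) + sin(seq_len(n))  # deterministic, not axis-aligned
  v <- v / sqrt(sum(v^2))
  rho <- 0
  for (k in seq_len(iterations)) {
    v2 <- as.numeric(W %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) return(0)
    rho <- nv
    v <- v2 / nv
  }
  rho
}

resolve_input <- function(input, n, what = "input") {
  if (is.function(input)) return(input)
  input <- as.numeric(input)
  stopifnot_finite(input, what)
  if (length(input) == 1L) input <- rep(input, n)
  if (length(input) != n) {
    abort(sprintf("`%s` must have length 1 or %d (one per neuron).", what, n))
  }
  force(input)
  function(t) input
}

#' Integrate rate-network dynamics (Euler-Maruyama)
#'
#' Fixed-step Euler-Maruyama integration of the linear-threshold rate
#' dynamics. With `sigma_noise = 0` and a fixed input the trajectory is
#' deterministic; otherwise each step adds an independent Gaussian increment
#' with standard deviation `sigma_noise * sqrt(dt / 1000)` to each activation
#' (so that the accumulated noise has standard deviation `sigma_noise` after
#' one second).
#'
#' @param model A [network_model()].
#' @param input Constant per-neuron input current (scalar or length-n vector,
#'   pA), or a function `input(t)` returning such a vector for time `t` in ms.
#' @param duration Total simulated time, ms.
#' @param dt Integration step, ms; must satisfy `dt <= min(tau)/5`.
#' @param x0 Initial activations (default all zero).
#' @param seed Optional integer seed for the noise stream; runs with the same
#'   seed are bit-reproducible.
#' @param cap Activation magnitude (pA) beyond which the run is flagged as
#'   diverged and integration stops. Default `1e6`.
#'
#' @return A `rate_trajectory`: list with `times` (ms), `activations` and
#'   `rates` (time-by-neuron matrices), and a `diverged` flag. Use [tidy()]
#'   for a long tibble.
#' @export
simulate_network <- function(model, input, duration, dt = 1, x0 = NULL,
                             seed = NULL, cap = 1e6) {
  stopifnot(inherits(model, "network_model"))
  if (dt <= 0) abort("`dt` must be positive.")
  if (dt > min(model$tau) / 5) {
    abort(sprintf("`dt` = %g ms is too large; must be <= min(tau)/5 = %g ms.",
                  dt, min(model$tau) / 5))
  }
  n <- model$n_neurons
  input_fn <- resolve_input(input, n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n_steps <- max(1L, ceiling(duration / dt))
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  X <- matrix(NA_real_, n_steps + 1L, n)
  x <- if (is.null(x0)) rep(0, n) else {
    stopifnot(length(x0) == n)
    as.numeric(x0)
  }
  X[1L, ] <- x
  noisy <- any(model$sigma_noise > 0)
  noise_sd <- model$sigma_noise * sqrt(dt / 1000)
  diverged <- FALSE
  for (k in seq_len(n_steps)) {
    t_k <- times[k]
    drive <- recurrent_drive(model, x)
    dx <- (dt / model$tau) * (-x + drive + input_fn(t_k))
    x <- x + dx
    if (noisy) x <- x + rnorm(n, 0, noise_sd)
    if (any(abs(x) > cap)) {
      diverged <- TRUE
      X[k + 1L, ] <- x
      X <- X[seq_len(k + 1L), , drop = FALSE]
      times <- times[seq_len(k + 1L)]
      break
    }
    X[k + 1L, ] <- x
  }
  rates <- sweep(X, 2, model$beta, "-")
  rates[rates < 0] <- 0
  rates <- sweep(rates, 2, model$alpha, "*")
  structure(
    list(times = times, activations = X, rates = rates, diverged = diverged,
         dt = dt),
    class = "rate_trajectory"
  )
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf("<rate_trajectory> %d neurons x %d samples (%g ms)%s\n",
              ncol(x$rates), length(x$times), max(x$times),
              if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' @rdname simulate_network
#' @param x A `rate_trajectory`.
#' @param ... Unused.
#' @export
tidy.rate_trajectory <- function(x, ...) {
  n <- ncol(x$rates)
  tibble(
    time = rep(x$times, times = n),
    neuron = rep(seq_len(n), each = length(x$times)),
    activation = as.vector(x$activations),
    rate = as.vector(x$rates)
  )
}

#' Mean steady-state rates from the tail of a trajectory
#'
#' Averages firing rates over the final fraction of a simulated window, the
#' package's standard readout for stimulus responses from noisy simulations.
#'
#' @param trajectory A `rate_trajectory`.
#' @param fraction Final fraction of the window to average over (default 0.2).
#' @return Numeric vector of mean rates (Hz), one per neuron.
#' @export
steady_rates <- function(trajectory, fraction = 0.2) {
  stopifnot(inherits(trajectory, "rate_trajectory"))
  stopifnot_scalar_in(fraction, 0, 1, "fraction")
  n_t <- length(trajectory$times)
  keep <- seq.int(max(1L, ceiling(n_t * (1 - fraction))), n_t)
  colMeans(trajectory$rates[keep, , drop = FALSE])
}

#' Noise-free network fixed point
#'
#' Locates a steady state of the noise-free dynamics by damped fixed-point
#' iteration of the nullcline `x = W * max(0, x - beta) + I`. The damping
#' factor is equivalent to an Euler step of `damping * tau` ms; `"auto"`
#' picks a value from a power-iteration estimate of the spectral radius of
#' the weight matrix, which keeps the iteration stable for strongly coupled
#' (inhibition-stabilised) networks.
#'
#' @param model A [network_model()].
#' @param input Constant per-neuron input current (scalar or vector, pA).
#' @param tolerance Convergence tolerance on the residual
#'   `max |x - W max(0, x - beta) - I|`, pA. Default `1e-8`.
#' @param max_iterations Iteration cap. Default 10000.
#' @param damping Damping factor in (0, 1], or `"auto"`.
#' @param x0 Starting activations (default zero).
#' @param cap Divergence cap on `|x|`, pA.
#'
#' @return A `steady_state`: list with `activations`, `rates`, `converged`,
#'   `diverged`, `residual` and `iterations`. A non-converged result signals
#'   instability or oscillation at the probed input.
#' @export
fixed_point <- function(model, input, tolerance = 1e-8,
                        max_iterations = 10000, damping = "auto",
                        x0 = NULL, cap = 1e6) {
  stopifnot(inherits(model, "network_model"))
  n <- model$n_neurons
  input_fn <- resolve_input(input, n)
  I <- input_fn(0)
  stopifnot_finite(I, "input")
  if (identical(damping, "auto")) {
    rho <- spectral_radius_estimate(model$weights)
    damping <- min(0.5, 1.5 / (2 + rho))
  }
  stopifnot_scalar_in(damping, 1e-6, 1, "damping")
  x <- if (is.null(x0)) rep(0, n) else as.numeric(x0)
  converged <- FALSE
  diverged <- FALSE
  residual <- Inf
  iter <- 0L
  for (iter in seq_len(max_iterations)) {
    target <- recurrent_drive(model, x) + I
    resid <- target - x
    residual <- max(abs(resid))
    if (residual <= tolerance) {
      converged <- TRUE
      break
    }
    x <- x + damping * resid
    if (any(abs(x) > cap)) {
      diverged <- TRUE
      break
    }
  }
  structure(
    list(activations = x,
         rates = firing_rate(x, model$alpha, model$beta),
         converged = converged, diverged = diverged,
         residual = residual, iterations = iter, damping = damping),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> %d neurons; %s (residual %.3g after %d iterations)%s\n",
              length(x$activations),
              if (x$converged) "converged" else "NOT converged",
              x$residual, x$iterations,
              if (x$diverged) " [diverged]" else ""))
  invisible(x)
}

#' @rdname fixed_point
#' @param x A `steady_state`.
#' @param ... Unused.
#' @export
tidy.steady_state <- function(x, ...) {
  tibble(neuron = seq_along(x$activations),
         activation = x$activations, rate = x$rates)
}

#' Serialise a network model to plain-text files
#'
#' Writes the weight matrix in Matrix Market format (`<path>.mtx`) and the
#' per-neuron parameters as a JSON sidecar (`<path>.json`).
#'
#' @param model A [network_model()].
#' @param path File stem (without extension).
#' @return `path`, invisibly.
#' @export
write_network <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  W <- methods::as(methods::as(Matrix::Matrix(model$weights, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(W, paste0(path, ".mtx"))
  side <- list(tau = model$tau, alpha = model$alpha, beta = model$beta,
               sigma_noise = model$sigma_noise,
               is_inhibitory = model$is_inhibitory)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  W <- Matrix::readMM(paste0(path, ".mtx"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  network_model(methods::as(W, "CsparseMatrix"),
                tau = side$tau, alpha = side$alpha, beta = side$beta,
                sigma_noise = side$sigma_noise,
                is_inhibitory = side$is_inhibitory)
}
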