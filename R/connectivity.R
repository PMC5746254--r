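# Connectivity generators: Peters'-rule random, like-to-like, and
# feature-binding synapse probability distributions, plus multinomial
# synapse drawing with density scaling.

# Wrapped (periodic image-sum) Gaussian overlap kernel. For each target,
# returns sum_k exp(-(dx + k*W)^2 / (2 sigma2)) * (same in y), the exact
# torus integral of the product of two periodic Gaussian fields with
# combined variance sigma2 (up to a constant factor that cancels on
# normalisation).
wrapped_gaussian_kernel <- function(dx, dy, sigma2, geometry) {
  sx <- 0; sy <- 0
  Kx <- max(1L, ceiling(4 * sqrt(sigma2) / geometry$width))
  Ky <- max(1L, ceiling(4 * sqrt(sigma2) / geometry$height))
  for (k in -Kx:Kx) sx <- sx + exp(-(dx + k * geometry$width)^2 / (2 * sigma2))
  for (k in -Ky:Ky) sy <- sy + exp(-(dy + k * geometry$height)^2 / (2 * sigma2))
  sx * sy
}

# Unnormalised Peters overlap from one source to all targets (self = 0).
peters_weights <- function(layout, source_index) {
  geom <- layout_geometry(layout)
  dx <- layout$x - layout$x[source_index]
  dy <- layout$y - layout$y[source_index]
  dx <- dx - round(dx / geom$width) * geom$width
  dy <- dy - round(dy / geom$height) * geom$height
  sigma2 <- layout$sigma_d^2 + layout$sigma_a[source_index]^2
  w <- wrapped_gaussian_kernel(dx, dy, sigma2[1], geom)
  if (length(unique(sigma2)) > 1L) {
    # dendritic dispersions differ across targets: recompute exactly
    w <- vapply(seq_len(nrow(layout)), function(i) {
      wrapped_gaussian_kernel(dx[i], dy[i], sigma2[i], geom)
    }, numeric(1))
  }
  w[source_index] <- 0  # no self-connections
  w
}

#' Peters'-rule connection probabilities
#'
#' Probability of forming a synapse from a source neuron onto every other
#' neuron, proportional to the overlap of the source's axonal Gaussian field
#' with each target's dendritic field, integrated over the torus. The
#' overlap is computed in closed form as a wrapped Gaussian of inter-soma
#' distance with variance `sigma_d^2 + sigma_a^2`, and normalised to sum to
#' one over targets. Self-connections are excluded.
#'
#' @param layout A [place_population()] layout with >= 2 neurons.
#' @param source_index Index of the presynaptic neuron.
#' @return Numeric probability vector over all neurons (source entry 0).
#' @export
peters_probability <- function(layout, source_index) {
  if (nrow(layout) < 2L) abort("Need at least 2 neurons.")
  normalise_prob(peters_weights(layout, source_index))
}

# Orientation-similarity weights from one excitatory source to excitatory
# targets (NA for inhibitory targets -> 0 weight).
ori_weights <- function(layout, source_index, kappa1) {
  th <- layout$ori
  w <- ifelse(is.na(th), 0, von_mises_ori(th, th[source_index], kappa1))
  w[source_index] <- 0
  w
}

#' Like-to-like connection probabilities
#'
#' Orientation-specific connectivity from an excitatory source neuron.
#' The share of output directed at inhibitory targets is fixed at its
#' Peters'-rule overlap share (connections to and from inhibitory neurons
#' are non-specific, and the excitatory-to-inhibitory weight must not
#' depend on the specificity parameters or the excitation/inhibition
#' balance would be destroyed). Within the excitatory-target share, a
#' proportion `s1` of the probability mass follows the
#' orientation-modulated distribution `[[p_Peters * p_ori]]` (von Mises
#' similarity of preferred orientation, doubled-angle convention) and the
#' remaining `1 - s1` follows plain Peters'-rule overlap. With `s1 = 0`
#' this is identical to [peters_probability()].
#'
#' @inheritParams peters_probability
#' @param s1 Proportional strength of like-to-like specificity, in `[0, 1]`.
#' @param kappa1 von Mises concentration of the orientation similarity
#'   (default 0.5).
#' @return Normalised probability vector over all neurons.
#' @export
like_to_like_probability <- function(layout, source_index, s1, kappa1 = 0.5) {
  stopifnot_scalar_in(s1, 0, 1, "s1")
  if (layout$inhibitory[source_index]) {
    abort("Source neuron must be excitatory for the like-to-like rule.")
  }
  pet <- peters_weights(layout, source_index)
  exc <- !layout$inhibitory
  share_exc <- sum(pet[exc]) / sum(pet)
  pet_exc <- ifelse(exc, pet, 0)
  p_inh <- ifelse(exc, 0, pet)
  p <- (1 - share_exc) * normalise_prob_or_zero(p_inh) +
    share_exc * (1 - s1) * normalise_prob(pet_exc)
  if (s1 > 0) {
    p <- p + share_exc * s1 *
      normalise_prob(pet_exc * ori_weights(layout, source_index, kappa1))
  }
  p
}

# normalise, returning all-zero for an all-zero vector (empty class share)
normalise_prob_or_zero <- function(p) {
  if (sum(p) <= 0) return(p * 0) else normalise_prob(p)
}

#' Smoothed complex orientation fields for subnetwork composition
#'
#' Draws a unit-magnitude complex number with a uniform random angle for
#' every neuron and every (subnetwork, component) pair, then smooths each
#' field by Gaussian-weighted summation over neuron positions on the torus.
#' The angle of the smoothed field at each neuron's position defines one
#' orientation component (doubled-angle convention) of one subnetwork
#' there; composition therefore varies smoothly across cortical space.
#'
#' @param layout A [place_population()] layout.
#' @param n_subnetworks Number of subnetworks `N_S` (default 6).
#' @param n_orientations Orientation components per subnetwork (default 2).
#' @param filter_sigma Gaussian smoothing dispersion, um (default 75).
#' @param seed Optional integer seed.
#' @return A `subnetwork_composition`: list with `theta`, an
#'   `n x n_subnetworks x n_orientations` array of component angles in
#'   `[-pi, pi)` (doubled-angle convention), plus the generating parameters.
#' @export
generate_subnetwork_fields <- function(layout, n_subnetworks = 6,
                                       n_orientations = 2, filter_sigma = 75,
                                       seed = NULL) {
  if (n_subnetworks < 1 || n_orientations < 1) {
    abort("`n_subnetworks` and `n_orientations` must be >= 1.")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  geom <- layout_geometry(layout)
  n <- nrow(layout)
  n_fields <- n_subnetworks * n_orientations
  zeta <- matrix(runif(n * n_fields, -pi, pi), n, n_fields)
  # real/imaginary parts of z = exp(-i * zeta)
  zr <- cos(zeta); zi <- -sin(zeta)
  Zr <- matrix(0, n, n_fields); Zi <- matrix(0, n, n_fields)
  block <- max(1L, floor(2e6 / n))
  starts <- seq(1L, n, by = block)
  for (b in starts) {
    idx <- b:min(b + block - 1L, n)
    dx <- outer(layout$x, layout$x[idx], "-")
    dx <- abs(dx - round(dx / geom$width) * geom$width)
    dy <- outer(layout$y, layout$y[idx], "-")
    dy <- abs(dy - round(dy / geom$height) * geom$height)
    G <- exp(-(dx^2 + dy^2) / (2 * filter_sigma^2))
    Zr[idx, ] <- crossprod(G, zr)
    Zi[idx, ] <- crossprod(G, zi)
  }
  theta <- array(atan2(Zi, Zr), dim = c(n, n_subnetworks, n_orientations))
  structure(
    list(theta = theta, n_subnetworks = n_subnetworks,
         n_orientations = n_orientations, filter_sigma = filter_sigma),
    class = "subnetwork_composition"
  )
}

#' @export
print.subnetwork_composition <- function(x, ...) {
  cat(sprintf("<subnetwork_composition> %d neurons x %d subnetworks x %d orientation components (filter %g um)\n",
              dim(x$theta)[1], x$n_subnetworks, x$n_orientations,
              x$filter_sigma))
  invisible(x)
}

#' Assign neurons to subnetworks
#'
#' Membership probability of neuron `i` in subnetwork `k` is proportional to
#' the best von Mises similarity (concentration `kappa2`) between the
#' neuron's preferred orientation and any of the subnetwork's orientation
#' components at the neuron's position, normalised over subnetworks; each
#' neuron is assigned to the argmax subnetwork. Inhibitory neurons (no
#' preferred orientation) receive `NA`.
#'
#' @param layout A [place_population()] layout.
#' @param composition A [generate_subnetwork_fields()] result.
#' @param kappa2 von Mises concentration for membership (default 4).
#' @return Integer vector of subnetwork indices (NA for inhibitory neurons).
#' @export
assign_membership <- function(layout, composition, kappa2 = 4) {
  stopifnot(inherits(composition, "subnetwork_composition"))
  n <- nrow(layout)
  stopifnot(dim(composition$theta)[1] == n)
  theta2 <- 2 * layout$ori  # doubled-angle preferred orientation
  sim <- matrix(-Inf, n, composition$n_subnetworks)
  for (k in seq_len(composition$n_subnetworks)) {
    best <- -Inf
    for (q in seq_len(composition$n_orientations)) {
      best <- pmax(best, exp(kappa2 * cos(theta2 - composition$theta[, k, q])))
    }
    sim[, k] <- best
  }
  m <- max.col(sim, ties.method = "first")
  m[layout$inhibitory | is.na(layout$ori)] <- NA_integer_
  m
}

#' Feature-binding connection probabilities
#'
#' Extends the like-to-like mixture with a subnetwork-binding component.
#' As in [like_to_like_probability()], the inhibitory-target share is fixed
#' at its Peters'-rule value; within the excitatory-target share, a
#' proportion `s2` of the probability mass is restricted to targets in the
#' same subnetwork as the source (Peters'-rule weighted), the remaining
#' `1 - s2` follows the like-to-like mixture with strength `s1`. With
#' `s2 = 0` this is identical to [like_to_like_probability()].
#'
#' @inheritParams like_to_like_probability
#' @param composition A [generate_subnetwork_fields()] result (used for its
#'   membership; may be `NULL` when `membership` is given).
#' @param membership Integer subnetwork index per neuron, as returned by
#'   [assign_membership()].
#' @param s2 Proportional strength of feature-binding specificity.
#' @return Normalised probability vector over all neurons.
#' @export
feature_binding_probability <- function(layout, composition, membership,
                                        source_index, s1, s2, kappa1 = 0.5) {
  stopifnot_scalar_in(s1, 0, 1, "s1")
  stopifnot_scalar_in(s2, 0, 1, "s2")
  if (layout$inhibitory[source_index]) {
    abort("Source neuron must be excitatory for the feature-binding rule.")
  }
  if (is.null(membership)) {
    membership <- assign_membership(layout, composition)
  }
  pet <- peters_weights(layout, source_index)
  exc <- !layout$inhibitory
  share_exc <- sum(pet[exc]) / sum(pet)
  pet_exc <- ifelse(exc, pet, 0)
  p_inh <- ifelse(exc, 0, pet)
  p <- (1 - share_exc) * normalise_prob_or_zero(p_inh) +
    share_exc * (1 - s2) * (1 - s1) * normalise_prob(pet_exc)
  if (s1 > 0 && s2 < 1) {
    p <- p + share_exc * (1 - s2) * s1 *
      normalise_prob(pet_exc * ori_weights(layout, source_index, kappa1))
  }
  if (s2 > 0) {
    same <- !is.na(membership) & membership == membership[source_index]
    same[source_index] <- FALSE
    bind_w <- pet_exc * as.numeric(same)
    if (sum(bind_w) <= 0) {
      if (s2 >= 1) {
        abort("No same-subnetwork targets available with s2 = 1; the binding distribution is undefined.")
      }
      warn("No same-subnetwork targets for this source; binding mass reassigned to the remaining mixture components.")
      p <- p / (1 - s2 * share_exc) # reweight: drop only the binding share
    } else {
      p <- p + share_exc * s2 * normalise_prob(bind_w)
    }
  }
  p
}

#' Connectivity rule specification
#'
#' Bundles the parameters of a connectivity generator. Presets follow the
#' published model configurations: `"random"` (`s1 = s2 = 0`),
#' `"like_to_like"` (`s1 = 0.8`, `kappa1 = 0.5`) and `"feature_binding"`
#' (`s1 = 0.1`, `s2 = 0.25`, `kappa1 = 0.5`, `kappa2 = 4`, 6 subnetworks of
#' 2 orientations). `"feature_binding_methods"` is an alternative published
#' parameterisation (`s1 = 0.45`, `s2 = 0.225`).
#'
#' @param rule One of `"random"`, `"like_to_like"`, `"feature_binding"`,
#'   `"feature_binding_methods"`.
#' @param s1,s2,kappa1,kappa2,n_subnetworks,n_orientations Override the
#'   preset values.
#' @param density_factor Fraction of nominal synapse budgets actually drawn
#'   (default 0.1); per-synapse strength is rescaled by its inverse so each
#'   neuron's total output weight is preserved.
#' @return A `connectivity_spec`.
#' @export
connectivity_spec <- function(rule = c("random", "like_to_like",
                                       "feature_binding",
                                       "feature_binding_methods"),
                              s1 = NULL, s2 = NULL, kappa1 = NULL,
                              kappa2 = NULL, n_subnetworks = NULL,
                              n_orientations = NULL, density_factor = 0.1) {
  rule <- match.arg(rule)
  preset <- switch(rule,
    random = list(s1 = 0, s2 = 0, kappa1 = 0.5, kappa2 = 4,
                  n_subnetworks = 6, n_orientations = 2),
    like_to_like = list(s1 = 0.8, s2 = 0, kappa1 = 0.5, kappa2 = 4,
                        n_subnetworks = 6, n_orientations = 2),
    feature_binding = list(s1 = 0.1, s2 = 0.25, kappa1 = 0.5, kappa2 = 4,
                           n_subnetworks = 6, n_orientations = 2),
    feature_binding_methods = list(s1 = 0.45, s2 = 0.225, kappa1 = 0.5,
                                   kappa2 = 4, n_subnetworks = 6,
                                   n_orientations = 2)
  )
  spec <- list(
    rule = if (rule == "feature_binding_methods") "feature_binding" else rule,
    s1 = s1 %||% preset$s1, s2 = s2 %||% preset$s2,
    kappa1 = kappa1 %||% preset$kappa1, kappa2 = kappa2 %||% preset$kappa2,
    n_subnetworks = n_subnetworks %||% preset$n_subnetworks,
    n_orientations = n_orientations %||% preset$n_orientations,
    density_factor = density_factor
  )
  stopifnot_scalar_in(spec$s1, 0, 1, "s1")
  stopifnot_scalar_in(spec$s2, 0, 1, "s2")
  if (density_factor <= 0) abort("`density_factor` must be positive.")
  structure(spec, class = "connectivity_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.connectivity_spec <- function(x, ...) {
  cat(sprintf("<connectivity_spec> rule %s: s1 = %g, s2 = %g, kappa1 = %g, kappa2 = %g, N_S = %d, components = %d, density_factor = %g\n",
              x$rule, x$s1, x$s2, x$kappa1, x$kappa2, x$n_subnetworks,
              x$n_orientations, x$density_factor))
  invisible(x)
}

#' Draw a synapse matrix over connection probability distributions
#'
#' Draws `round(synapse_budget * density_factor)` output synapses for every
#' neuron as a multinomial sample over that neuron's connection probability
#' vector. Excitatory sources use the distribution prescribed by the rule
#' in `spec`; inhibitory sources always use plain Peters'-rule overlap
#' (non-specific). Per-synapse strength is `g / density_factor` so that
#' each neuron's total output weight is independent of the density scaling;
#' unitless weights are assembled as `w_ij = g_j * n_ij * alpha_j`, negative
#' for inhibitory sources (10x stronger synapses by default).
#'
#' @param layout A [place_population()] layout.
#' @param spec A [connectivity_spec()].
#' @param composition,membership Subnetwork composition and membership
#'   (required for the feature-binding rule; generated on the fly from
#'   `seed` when omitted).
#' @param probabilities Optional pre-computed probabilities: a function
#'   `probabilities(source_index)` returning a probability vector over
#'   targets, overriding the rule in `spec`.
#' @param seed Optional integer seed for the multinomial draws (and field
#'   generation when needed).
#' @param g_exc Current per excitatory synapse, pA/Hz (default 0.01).
#' @param g_inh_multiple Inhibitory synapse strength relative to excitatory
#'   (default 10).
#' @param alpha I-F gain used in the weight assembly, Hz/pA (default 0.066).
#'
#' @return A `synapse_matrix`: list with sparse `counts` and signed
#'   `weights` matrices (rows = targets, columns = sources), the layout
#'   metadata and, for the feature-binding rule, the `membership` used.
#' @export
draw_synapses <- function(layout, spec, composition = NULL,
                          membership = NULL, probabilities = NULL,
                          seed = NULL, g_exc = 0.01, g_inh_multiple = 10,
                          alpha = 0.066) {
  stopifnot(inherits(spec, "connectivity_spec"))
  n <- nrow(layout)
  if (n < 2L) abort("Need at least 2 neurons.")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  if (spec$rule == "feature_binding" && is.null(probabilities)) {
    if (is.null(membership)) {
      if (is.null(composition)) {
        composition <- generate_subnetwork_fields(
          layout, spec$n_subnetworks, spec$n_orientations)
      }
      membership <- assign_membership(layout, composition, spec$kappa2)
    }
  }
  prob_for <- probabilities %||% function(j) {
    if (layout$inhibitory[j]) {
      peters_probability(layout, j)
    } else {
      switch(spec$rule,
        random = peters_probability(layout, j),
        like_to_like = like_to_like_probability(layout, j, spec$s1,
                                                spec$kappa1),
        feature_binding = feature_binding_probability(
          layout, composition, membership, j, spec$s1, spec$s2, spec$kappa1)
      )
    }
  }
  sizes <- as.integer(round(layout$synapse_budget * spec$density_factor))
  ii <- vector("list", n); nn <- vector("list", n)
  for (j in seq_len(n)) {
    p <- prob_for(j)
    counts <- rmultinom(1L, sizes[j], p)[, 1L]
    nz <- which(counts > 0L)
    ii[[j]] <- nz
    nn[[j]] <- counts[nz]
  }
  lens <- lengths(ii)
  counts <- Matrix::sparseMatrix(
    i = unlist(ii), j = rep.int(seq_len(n), lens), x = unlist(nn),
    dims = c(n, n))
  g <- ifelse(layout$inhibitory, -g_exc * g_inh_multiple, g_exc) /
    spec$density_factor
  weights <- counts %*% Matrix::Diagonal(n, g * alpha)
  structure(
    list(counts = counts,
         weights = methods::as(weights, "CsparseMatrix"),
         g = g, alpha = rep(alpha, n), density_factor = spec$density_factor,
         membership = membership, spec = spec),
    class = "synapse_matrix"
  )
}

#' @export
print.synapse_matrix <- function(x, ...) {
  cat(sprintf("<synapse_matrix> %d neurons, %d synapses over %d connections (rule %s)\n",
              nrow(x$counts), sum(x$counts@x), length(x$counts@x),
              x$spec$rule))
  invisible(x)
}

#' @rdname draw_synapses
#' @param x A `synapse_matrix`.
#' @param ... Unused.
#' @export
tidy.synapse_matrix <- function(x, ...) {
  tm <- methods::as(x$counts, "TsparseMatrix")
  tibble(target = tm@i + 1L, source = tm@j + 1L, n_synapses = tm@x,
         weight = x$weights[cbind(tm@i + 1L, tm@j + 1L)])
}

#' Write/read a synapse matrix in Matrix Market format
#'
#' Persists the integer synapse-count matrix as `<path>.mtx` and the
#' assembly metadata (per-neuron `g`, `alpha`, density factor, membership)
#' as a JSON sidecar.
#'
#' @param synapses A [draw_synapses()] result.
#' @param path File stem (no extension).
#' @export
write_synapses <- function(synapses, path) {
  Matrix::writeMM(synapses$counts, paste0(path, ".mtx"))
  side <- list(g = synapses$g, alpha = synapses$alpha,
               density_factor = synapses$density_factor,
               membership = synapses$membership,
               spec = unclass(synapses$spec))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       null = "null")
  invisible(path)
}

#' Build a full large-scale V1 network model
#'
#' Convenience pipeline: generates subnetwork fields and membership where
#' the rule needs them, draws the synapse matrix, and assembles a
#' [network_model()] ready for simulation.
#'
#' @inheritParams draw_synapses
#' @param tau Neuron time constant, ms.
#' @return A list with `model` ([network_model()]), `synapses`
#'   (`synapse_matrix`), `layout`, `membership` and `composition`.
#' @export
build_v1_network <- function(layout, spec, seed = NULL, tau = 10,
                             alpha = 0.066, g_exc = 0.01,
                             g_inh_multiple = 10) {
  composition <- NULL
  membership <- NULL
  if (spec$rule == "feature_binding") {
    field_seed <- if (is.null(seed)) NULL else seed + 1L
    composition <- generate_subnetwork_fields(
      layout, spec$n_subnetworks, spec$n_orientations, seed = field_seed)
    membership <- assign_membership(layout, composition, spec$kappa2)
  }
  synapses <- draw_synapses(layout, spec, composition = composition,
                            membership = membership, seed = seed,
                            g_exc = g_exc, g_inh_multiple = g_inh_multiple,
                            alpha = alpha)
  model <- network_model(synapses$weights, tau = tau, alpha = alpha,
                         beta = 0, is_inhibitory = layout$inhibitory)
  list(model = model, synapses = synapses, layout = layout,
       membership = membership, composition = composition, spec = spec)
}
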