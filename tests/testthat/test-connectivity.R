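test_that("Peters probabilities are a distribution that decays with distance", {
  lay <- tiny_layout(80, side = 3000)  # large torus: wrapping negligible
  p <- peters_probability(lay, 1)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  expect_equal(p[1], 0)  # no self-connection
  # the nearest neuron takes the highest probability, and probability
  # decays monotonically with minimal-image distance
  d <- torus_distance(cbind(lay$x, lay$y),
                      cbind(lay$x[1], lay$y[1])[rep(1, nrow(lay)), ],
                      attr(lay, "geometry"))
  expect_equal(which.max(p), order(d)[2])  # order(d)[1] is the source itself
  # probability decays with minimal-image distance (wrap corrections can
  # reorder near-ties, so rank agreement rather than strict monotonicity)
  expect_lt(cor(p[-1], d[-1], method = "spearman"), -0.999)
  expect_error(peters_probability(lay[1, ], 1), "2 neurons")
})

test_that("closed-form field overlap matches torus quadrature", {
  # small torus where wrapping matters; quadrature of the product of
  # periodic Gaussian fields is the independent oracle
  side <- 400
  lay <- manual_layout(x = c(50, 180, 320, 10), y = c(60, 300, 150, 390),
                       ori = c(0, 1, 2, 0.5), side = side,
                       sigma_d = 75, sigma_a = 120)
  p <- peters_probability(lay, 1)
  # quadrature on a fine grid with wrapped fields
  field <- function(gx, gy, cx, cy, sigma) {
    out <- 0
    for (kx in -2:2) for (ky in -2:2) {
      out <- out + exp(-((gx - cx + kx * side)^2 + (gy - cy + ky * side)^2) /
                         (2 * sigma^2))
    }
    out
  }
  h <- 2
  gx <- seq(0, side - h, by = h) + h / 2
  grid <- expand.grid(x = gx, y = gx)
  overlap <- vapply(seq_len(nrow(lay)), function(i) {
    if (i == 1) return(0)
    ax <- field(grid$x, grid$y, lay$x[1], lay$y[1], lay$sigma_a[1])
    dd <- field(grid$x, grid$y, lay$x[i], lay$y[i], lay$sigma_d[i])
    sum(ax * dd) * h^2
  }, numeric(1))
  expect_equal(p, overlap / sum(overlap), tolerance = 1e-6)
})

test_that("like-to-like rule reduces to Peters at s1 = 0 and weights orientation", {
  lay <- tiny_layout(100)
  src <- which(!lay$inhibitory)[1]
  expect_equal(like_to_like_probability(lay, src, s1 = 0),
               peters_probability(lay, src))
  p <- like_to_like_probability(lay, src, s1 = 0.8, kappa1 = 0.5)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  expect_error(like_to_like_probability(lay, src, s1 = 2), "s1")
  # fully specific rule on equidistant targets: iso- over ortho-oriented
  # probability ratio is e^(2 kappa1)
  lay2 <- manual_layout(x = c(500, 400, 600), y = c(500, 500, 500),
                        ori = c(0, 0, pi / 2))
  p2 <- like_to_like_probability(lay2, 1, s1 = 1, kappa1 = 0.5)
  expect_equal(p2[2] / p2[3], exp(2 * 0.5), tolerance = 1e-12)
})

test_that("subnetwork fields are smooth on the torus and reproducible", {
  lay <- tiny_layout(400, seed = 21, side = 1200)
  comp <- generate_subnetwork_fields(lay, n_subnetworks = 3,
                                     n_orientations = 2, seed = 9)
  expect_equal(dim(comp$theta), c(400, 3, 2))
  expect_true(all(comp$theta >= -pi & comp$theta <= pi))
  comp2 <- generate_subnetwork_fields(lay, 3, 2, seed = 9)
  expect_identical(comp$theta, comp2$theta)
  # circular agreement of one component between nearby neurons exceeds
  # that between distant neurons
  geom <- attr(lay, "geometry")
  th <- comp$theta[, 1, 1]
  pos <- cbind(lay$x, lay$y)
  pairs <- t(utils::combn(seq_len(120), 2))
  d <- torus_distance(pos[pairs[, 1], ], pos[pairs[, 2], ], geom)
  agree <- cos(th[pairs[, 1]] - th[pairs[, 2]])
  expect_gt(mean(agree[d < 50]), mean(agree[d > 500]))
})

test_that("very wide smoothing makes the composition spatially constant", {
  lay <- tiny_layout(150, seed = 31, side = 400)
  comp <- generate_subnetwork_fields(lay, 1, 1, filter_sigma = 1e5, seed = 2)
  th <- comp$theta[, 1, 1]
  expect_lt(max(abs(wrap_angle_oracle(th - th[1]))), 1e-3)
})

test_that("membership goes to the best-matching subnetwork", {
  lay <- manual_layout(x = c(100, 200, 300), y = c(100, 100, 100),
                       ori = c(0, pi / 4, pi / 2))
  # hand-built composition: subnetwork 1 holds doubled-angle 0, the other
  # subnetwork is orthogonal everywhere
  comp <- structure(list(
    theta = array(rep(c(0, pi, 0, pi, 0, pi), each = 3), c(3, 2, 2) ),
    n_subnetworks = 2, n_orientations = 2, filter_sigma = 75),
    class = "subnetwork_composition")
  comp$theta[, 1, ] <- 0      # SN1 components at doubled angle 0
  comp$theta[, 2, ] <- pi     # SN2 components orthogonal
  m <- assign_membership(lay, comp, kappa2 = 4)
  expect_equal(m[1], 1L)  # ori 0 matches SN1 exactly
  expect_equal(m[3], 2L)  # ori pi/2 (doubled pi) matches SN2
  expect_true(all(m %in% 1:2))
  lay_i <- lay
  lay_i$inhibitory[2] <- TRUE
  lay_i$ori[2] <- NA
  expect_true(is.na(assign_membership(lay_i, comp)[2]))
})

test_that("feature-binding rule nests the like-to-like rule", {
  lay <- tiny_layout(120, seed = 41)
  comp <- generate_subnetwork_fields(lay, 4, 2, seed = 5)
  mem <- assign_membership(lay, comp, kappa2 = 4)
  src <- which(!lay$inhibitory)[3]
  expect_equal(
    feature_binding_probability(lay, comp, mem, src, s1 = 0.3, s2 = 0,
                                kappa1 = 0.5),
    like_to_like_probability(lay, src, s1 = 0.3, kappa1 = 0.5))
  p <- feature_binding_probability(lay, comp, mem, src, s1 = 0.1, s2 = 0.25)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  # s1 = 0, s2 = 1: excitatory support restricted to the same subnetwork
  p1 <- feature_binding_probability(lay, comp, mem, src, s1 = 0, s2 = 1)
  exc <- !lay$inhibitory
  off <- exc & (is.na(mem) | mem != mem[src])
  expect_equal(sum(p1[off]), 0)
  expect_gt(sum(p1[exc & !off]), 0)
})

test_that("synapse draws respect budgets, weight constancy and probabilities", {
  lay <- tiny_layout(100, seed = 51)
  spec <- connectivity_spec("random", density_factor = 0.1)
  syn <- draw_synapses(lay, spec, seed = 3)
  sizes <- round(lay$synapse_budget * 0.1)
  expect_equal(unname(Matrix::colSums(syn$counts)), sizes)
  w_out <- Matrix::colSums(syn$weights)
  w_exc <- w_out[!lay$inhibitory]
  w_inh <- w_out[lay$inhibitory]
  # total output weight preserved despite density scaling:
  # 814 synapses x (0.01/0.1) pA/Hz x 0.066 Hz/pA
  expect_equal(unname(w_exc[1]), 814 * (0.01 / 0.1) * 0.066)
  expect_lt(max(abs(w_exc - w_exc[1])), 1e-12)
  expect_lt(max(abs(w_inh - w_inh[1])), 1e-12)
  expect_true(all(w_inh < 0))
  # inhibitory synapses 10x stronger per synapse
  expect_equal(abs(w_inh[1]) / 857, 10 * (w_exc[1] / 814), tolerance = 1e-9)
  expect_error(connectivity_spec("random", density_factor = 0),
               "density_factor")
})

test_that("multinomial sampling matches the probability vector", {
  lay <- tiny_layout(40, seed = 61)
  p <- peters_probability(lay, 2)
  set.seed(12)
  counts <- rowSums(rmultinom(100, 1000, p))
  # chi-square goodness of fit against the generating probabilities
  keep <- p > 0
  chi <- suppressWarnings(chisq.test(counts[keep], p = p[keep] / sum(p[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("like-to-like synapse fraction to similar orientations grows with s1", {
  lay <- tiny_layout(400, seed = 71, side = 1000)
  frac_similar <- vapply(c(0, 0.4, 0.8), function(s1) {
    spec <- connectivity_spec("like_to_like", s1 = s1)
    syn <- draw_synapses(lay, spec, seed = 8)
    tm <- tidy(syn)
    tm <- tm[!lay$inhibitory[tm$source] & !lay$inhibitory[tm$target], ]
    dori <- abs(plaidnet_ori_diff(lay$ori[tm$source], lay$ori[tm$target]))
    sum(tm$n_synapses[dori < 30 * pi / 180]) / sum(tm$n_synapses)
  }, numeric(1))
  expect_true(all(diff(frac_similar) > 0))
})

test_that("feature-binding same-subnetwork share exceeds baseline by the s2 share", {
  lay <- tiny_layout(500, seed = 81, side = 1000)
  comp <- generate_subnetwork_fields(lay, 6, 2, seed = 4)
  mem <- assign_membership(lay, comp, 4)
  frac_same <- function(rule_spec) {
    syn <- draw_synapses(lay, rule_spec, composition = comp,
                         membership = mem, seed = 19)
    tm <- tidy(syn)
    tm <- tm[!lay$inhibitory[tm$source] & !lay$inhibitory[tm$target], ]
    same <- mem[tm$source] == mem[tm$target]
    sum(tm$n_synapses[same]) / sum(tm$n_synapses)
  }
  f_random <- frac_same(connectivity_spec("random"))
  f_fb <- frac_same(connectivity_spec("feature_binding"))  # s2 = 0.25
  expect_gt(f_fb, f_random + 0.25 * (1 - f_random) - 0.03)
})

test_that("connectivity specs round-trip through YAML", {
  spec <- connectivity_spec("feature_binding_methods")
  expect_equal(spec$s1, 0.45)
  expect_equal(spec$s2, 0.225)
  path <- file.path(withr::local_tempdir(), "spec.yaml")
  write_config_yaml(spec, path)
  spec2 <- read_config_yaml(path)
  expect_equal(unclass(spec2), unclass(spec))
  cfg <- five_node_config(s = 0.2)
  path2 <- file.path(withr::local_tempdir(), "cfg.yaml")
  write_config_yaml(cfg, path2)
  expect_equal(unclass(read_config_yaml(path2)), unclass(cfg))
})
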