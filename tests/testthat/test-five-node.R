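nominal_w_E <- 8142 * 0.01 * 0.066
nominal_w_I <- 8566 * 0.1 * 0.066

test_that("five-node weight matrix implements the block structure", {
  # direct evaluation of the defining quantities
  W <- build_five_node_weights(five_node_config(s = 0.5, w_E = 5, w_I = 5,
                                                f_I = 0.2))
  expect_equal(W[1, 1], 1.5)  # a = w_S/2 + w_N/4 with w_S = w_N = 2
  expect_equal(W[1, 2], 1.5)
  expect_equal(W[1, 3], 0.5)  # b = w_N/4
  expect_equal(W[3, 2], 0.5)
  expect_equal(W[1, 5], -1)   # -w_ie = -w_I (1-f_I)/4
  expect_equal(W[5, 1], 1)    # w_ei = w_E f_I
  expect_equal(W[5, 5], -1)   # -w_I f_I
  # s = 0: fully uniform excitatory block
  W0 <- build_five_node_weights(five_node_config(s = 0, w_E = 5, f_I = 0.2))
  expect_equal(unique(as.vector(W0[1:4, 1:4])), 5 * 0.8 / 4)
  # s = 1: no cross-subnetwork weight
  W1 <- build_five_node_weights(five_node_config(s = 1, w_E = 5, f_I = 0.2))
  expect_equal(W1[1, 3], 0)
  expect_equal(W1[1, 1], 5 * 0.8 / 2)
  expect_error(five_node_config(s = 1.5), "s")
})

test_that("eigenvalue classification separates the regimes", {
  # W = 0: pure leak, intrinsically stable
  r0 <- classify_stability(matrix(0, 5, 5))
  expect_true(r0$stable)
  expect_equal(r0$regime, "AS")
  expect_true(all(abs(r0$eigenvalues + 0.1) < 1e-12))
  # single self-excited neuron beyond unity gain: exponential runaway
  r1 <- classify_stability(matrix(1.5, 1, 1), inhibitory = FALSE)
  expect_false(r1$stable)
  expect_equal(r1$regime, "Exp")
  # rotational coupling: unstable complex pair classifies as IO
  Wrot <- matrix(c(1.2, -5, 5, 1.2), 2, 2)
  r2 <- classify_stability(Wrot, inhibitory = c(FALSE, FALSE))
  expect_equal(r2$regime, "IO")
  expect_error(classify_stability(matrix(0, 2, 3)), "square")
})

test_that("nominal cortical weights give an inhibition-stabilised network", {
  W <- build_five_node_weights(five_node_config(s = 0))
  rep <- classify_stability(W)
  expect_true(rep$stable)
  expect_equal(rep$regime, "ISN")
  # the excitatory-only subsystem must be unstable
  expect_gt(max(Re(rep$eigenvalues_exc)), 0)
})

test_that("stability classification agrees with simulation (oracle equivalence)", {
  for (s in c(0, 0.1, 0.2, 0.5, 1)) {
    cfg <- five_node_config(s = s)
    W <- build_five_node_weights(cfg)
    rep <- classify_stability(W)
    m <- network_model(W, tau = 10)
    # perturb around a weakly driven state and watch for growth
    trj <- simulate_network(m, rep(0.1, 5), duration = 800, dt = 1,
                            x0 = rep(0.1, 5) + c(0.05, 0, 0, 0, 0.01))
    blew_up <- trj$diverged || max(abs(trj$activations)) > 100
    expect_equal(blew_up, rep$regime %in% c("Exp", "IO"),
                 info = sprintf("s = %g", s))
  }
})

test_that("competition current: none without excitation, onset with specificity", {
  expect_equal(competition_current(five_node_config(s = 0, w_E = 0, w_I = 0)), 0)
  comp0 <- competition_current(five_node_config(s = 0))
  comp02 <- competition_current(five_node_config(s = 0.2))
  expect_gte(comp0, 0)    # random connectivity: no competition
  expect_lt(comp02, 0)    # 20% specific synapses: competition
  expect_gte(comp0, comp02)
  # onset within (0, 0.25]
  s_grid <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  comps <- vapply(s_grid, function(s) {
    tryCatch(competition_current(five_node_config(s = s)),
             error = function(e) NA_real_)
  }, numeric(1))
  expect_true(any(comps < 0, na.rm = TRUE))
})

test_that("competition strengthens with specificity at stable weights", {
  # monotone non-increasing net current over a 5-point sweep, verified
  # against an independent long-simulation oracle at each point
  s_grid <- c(0, 0.05, 0.1, 0.15, 0.2)
  comps <- vapply(s_grid, function(s) {
    competition_current(five_node_config(s = s))
  }, numeric(1))
  expect_true(all(diff(comps) < 0))
  cfg <- five_node_config(s = 0.15)
  W <- build_five_node_weights(cfg)
  m <- network_model(W, tau = 10)
  trj <- simulate_network(m, c(cfg$iota, 0, 0, 0, 0), duration = 1500, dt = 1)
  x_end <- trj$activations[nrow(trj$activations), ]
  oracle <- sum(W[3, ] * pmax(0, x_end))
  expect_equal(comps[s_grid == 0.15], oracle, tolerance = 1e-4)
})

test_that("phase diagram reproduces the qualitative regime layout", {
  pd <- phase_diagram(
    x_values = nominal_w_I * c(0.5, 1, 150),
    y_values = nominal_w_E * c(0.05, 1, 5),
    x_param = "w_I", y_param = "w_E",
    config = five_node_config(s = 0), competition = FALSE)
  expect_equal(nrow(pd), 9)
  expect_true(all(!is.na(pd$regime)))
  get <- function(wi, we) pd$regime[abs(pd$w_I - nominal_w_I * wi) < 1e-9 &
                                      abs(pd$w_E - nominal_w_E * we) < 1e-9]
  expect_equal(get(1, 0.05), "AS")    # weak excitation: intrinsically stable
  expect_equal(get(1, 1), "ISN")      # nominal: needs inhibitory feedback
  expect_equal(get(1, 5), "Exp")      # strong excitation: runaway
  expect_equal(get(150, 1), "IO")     # extreme inhibition: oscillation
})

test_that("zero-excitation row is intrinsically stable everywhere", {
  pd <- phase_diagram(x_values = nominal_w_I * c(0.1, 1, 10),
                      y_values = 0, x_param = "w_I", y_param = "w_E",
                      config = five_node_config(s = 0), competition = FALSE,
                      check_oscillation = FALSE)
  expect_true(all(pd$regime == "AS"))
})

test_that("nominal weights destabilise at 40% specificity", {
  rep <- classify_stability(build_five_node_weights(five_node_config(s = 0.4)))
  expect_false(rep$stable)
})

test_that("specificity sweep of the phase diagram finds the competition onset", {
  pd <- phase_diagram(x_values = c(0, 0.1, 0.2), y_values = nominal_w_E,
                      x_param = "s", y_param = "w_E",
                      config = five_node_config(), competition = TRUE,
                      check_oscillation = FALSE)
  expect_gte(pd$competition[pd$s == 0], 0)
  expect_lt(pd$competition[pd$s == 0.2], 0)
})

test_that("mixture experiment shows amplification and switching at s = 0.25", {
  mx <- mixture_experiment(five_node_config(s = 0.25),
                           mixture_levels = seq(0, 100, by = 10))
  ref <- attr(mx, "reference")
  expect_true(is.finite(ref))
  # pure stimulus amplified above the single-component reference
  expect_gt(mx$rate_sn1[mx$mixture == 0], ref)
  # symmetry: m = 100 mirrors m = 0 with subnetworks swapped
  expect_equal(mx$rate_sn2[mx$mixture == 100], mx$rate_sn1[mx$mixture == 0],
               tolerance = 1e-6)
  expect_equal(mx$winner[mx$mixture == 0], "SN1")
  expect_equal(mx$winner[mx$mixture == 100], "SN2")
  # the winner switches across the 50% mixture: sign change of the margin
  margin <- mx$rate_sn1 - mx$rate_sn2
  expect_gt(margin[mx$mixture == 10], 0)
  expect_lt(margin[mx$mixture == 90], 0)
  expect_equal(mx$winner[mx$mixture == 50], "tie")
  expect_true(all(mx$rate_sn1 >= 0 & mx$rate_sn2 >= 0))
})

test_that("without specificity the mixture margin varies smoothly", {
  mx <- mixture_experiment(five_node_config(s = 0),
                           mixture_levels = seq(0, 100, by = 5))
  expect_true(all(mx$converged))
  margin <- mx$rate_sn1 - mx$rate_sn2
  # margin strictly decreasing, zero only at m = 50
  expect_true(all(diff(margin) < 0))
  expect_equal(margin[mx$mixture == 50], 0, tolerance = 1e-9)
  expect_true(all(abs(margin[mx$mixture != 50]) > 1e-6))
  # rates continuous in m: no jumps larger than the level spacing implies
  expect_lt(max(abs(diff(mx$rate_sn1))), 0.05)
  # cross-check each level against the simulation oracle
  cfg <- five_node_config(s = 0)
  m40 <- mx[mx$mixture == 40, ]
  W <- build_five_node_weights(cfg)
  trj <- simulate_network(network_model(W, tau = cfg$tau),
                          c(0.6, 0.6, 0.4, 0.4, 0) * cfg$iota,
                          duration = 1000, dt = 1)
  expect_equal(m40$rate_sn1, mean(steady_rates(trj)[1:2]), tolerance = 1e-3)
})

test_that("stability report methods expose eigenvalues tidily", {
  rep <- classify_stability(build_five_node_weights(five_node_config(s = 0)))
  g <- glance(rep)
  expect_equal(g$regime, "ISN")
  td <- tidy(rep)
  expect_equal(nrow(td), 10)  # 5 full + 5 excitatory-only
  expect_setequal(unique(td$system), c("full", "excitatory_only"))
})
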