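test_that("selectivity indices match direct formula evaluation", {
  expect_equal(osi(c(1, 0, 0, 0)), 1)
  expect_equal(osi(rep(2, 6)), 0)
  expect_equal(osi(c(2, 1, 1, 1)), 0.2)
  expect_true(is.na(osi(c(0, 0, 0))))
  expect_error(osi(1), "2 grating")
  expect_error(osi(c(-1, 2)), "non-negative")

  expect_equal(psi(c(5, 0, 0)), 1)
  expect_equal(psi(rep(3, 10)), 0)
  expect_equal(psi(c(2, 1, 1)), 0.5)  # 1 - (-1 + 4/2)/2
  expect_true(is.na(psi(c(0, 0))))

  expect_equal(modulation_index(c(1, 0), c(1, 0.5)), 0)
  expect_equal(modulation_index(c(2, 1), c(0, 0)), -1)
  expect_equal(modulation_index(1, 3), 0.5)
  expect_true(is.na(modulation_index(0, 0)))
})

make_mean_table <- function(G, P) {
  # G, P: neurons x stimuli matrices of trial means
  st <- dplyr::bind_rows(
    tibble::tibble(stimulus_id = paste0("g", seq_len(ncol(G))),
                   kind = "grating", ori1 = seq_len(ncol(G)), ori2 = NA),
    tibble::tibble(stimulus_id = paste0("p", seq_len(ncol(P))),
                   kind = "plaid", ori1 = 0, ori2 = 1))
  resp <- dplyr::bind_rows(
    tibble::tibble(neuron = rep(seq_len(nrow(G)), ncol(G)),
                   stimulus_id = rep(paste0("g", seq_len(ncol(G))), each = nrow(G)),
                   trial = 1L, response = as.vector(G)),
    tibble::tibble(neuron = rep(seq_len(nrow(P)), ncol(P)),
                   stimulus_id = rep(paste0("p", seq_len(ncol(P))), each = nrow(P)),
                   trial = 1L, response = as.vector(P)))
  response_table(resp, st)
}

test_that("pairwise correlations follow closed-form Pearson values", {
  G <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 0, 0, 0))
  P <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  tbl <- make_mean_table(G, P)
  pairs <- pairwise_correlations(tbl)
  expect_equal(nrow(pairs), 3)
  pick <- function(a, b) pairs[pairs$neuron_a == a & pairs$neuron_b == b, ]
  # orthogonal one-hot grating vectors of length 4: rho_g = -1/3
  expect_equal(pick(1, 2)$rho_g, -1 / 3)
  expect_equal(pick(1, 3)$rho_g, 1)    # identical tuning
  expect_equal(pick(1, 2)$rho_p, 1)
  expect_equal(pick(1, 3)$rho_p, -1)   # reversed plaid tuning
  # symmetry in pair order is structural: pairs are unordered and unique
  expect_true(all(pairs$neuron_a < pairs$neuron_b))
})

test_that("zero-variance neurons are excluded with a reason", {
  G <- rbind(c(1, 0, 0, 0), c(2, 2, 2, 2), c(0, 1, 0, 0))
  P <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  pairs <- pairwise_correlations(make_mean_table(G, P))
  excluded <- attr(pairs, "excluded")
  expect_equal(excluded$neuron, 2)
  expect_match(excluded$reason, "zero-variance grating")
  expect_equal(nrow(pairs), 1)
})

test_that("grating-plaid R2 is 1 for identical correlation structure and
           near 0 for independent pairs", {
  set.seed(5)
  # neurons with matched grating/plaid tuning: rho_p tracks rho_g exactly
  n <- 20
  base <- matrix(runif(n * 4), n, 4)
  tbl <- make_mean_table(base, base)  # plaid tuning identical to grating
  pairs <- pairwise_correlations(tbl)
  pairs$osi_a <- pairs$osi_b <- 1  # bypass the filter for the algebra check
  expect_equal(grating_plaid_r2(pairs), 1, tolerance = 1e-9)
  # independent permutation oracle: R2 collapses
  big <- tibble::tibble(
    neuron_a = 1, neuron_b = 2,
    rho_g = runif(10000, -1, 1), rho_p = runif(10000, -1, 1),
    osi_a = 1, osi_b = 1)
  class(big) <- c("pair_correlations", class(big))
  expect_lt(grating_plaid_r2(big), 0.01)
  expect_error(grating_plaid_r2(big[1:2, ]), ">= 3")
})

test_that("R2 is invariant to per-neuron affine rescaling of responses", {
  set.seed(8)
  G <- matrix(runif(40), 10, 4)
  P <- matrix(runif(30), 10, 3)
  r2_a <- grating_plaid_r2(pairwise_correlations(make_mean_table(G, P)),
                           osi_threshold = -1)
  scale <- runif(10, 0.5, 3)
  shift <- runif(10, 0, 0.2)
  r2_b <- grating_plaid_r2(
    pairwise_correlations(make_mean_table(G * scale + shift, P * scale + shift)),
    osi_threshold = -1)
  expect_equal(r2_a, r2_b, tolerance = 1e-9)
})

test_that("modulation classes count correctly and Fisher test matches
           exact enumeration", {
  mi <- c(0.2, 0.06, 0.049, -0.02, -0.051, -0.3, NA)
  summ <- classify_modulation(mi)
  expect_equal(summ$count[summ$class == "facilitating"], 2)
  expect_equal(summ$count[summ$class == "suppressing"], 2)
  expect_equal(summ$count[summ$class == "non_modulated"], 2)
  expect_equal(sum(summ$count), 6)

  # identical populations: p = 1
  expect_equal(fisher_compare(summ, summ)$p_value, 1)

  # 2x2 reduction against a hand-rolled hypergeometric enumeration
  a <- classify_modulation(c(rep(0.2, 8), rep(-0.2, 2)))
  b <- classify_modulation(c(rep(0.2, 1), rep(-0.2, 9)))
  p_pkg <- fisher_compare(a, b)$p_value
  # enumeration oracle over all tables with the same margins
  margins <- list(r = c(10, 10), c = c(9, 11))
  probs <- vapply(0:9, function(k) {
    dhyper(k, margins$c[1], margins$c[2], margins$r[1])
  }, numeric(1))
  p_oracle <- sum(probs[probs <= probs[8 + 1] + 1e-12])
  expect_equal(p_pkg, p_oracle, tolerance = 1e-9)
  expect_equal(p_pkg, 0.005477, tolerance = 1e-3)
})

test_that("responsivity filter excludes null neurons and keeps strong ones", {
  set.seed(21)
  st <- build_stimulus_protocol("oscillating5_plaids")
  n <- 150
  neuropil <- rnorm(5000, 0, 1)
  # neurons drawn from the neuropil distribution itself
  null_resp <- tidyr::crossing(neuron = seq_len(n),
                               stimulus_id = st$stimulus_id,
                               trial = 1:10) |>
    dplyr::mutate(response = rnorm(dplyr::n(), 0, 1))
  tbl <- response_table(null_resp, st)
  filt <- responsivity_filter(tbl, neuropil, alpha = 0.01)
  expect_lte(mean(filt$included), 0.05)
  # a neuron far above the neuropil is always included
  strong <- null_resp
  strong$response[strong$neuron == 1] <- 10 +
    strong$response[strong$neuron == 1]
  filt2 <- responsivity_filter(response_table(strong, st), neuropil)
  expect_true(filt2$included[filt2$neuron == 1])
  # degenerate alpha = 1: thresholds at the distribution minimum
  filt3 <- responsivity_filter(response_table(strong, st), neuropil,
                               alpha = 1)
  expect_true(filt3$included[filt3$neuron == 1])
  expect_error(responsivity_filter(tbl, numeric(0)), "empty")
})

test_that("RF centre estimation matches symmetry and a dense-grid oracle", {
  # single nonzero response: centre at that location
  grid <- tidyr::crossing(x = (0:4) * 9, y = (0:4) * 9) |>
    dplyr::mutate(response = 0)
  grid$response[grid$x == 18 & grid$y == 27] <- 2
  ctr <- estimate_rf_centre(grid)
  expect_equal(ctr$x, 18, tolerance = 0.11)
  expect_equal(ctr$y, 27, tolerance = 0.11)
  # four equal responses at the corners of a small square (side below the
  # field dispersion): centre at the midpoint by symmetry
  sq <- tibble::tibble(x = c(0, 6, 0, 6), y = c(0, 0, 6, 6), response = 1)
  ctr2 <- estimate_rf_centre(sq)
  expect_equal(ctr2$x, 3, tolerance = 0.11)
  expect_equal(ctr2$y, 3, tolerance = 0.11)
  # random weights against a brute-force argmax oracle on a 0.1 v.d. grid
  set.seed(31)
  rnd <- tidyr::crossing(x = (0:4) * 9, y = (0:4) * 9) |>
    dplyr::mutate(response = runif(25))
  ctr3 <- estimate_rf_centre(rnd, resolution = 0.1)
  xs <- seq(-15, 51, by = 0.1)
  mix <- function(px, py) {
    sum(rnd$response * exp(-((px - rnd$x)^2 + (py - rnd$y)^2) / (2 * 7.5^2)))
  }
  vals <- outer(xs, xs, Vectorize(mix))
  peak <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  expect_equal(ctr3$x, xs[peak[1]], tolerance = 0.11)
  expect_equal(ctr3$y, xs[peak[2]], tolerance = 0.11)
  expect_error(estimate_rf_centre(dplyr::mutate(rnd, response = 0)),
               "positive")
})

test_that("movie signal correlation masks onset windows", {
  times <- seq(0, 20, by = 0.1)
  a <- sin(times)
  b <- sin(times) + 0.1 * cos(3 * times)
  expect_equal(movie_signal_correlation(a, a, times, c(0, 10)), 1)
  expect_equal(movie_signal_correlation(a, -a, times, c(0, 10)), -1)
  onsets <- c(0, 7, 14)
  r <- movie_signal_correlation(a, b, times, onsets, exclusion = 1)
  keep <- !((times >= 0 & times < 1) | (times >= 7 & times < 8) |
              (times >= 14 & times < 15))
  expect_equal(r, cor(a[keep], b[keep]))
  expect_false(identical(r, cor(a, b)))
  expect_error(movie_signal_correlation(a, b[-1], times, 0), "equal length")
})
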