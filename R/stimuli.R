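#' Grating input currents
#'
#' Injected current for a full-field grating of orientation `theta_g`:
#' proportional to each excitatory neuron's von Mises input tuning curve
#' evaluated at the grating orientation (doubled-angle convention), zero
#' for inhibitory neurons, and renormalised so the total current injected
#' into the network equals the stimulus amplitude `A`.
#'
#' @param layout A [place_population()] layout.
#' @param theta_g Grating orientation, radians (true orientation).
#' @param amplitude Total injected current `A`, pA.
#' @param kappa Tuning width parameter; defaults to the layout's
#'   `kappa_input` column.
#' @return Numeric per-neuron current vector (pA), summing to `amplitude`.
#' @export
grating_input <- function(layout, theta_g, amplitude, kappa = NULL) {
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  kappa <- kappa %||% layout$kappa_input
  v <- ifelse(is.na(layout$ori), 0,
              von_mises_ori(theta_g, layout$ori, kappa))
  if (amplitude == 0 || sum(v) == 0) return(rep(0, nrow(layout)))
  amplitude * v / sum(v)
}

#' Plaid input currents
#'
#' Input for a plaid composed of two grating components: the linear average
#' of the two component tuning-curve inputs, renormalised so the total
#' injected current equals `amplitude`. Symmetric in the two components;
#' identical components reduce to [grating_input()].
#'
#' @inheritParams grating_input
#' @param theta_g1,theta_g2 Component orientations, radians.
#' @return Numeric per-neuron current vector (pA), summing to `amplitude`.
#' @export
plaid_input <- function(layout, theta_g1, theta_g2, amplitude, kappa = NULL) {
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  kappa <- kappa %||% layout$kappa_input
  v <- ifelse(is.na(layout$ori), 0,
              (von_mises_ori(theta_g1, layout$ori, kappa) +
                 von_mises_ori(theta_g2, layout$ori, kappa)) / 2)
  if (amplitude == 0 || sum(v) == 0) return(rep(0, nrow(layout)))
  amplitude * v / sum(v)
}

#' Grating/plaid stimulus protocols
#'
#' Builds the stimulus batteries used throughout the package:
#'
#' * `"oscillating5_plaids"`: five grating orientations spanning +/-40
#'   degrees around a base orientation, plus all 10 pairwise plaids
#'   (15 stimuli; mirrors the contrast-oscillating protocol).
#' * `"drifting16_plaids"`: 16 drift directions plus three full plaid sets
#'   at 45, 90 and 135 degree relative component orientations (64 stimuli).
#' * `"custom"`: gratings at `orientations` plus all pairwise plaids when
#'   `plaids = TRUE`.
#'
#' @param name Protocol name.
#' @param base_orientation Base orientation for `oscillating5_plaids`,
#'   radians (default `pi/2`).
#' @param orientations Orientations (radians) for `"custom"`.
#' @param plaids For `"custom"`: also include all pairwise plaids?
#' @param amplitude Stimulus amplitude `A` passed on to input generation,
#'   pA (recorded per stimulus; `NA` means "decide at simulation time").
#' @param duration Stimulus duration, ms.
#' @return A `stimulus_set` tibble: `stimulus_id`, `kind` (`"grating"` or
#'   `"plaid"`), `ori1`, `ori2` (radians; `NA` for gratings), `amplitude`,
#'   `duration`, with the protocol name attached as attribute.
#' @export
build_stimulus_protocol <- function(name = c("oscillating5_plaids",
                                             "drifting16_plaids", "custom"),
                                    base_orientation = pi / 2,
                                    orientations = NULL, plaids = TRUE,
                                    amplitude = NA_real_, duration = 500) {
  name <- match.arg(name)
  deg <- pi / 180
  if (name == "oscillating5_plaids") {
    oris <- base_orientation + c(-40, -20, 0, 20, 40) * deg
    grat <- tibble(kind = "grating", ori1 = oris, ori2 = NA_real_)
    pairs <- utils::combn(oris, 2)
    pl <- tibble(kind = "plaid", ori1 = pairs[1, ], ori2 = pairs[2, ])
  } else if (name == "drifting16_plaids") {
    dirs <- seq(0, 2 * pi, length.out = 17)[-17]
    grat <- tibble(kind = "grating", ori1 = dirs, ori2 = NA_real_)
    pl <- list_rbind(map(c(45, 90, 135) * deg, function(delta) {
      tibble(kind = "plaid", ori1 = dirs, ori2 = dirs + delta)
    }))
  } else {
    if (is.null(orientations) || length(orientations) == 0) {
      abort("`orientations` must be supplied for the custom protocol.")
    }
    grat <- tibble(kind = "grating", ori1 = orientations, ori2 = NA_real_)
    pl <- if (plaids && length(orientations) >= 2) {
      pairs <- utils::combn(orientations, 2)
      tibble(kind = "plaid", ori1 = pairs[1, ], ori2 = pairs[2, ])
    } else {
      tibble(kind = character(), ori1 = numeric(), ori2 = numeric())
    }
  }
  out <- bind_rows(grat, pl) |>
    mutate(stimulus_id = paste0(substr(.data$kind, 1, 1), dplyr::row_number()),
           amplitude = amplitude, duration = duration) |>
    select("stimulus_id", "kind", "ori1", "ori2", "amplitude", "duration")
  class(out) <- c("stimulus_set", class(out))
  attr(out, "protocol") <- name
  out
}

#' Input currents for one stimulus row
#'
#' @param layout A [place_population()] layout.
#' @param stimulus One row of a [build_stimulus_protocol()] tibble.
#' @param amplitude Total injected current, pA; defaults to the stimulus
#'   row's amplitude.
#' @return Per-neuron current vector, pA.
#' @export
stimulus_input <- function(layout, stimulus, amplitude = NULL) {
  amplitude <- amplitude %||% stimulus$amplitude
  if (is.na(amplitude)) abort("Stimulus amplitude is unset.")
  if (stimulus$kind == "plaid") {
    plaid_input(layout, stimulus$ori1, stimulus$ori2, amplitude)
  } else if (stimulus$kind == "grating") {
    grating_input(layout, stimulus$ori1, amplitude)
  } else {
    rep(0, nrow(layout))
  }
}
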