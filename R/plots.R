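# Additional plotting methods.

#' Heat map of trial-averaged responses
#'
#' Neurons (ordered by preferred stimulus) against stimuli, coloured by
#' response normalised to each neuron's maximum.
#'
#' @param object A `response_means` tibble ([simulate_protocol()] output)
#'   or [trial_means()] result.
#' @param max_neurons Subsample cap for plotting (default 500).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.response_means <- function(object, max_neurons = 500, ...) {
  df <- as_tibble(object) |>
    group_by(.data$neuron) |>
    mutate(norm = .data$response / max(.data$response, 1e-12),
           pref = .data$stimulus_id[which.max(.data$response)]) |>
    ungroup()
  ids <- unique(df$neuron)
  if (length(ids) > max_neurons) {
    keep <- ids[seq(1L, length(ids), length.out = max_neurons)]
    df <- filter(df, .data$neuron %in% keep)
  }
  df <- mutate(df, neuron_rank = as.integer(factor(
    .data$neuron, levels = unique(.data$neuron[order(.data$pref)]))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stimulus_id,
                                   y = .data$neuron_rank,
                                   fill = .data$norm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "r / r_max") +
    ggplot2::labs(x = "stimulus", y = "neuron (by preferred stimulus)") +
    ggplot2::theme_minimal()
}
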