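#' Plot fractional occupancy by group
#'
#' Boxplots of per-subject fractional occupancy for each state, split by
#' diagnostic group.
#'
#' @param data metrics table joined with cohort metadata (`FO_*` columns plus
#'   a grouping column).
#' @param group name of the grouping column.
#' @return a ggplot object.
#' @export
plot_fractional_occupancy <- function(data, group = "group") {
  long <- data |>
    dplyr::select(dplyr::all_of(group), dplyr::starts_with("FO_")) |>
    tidyr::pivot_longer(dplyr::starts_with("FO_"), names_to = "state",
                        values_to = "occupancy") |>
    dplyr::mutate(state = sub("FO_", "state ", .data$state))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$occupancy,
                                     fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "Fractional occupancy") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.statedyn_hmm <- function(object, ...) {
  df <- as.data.frame(as.table(object$trans))
  names(df) <- c("from", "to", "probability")
  df$from <- factor(as.integer(df$from), levels = rev(seq_len(object$K)))
  df$to <- as.integer(df$to)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$probability)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "To state", y = "From state",
                  title = "Transition / persistence probabilities") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.permutation_result <- function(object, ...) {
  cells <- object$cells
  cells$from <- factor(cells$from_state,
                       levels = rev(sort(unique(cells$from_state))))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$to_state, y = .data$from,
                                      fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$fwe_p < 0.05, "*", "")), size = 6) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(x = "To state", y = "From state",
                  title = sprintf("Group contrast t (%s); * FWE p < .05",
                                  object$direction)) +
    ggplot2::theme_minimal()
}
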