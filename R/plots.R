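# ggplot2 views of cards, score distributions, profiles and GA traces.

#' Heat map of a scoring card
#'
#' Draws the 20 x 20 dipeptide propensity matrix ([card_heatmap_matrix()]):
#' rows are the first residue of each dipeptide, columns the second.
#'
#' @param object A scoring card.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scoring_card
#' @export
autoplot.scoring_card <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$second, y = .data$first, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1000), name = "propensity") +
    ggplot2::scale_y_discrete(limits = rev(AA_ALPHABET)) +
    ggplot2::labs(
      x = "second residue", y = "first residue",
      title = "Dipeptide propensity scores"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Best-fitness trace of a GA run
#'
#' @param object An `scm_ga` object from [ga_optimize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scm_ga
#' @export
autoplot.scm_ga <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best fitness", title = "GA refinement trace") +
    ggplot2::theme_minimal()
}

#' Score distributions of the two classes
#'
#' Overlaid histograms of sequence scores by class label, on the card's
#' \eqn{[0, 1000]} scale, with the decision threshold drawn when available.
#'
#' @param data A labeled, scored tibble (e.g. from [score_sequences()] or
#'   [classify()] on a labeled dataset).
#' @param card Optional scoring card supplying the threshold line.
#' @param bin_width Histogram bin width in score units.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(data, card = NULL, bin_width = 25) {
  check_labeled(data)
  if (!"score" %in% names(data)) {
    abort("`data` must have a `score` column (see `score_sequences()`)",
      class = "scmseq_type_error"
    )
  }
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_histogram(binwidth = bin_width, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = "sequence score", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(card) && !is.na(card$threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = card$threshold, linetype = "dashed")
  }
  p
}

#' Positional dipeptide-score profile plot
#'
#' @param profile A profile tibble from [positional_profile()].
#' @return A ggplot object; the smoothed track is drawn as a line over the
#'   raw per-position scores when present.
#' @export
plot_positional_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(alpha = if ("smoothed" %in% names(profile)) 0.35 else 1) +
    ggplot2::labs(x = "sequence position", y = "dipeptide score") +
    ggplot2::theme_minimal()
  if ("smoothed" %in% names(profile)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.8)
  }
  p
}
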