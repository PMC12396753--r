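#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a prediction track against an empirical track
#'
#' Overlays the ensemble-mean per-nucleotide probability (with a shaded
#' standard-error ribbon when available) on the empirical footprint
#' frequency.
#'
#' @param pred Prediction track (`position` plus `prob` or `mean`/`sem`).
#' @param emp Optional empirical track from [empirical_track()].
#' @return A ggplot object.
#' @export
plot_track_comparison <- function(pred, emp = NULL) {
  val <- if ("prob" %in% names(pred)) pred$prob else pred$mean
  df <- tibble(position = pred$position, value = val,
               sem = if ("sem" %in% names(pred)) pred$sem else 0)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$value - .data$sem, 0),
                                      ymax = pmin(.data$value + .data$sem, 1)),
                         fill = "#d95f8c", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "#d95f8c") +
    ggplot2::labs(x = "position (nt)", y = "P(in R-loop)") +
    ggplot2::theme_minimal()
  if (!is.null(emp)) {
    gg <- gg + ggplot2::geom_line(
      data = tibble(position = emp$position, value = emp$prob),
      ggplot2::aes(y = .data$value), linetype = "dotted", colour = "#3355bb")
  }
  gg
}

#' @export
autoplot.rloop_ensemble <- function(object, plasmid = NULL, ...) {
  nm <- plasmid %||% names(object$tracks)[[1]]
  plot_track_comparison(object$tracks[[nm]])
}

#' Plot the entropy-threshold profile of a ranked weight list
#'
#' Shows per-rank entropy `H` and its running average `h`, with the cutoff
#' rank (global maximum of `h`) marked.
#'
#' @param x Output of [entropy_threshold()].
#' @return A ggplot object.
#' @export
plot_entropy_threshold <- function(x) {
  cutoff <- attr(x, "cutoff_rank")
  long <- tidyr::pivot_longer(x[, c("rank", "H", "h")],
                              c("H", "h"), names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(.data$rank, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "rank", y = "entropy",
                  subtitle = paste("cutoff rank", cutoff)) +
    ggplot2::theme_minimal()
}

#' Boxplots of production-rule probabilities by topology
#'
#' @param ensembles Named list (topology -> ensemble), as in
#'   [rule_probability_report()].
#' @param rules Rules to display (default: the six main chain rules).
#' @return A ggplot object.
#' @export
plot_rule_probabilities <- function(ensembles,
                                    rules = c("S -> sigma S",
                                              "S -> sigma_hat S",
                                              "R -> tau R",
                                              "R -> tau_hat R",
                                              "Q -> sigma Q",
                                              "Q -> sigma_hat Q")) {
  probs <- purrr::imap_dfr(ensembles, function(ens, topo) {
    models <- if (inherits(ens, "rloop_ensemble")) ens$models else ens
    purrr::map_dfr(models, tidy) |> mutate(topology = topo)
  }) |>
    filter(.data$rule %in% rules)
  ggplot2::ggplot(probs, ggplot2::aes(.data$topology, .data$prob,
                                      fill = .data$topology)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~ .data$rule, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "rule probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
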