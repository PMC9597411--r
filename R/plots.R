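#' Plot per-pillar orthology confidence
#'
#' Shows the MAP joint-state posterior along the ancestral pillar order, with
#' contiguity-block starts marked; the analogue of reading the confidence
#' track above a pillar diagram.
#'
#' @param posterior An `orthology_posterior`.
#' @param pillars Optional [pillar_set()]; when given, block starts are drawn
#'   as dashed lines.
#' @return A ggplot object.
#' @export
plot_orthology_confidence <- function(posterior, pillars = NULL) {
  d <- posterior$map |>
    dplyr::mutate(position = dplyr::row_number())
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$prob)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "pillar (ancestral order)",
                  y = "MAP orthology-state posterior") +
    ggplot2::theme_minimal()
  if (!is.null(pillars)) {
    p <- p + ggplot2::geom_vline(xintercept = contiguity_breaks(pillars),
                                 linetype = "dashed", colour = "steelblue",
                                 alpha = 0.5)
  }
  p
}

#' @export
#' @rdname plot_orthology_confidence
#' @param object,... `autoplot` method arguments.
autoplot.orthology_posterior <- function(object, ...) {
  plot_orthology_confidence(object, ...)
}

#' Plot surviving-gene counts per subgenome
#'
#' Bar chart of the (expected) number of genes surviving from each subgenome
#' in each genome - the visual signature of biased fractionation (LF > IF >
#' MF when losses are biased).
#'
#' @param survival A tibble from [count_surviving()].
#' @return A ggplot object.
#' @export
plot_survival <- function(survival) {
  survival |>
    dplyr::mutate(subgenome = factor(.data$subgenome,
                                     levels = subgenomes())) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$subgenome, y = .data$count,
                                 fill = .data$subgenome)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~genome) +
    ggplot2::labs(x = "subgenome", y = "surviving genes") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot repeat density per subgenome
#'
#' @param density A tibble from [re_density()].
#' @param log_scale Use a log10 y axis (repeat densities span orders of
#'   magnitude between genome-specific and ancestral repeats).
#' @return A ggplot object.
#' @export
plot_re_density <- function(density, log_scale = FALSE) {
  p <- density |>
    dplyr::mutate(subgenome = factor(.data$subgenome,
                                     levels = subgenomes())) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$subgenome, y = .data$density,
                                 fill = .data$subgenome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "subgenome", y = "RE density (hits/kB)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  if ("genome" %in% names(density)) p <- p + ggplot2::facet_wrap(~genome)
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a fitted model's relative loss rates
#'
#' @param object A `wgt_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wgt_fit <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(.data$block %in% c("rate", "root_rate")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$term, y = .data$estimate,
                                 fill = .data$block)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "relative loss rate (alpha units)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
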