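# Plotting helpers. All return ggplot objects.

#' Plot normalized temporal fitness profiles
#'
#' One line per gene across passages, optionally colored by a label table
#' (archetype or cluster).
#'
#' @param norm Normalized profile tibble from [condition_normalize()].
#' @param labels Optional tibble with `locus` and one label column (e.g.
#'   the output of [label_archetypes()] or `tidy()` of a clustering).
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_profiles <- function(norm, labels = NULL, alpha = 0.4) {
  df <- norm
  colour <- NULL
  if (!is.null(labels)) {
    label_col <- setdiff(names(labels), "locus")[1]
    df <- df |> left_join(labels, by = "locus")
    colour <- label_col
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$passage, y = .data$g,
                                        group = .data$locus))
  if (is.null(colour)) {
    p <- p + ggplot2::geom_line(alpha = alpha)
  } else {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = factor(.data[[colour]])),
                                alpha = alpha) +
      ggplot2::labs(colour = colour)
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "passage",
      y = expression(log[2] ~ "fitness (cheesecloth - control)")
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.barseq_run <- function(object, ...) {
  sel_norm <- object$normalized |>
    filter(.data$locus %in% object$selected$locus)
  plot_profiles(sel_norm, labels = object$archetypes, ...)
}

#' @export
autoplot.barseq_clust <- function(object, norm, ...) {
  plot_profiles(norm, labels = object$assignment, ...)
}
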