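#' ECDF-shift plot for a KS result
#'
#' Cumulative frequency curves of the test and background samples; a
#' rightward shift of the test curve is the de-repression signature the
#' one-sided KS test quantifies.
#'
#' @param object A `ks_shift` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ks_shift <- function(object, ...) {
  df <- tidyr::pivot_longer(object$ecdf, c("F_test", "F_background"),
                            names_to = "sample", values_to = "F") |>
    dplyr::mutate(sample = dplyr::recode(.data$sample,
                                         F_test = "test",
                                         F_background = "background"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$F,
                                   colour = .data$sample)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "log2 fold change", y = "cumulative fraction",
      subtitle = sprintf("D = %.3f, p = %.3g (%s)",
                         object$D, object$p, object$method)
    ) +
    ggplot2::theme_minimal()
}

#' Hockey-stick plot of stitched-region signals
#'
#' @param flagged Output of [hockey_stick_cutoff()] (tibble form).
#' @return A ggplot object with super-enhancers highlighted.
#' @export
plot_hockey_stick <- function(flagged) {
  assert_cols(flagged, c("scaled_x", "scaled_y", "is_SE"))
  ggplot2::ggplot(flagged, ggplot2::aes(x = .data$scaled_x,
                                        y = .data$scaled_y,
                                        colour = .data$is_SE)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "region rank (scaled)", y = "H3K27ac signal (scaled)",
                  colour = "super-enhancer") +
    ggplot2::theme_minimal()
}

#' Tag length histogram
#'
#' @param dist Output of [tag_length_distribution()].
#' @return A ggplot object; the modal length is marked.
#' @export
plot_length_distribution <- function(dist) {
  assert_cols(dist, c("length", "n"))
  mode <- modal_length(dist)
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = mode, linetype = "dashed") +
    ggplot2::labs(x = "tag length (nt)", y = "tags",
                  subtitle = sprintf("mode = %d nt", mode)) +
    ggplot2::theme_minimal()
}

#' Feature distribution bar chart
#'
#' @param fd Output of [feature_distribution()].
#' @return A ggplot object.
#' @export
plot_feature_distribution <- function(fd) {
  assert_cols(fd, c("feature", "fraction"))
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$feature, y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "fraction of clusters") +
    ggplot2::theme_minimal()
}
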