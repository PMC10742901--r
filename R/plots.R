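#' Plot growth statistics over Monte Carlo steps
#'
#' Time series of mean backbone length, mean polymer length and free
#' monomer count, faceted by quantity; ensemble input shows one line per
#' box.
#'
#' @param stats A statistics tibble as produced by [run_box()] (columns
#'   `step`, `mean_backbone`, `mean_length`, `n_free_monomers`,
#'   optionally `box_id`).
#' @return A ggplot object.
#' @export
plot_growth <- function(stats) {
  long <- tidyr::pivot_longer(
    stats, c("mean_backbone", "mean_length", "n_free_monomers"),
    names_to = "quantity", values_to = "value")
  labs <- c(mean_backbone = "mean backbone length (monomers)",
            mean_length = "mean polymer length (monomers)",
            n_free_monomers = "free monomers")
  long$quantity <- factor(labs[long$quantity], levels = unname(labs))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value))
  if ("box_id" %in% names(stats)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$box_id),
                                alpha = 0.3) +
      ggplot2::stat_summary(fun = mean, geom = "line", colour = "red",
                            linewidth = 1)
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Monte Carlo step", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname run_box
#' @param object An `mc_run`.
#' @export
autoplot.mc_run <- function(object, ...) plot_growth(object$stats)

#' @rdname run_ensemble
#' @param object An `mc_ensemble`.
#' @export
autoplot.mc_ensemble <- function(object, ...) plot_growth(object$stats)

#' @rdname ensemble_similarity
#' @param object A `similarity_matrix`.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$i, y = .data$j,
                               fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "box", y = "box", fill = "Jaccard") +
    ggplot2::theme_minimal()
}

#' Histogram of subcube monomer counts
#'
#' @param counts A tibble from [subcube_counts()].
#' @return A ggplot object.
#' @export
plot_subcube_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "monomers per subcube", y = "subcubes") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
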