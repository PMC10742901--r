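#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname run_box
#' @param x An `mc_run`.
#' @param ... Unused.
#' @export
tidy.mc_run <- function(x, ...) x$stats

#' @rdname run_box
#' @export
glance.mc_run <- function(x, ...) {
  last <- x$stats[nrow(x$stats), ]
  total <- x$counters[["accepted"]] + x$counters[["reverted"]]
  tibble(steps = x$final$step_count,
         n_beads = nrow(x$final$pos),
         n_polymers = last$n_polymers,
         n_free_monomers = last$n_free_monomers,
         mean_backbone = last$mean_backbone,
         mean_length = last$mean_length,
         acceptance_rate = if (total > 0) {
           x$counters[["accepted"]] / total
         } else NA_real_,
         combinations = x$counters[["combination"]],
         breakdowns = x$counters[["breakdown"]])
}

#' @rdname run_ensemble
#' @param x An `mc_ensemble`.
#' @param ... Unused.
#' @export
tidy.mc_ensemble <- function(x, ...) x$stats

#' @rdname run_ensemble
#' @export
glance.mc_ensemble <- function(x, ...) {
  per_box <- bind_rows(purrr::map(x$runs, glance))
  tibble(n_boxes = length(x$runs),
         steps = per_box$steps[1],
         mean_backbone = mean(per_box$mean_backbone, na.rm = TRUE),
         mean_length = mean(per_box$mean_length, na.rm = TRUE),
         mean_free_monomers = mean(per_box$n_free_monomers),
         acceptance_rate = mean(per_box$acceptance_rate))
}

#' @rdname ensemble_similarity
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @export
tidy.similarity_matrix <- function(x, ...) x$series

#' @rdname ensemble_similarity
#' @export
glance.similarity_matrix <- function(x, ...) {
  off <- x$series$jaccard[x$series$i != x$series$j]
  tibble(n_boxes = nrow(x$matrix), n_comparisons = nrow(x$series),
         step = x$step,
         mean_jaccard = if (length(off)) mean(off) else NA_real_,
         sd_jaccard = if (length(off) > 1) stats::sd(off) else NA_real_)
}
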