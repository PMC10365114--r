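#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   facet_wrap labs scale_fill_manual position_dodge theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot per-group accuracies of a group report
#'
#' Bar chart of cell accuracies by age bin and diagnosis; the worst group
#' is the shortest bar.
#'
#' @param object A `group_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_report <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$group <- sprintf("[%g, %g)", d$age_lo, d$age_hi)
  d$diagnosis <- factor(d$diagnosis, c(0, 1), c("CN", "AD"))
  ggplot(d, aes(x = .data$group, y = .data$accuracy, fill = .data$diagnosis)) +
    geom_col(position = position_dodge()) +
    labs(x = "Age bin (years)", y = "Accuracy", fill = "Diagnosis",
         title = "Group-stratified test accuracy") +
    theme_minimal()
}

#' Plot an adversarial run history
#'
#' Two panels: mean hard-set loss before/after each ascent, and the mean
#' target age per diagnosis across iterations.
#'
#' @param object A `cf_augment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cf_augment <- function(object, ...) {
  h <- tidy(object)
  loss <- tidyr::pivot_longer(h[, c("iteration", "loss_before", "loss_after")],
                              -"iteration", names_to = "series")
  ages <- tidyr::pivot_longer(
    h[, c("iteration", "mean_target_age_ad", "mean_target_age_cn")],
    -"iteration", names_to = "series")
  loss$panel <- "hard-set loss"; ages$panel <- "mean target age (yrs)"
  d <- dplyr::bind_rows(loss, ages)
  ggplot(d, aes(x = .data$iteration, y = .data$value, colour = .data$series)) +
    geom_line() + geom_point() +
    facet_wrap(~panel, scales = "free_y") +
    labs(x = "Outer iteration", y = NULL, colour = NULL,
         title = "Adversarial counterfactual augmentation run") +
    theme_minimal()
}

#' Target-age histograms before and after adversarial training
#'
#' Side-by-side histograms of the hard samples' target ages at
#' initialisation and after the final iteration, faceted by diagnosis:
#' the adversarial game pushes AD target ages old and CN target ages young
#' on a spuriously coupled cohort.
#'
#' @param result A `cf_augment`.
#' @param bin_edges Histogram bin edges (default 5-year bins over 60--90).
#' @return A ggplot object.
#' @export
plot_target_age_shift <- function(result, bin_edges = seq(60, 90, by = 5)) {
  tab <- target_age_table(result)
  tab <- tab[tab$iteration %in% c(0L, max(tab$iteration)), ]
  tab$when <- ifelse(tab$iteration == 0, "before", "after")
  d <- dplyr::group_by(tab, .data$when, .data$diagnosis) |>
    dplyr::reframe(age_histogram(.data$target_age, bin_edges))
  d$diagnosis <- factor(d$diagnosis, c(0, 1), c("CN", "AD"))
  d$when <- factor(d$when, c("before", "after"))
  ggplot(d, aes(x = .data$bin_lo + diff(bin_edges)[1] / 2, y = .data$count,
                fill = .data$when)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~diagnosis) +
    labs(x = "Target age (years)", y = "Count", fill = NULL,
         title = "Target ages before and after adversarial training") +
    theme_minimal()
}

#' Plot a rendered slice
#'
#' @param image Image matrix in `[-1, 1]`.
#' @param title Optional title.
#' @return A ggplot object.
#' @export
plot_slice <- function(image, title = NULL) {
  d <- tidyr::expand_grid(x = seq_len(nrow(image)), y = seq_len(ncol(image)))
  d$value <- as.vector(image)
  ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    labs(title = title, x = NULL, y = NULL, fill = "intensity") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
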