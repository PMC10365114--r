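#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a classifier fit into its training curve
#' @param x A `classifier_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `accuracy`.
#' @export
tidy.classifier_fit <- function(x, ...) x$history

#' One-row summary of a classifier fit
#' @param x A `classifier_fit`.
#' @param ... Unused.
#' @return Tibble with epochs trained and final loss/accuracy.
#' @export
glance.classifier_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), train_loss = last$loss,
                 train_accuracy = last$accuracy,
                 n_parameters = sum(vapply(x$classifier$params, length, integer(1))))
}

#' Tidy a generator fit into its training curve
#' @param x A `generator_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `mse`.
#' @export
tidy.generator_fit <- function(x, ...) x$history

#' One-row summary of a generator fit
#' @param x A `generator_fit`.
#' @param ... Unused.
#' @return Tibble with epochs and final regression mse.
#' @export
glance.generator_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 oracle_mse = x$history$mse[nrow(x$history)],
                 n_parameters = sum(vapply(x$generator$params, length, integer(1))))
}

#' Per-iteration record of an adversarial augmentation run
#' @param x A `cf_augment`.
#' @param ... Unused.
#' @return The `run_history` tibble (scalar columns only).
#' @export
tidy.cf_augment <- function(x, ...) {
  h <- tibble::as_tibble(x$history)
  h$target_ages <- NULL
  h
}

#' One-row summary of an adversarial augmentation run
#' @param x A `cf_augment`.
#' @param ... Unused.
#' @return Tibble with iterations, hard-set size, loss and mean-target-age
#'   endpoints.
#' @export
glance.cf_augment <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    iterations = nrow(h), n_hard = h$n_syn[1],
    loss_first = h$loss_before[1], loss_last = h$loss_after[nrow(h)],
    mean_target_age_initial = mean(attr(h, "initial_target_ages")),
    mean_target_age_final = h$mean_target_age[nrow(h)]
  )
}

#' Cells of a group report
#' @param x A `group_report`.
#' @param ... Unused.
#' @return Tibble of per (diagnosis x age-bin) cells.
#' @export
tidy.group_report <- function(x, ...) tibble::as_tibble(x)

#' Overall row of a group report
#' @param x A `group_report`.
#' @param ... Unused.
#' @return One-row tibble (overall accuracy/precision/recall, worst group).
#' @export
glance.group_report <- function(x, ...) overall_metrics(x)

#' Export target-age snapshots as a long table
#'
#' One row per (iteration, hard sample): the trajectory behind the
#' target-age histograms.
#'
#' @param result A `cf_augment`.
#' @return Tibble with `iteration`, `sample_id`, `diagnosis`, `target_age`;
#'   iteration 0 holds the initial ages.
#' @export
target_age_table <- function(result) {
  stopifnot(inherits(result, "cf_augment"))
  h <- result$history
  hard <- result$hard
  init <- tibble::tibble(iteration = 0L, sample_id = hard$sample_id,
                         diagnosis = hard$diagnosis,
                         target_age = attr(h, "initial_target_ages"))
  iters <- purrr::map_dfr(seq_len(nrow(h)), function(i) {
    tibble::tibble(iteration = i, sample_id = hard$sample_id,
                   diagnosis = hard$diagnosis,
                   target_age = h$target_ages[[i]])
  })
  dplyr::bind_rows(init, iters)
}
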