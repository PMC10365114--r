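#' Group-stratified classification metrics
#'
#' Evaluates a classifier on a test split stratified by diagnosis and age
#' bin.  Accuracy is computed per (diagnosis x age-bin) cell at threshold
#' 0.5; precision (`TP / (TP + FP)`) and recall (`TP / (TP + FN)`), with AD
#' as the positive class, are computed per age bin over both labels and
#' overall.  Bins are half-open `[lo, hi)`, the last bin closed.  The
#' worst group is the cell with minimal accuracy; empty cells are recorded
#' as `NA` and excluded.
#'
#' @param C Classifier (or fit), or a numeric vector of predicted AD
#'   probabilities aligned with `samples`.
#' @param samples Test samples (a `toy_dataset` split).
#' @param age_bins Bin edges in years; defaults to the dataset's own bins
#'   (`c(60, 70, 80, 90)` for uncoupled cohorts, `c(60, split, 90)` for
#'   spurious ones).
#' @param threshold Decision threshold (fixed 0.5).
#' @return A `group_report`: a tibble with one row per cell (`diagnosis`,
#'   `age_lo`, `age_hi`, `n`, `accuracy`) and attributes `bin_metrics` (per
#'   age bin: accuracy, precision, recall), `overall` and `worst_group`.
#'   `glance()` returns the overall row; `tidy()` the cells.
#' @export
#' @examples
#' cfg <- render_config(size = 32)
#' ds <- sample_dataset(40, seed = 1, cfg = cfg)
#' fit <- pretrain_classifier(ds, train_config(epochs = 5, seed = 1))
#' rep <- group_metrics(fit, dataset_split(ds, "test"))
#' glance(rep)
group_metrics <- function(C, samples, age_bins = NULL, threshold = 0.5) {
  age_bins <- age_bins %||% attr(samples, "age_bins") %||% c(60, 70, 80, 90)
  stopifnot(!is.unsorted(age_bins), length(age_bins) >= 2)
  p <- if (is.numeric(C)) {
    stopifnot(length(C) == nrow(samples))
    C
  } else {
    predict_proba(as_classifier(C), samples)
  }
  pred <- as.integer(p > threshold)
  y <- samples$diagnosis
  bin <- findInterval(samples$age, age_bins, rightmost.closed = TRUE)
  n_bins <- length(age_bins) - 1L
  grid <- tidyr::expand_grid(diagnosis = c(0L, 1L), bin = seq_len(n_bins))
  cells <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(r) {
    dx <- grid$diagnosis[r]; b <- grid$bin[r]
    m <- y == dx & bin == b
    tibble::tibble(
      diagnosis = dx, age_lo = age_bins[b], age_hi = age_bins[b + 1],
      n = sum(m),
      accuracy = if (any(m)) mean(pred[m] == y[m]) else NA_real_
    )
  }))
  bins <- dplyr::bind_rows(lapply(seq_len(n_bins), function(b) {
    m <- bin == b
    tp <- sum(pred[m] == 1 & y[m] == 1); fp <- sum(pred[m] == 1 & y[m] == 0)
    fn <- sum(pred[m] == 0 & y[m] == 1)
    tibble::tibble(
      age_lo = age_bins[b], age_hi = age_bins[b + 1], n = sum(m),
      accuracy = if (any(m)) mean(pred[m] == y[m]) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    )
  }))
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  overall <- tibble::tibble(
    n = length(y), accuracy = mean(pred == y),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
  ok <- !is.na(cells$accuracy)
  wi <- which(ok)[which.min(cells$accuracy[ok])]
  worst <- list(
    id = sprintf("%s %g-%g", ifelse(cells$diagnosis[wi] == 1, "AD", "CN"),
                 cells$age_lo[wi], cells$age_hi[wi]),
    accuracy = cells$accuracy[wi]
  )
  structure(cells, class = c("group_report", class(tibble::tibble())),
            bin_metrics = bins, overall = overall, worst_group = worst,
            age_bins = age_bins)
}

#' Overall metrics of a group report
#' @param report A `group_report`.
#' @return One-row tibble: overall accuracy/precision/recall, worst-group
#'   id and accuracy.
#' @export
overall_metrics <- function(report) {
  stopifnot(inherits(report, "group_report"))
  ov <- attr(report, "overall")
  w <- attr(report, "worst_group")
  tibble::tibble(n = ov$n, accuracy = ov$accuracy, precision = ov$precision,
                 recall = ov$recall, worst_group = w$id,
                 worst_group_accuracy = w$accuracy)
}

#' Worst-group accuracy of a group report
#' @param report A `group_report`.
#' @return The minimum cell accuracy.
#' @export
worst_group_accuracy <- function(report) {
  attr(report, "worst_group")$accuracy
}

#' Histogram counts over age bins
#'
#' Half-open bins `[lo, hi)` with the last bin closed, the convention used
#' for the target-age histograms before and after adversarial training.
#'
#' @param ages Numeric ages.
#' @param bin_edges Sorted bin edges.
#' @return Tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
#' @examples
#' age_histogram(c(60, 75, 90), c(60, 75, 90))
age_histogram <- function(ages, bin_edges) {
  stopifnot(!is.unsorted(bin_edges), length(bin_edges) >= 2)
  b <- findInterval(ages, bin_edges, rightmost.closed = TRUE)
  n_bins <- length(bin_edges) - 1L
  tibble::tibble(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    count = vapply(seq_len(n_bins), function(i) sum(b == i), integer(1))
  )
}

#' Compare several group reports in one ranking table
#'
#' One row per method, columns for each diagnosis x age-bin cell accuracy
#' plus overall and worst-group accuracy.  The best method per column is
#' recorded in the `best_per_column` attribute.
#'
#' @param reports Named list of `group_report` objects on the same bins.
#' @return A tibble, methods as rows.
#' @export
compare_runs <- function(reports) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  rows <- purrr::imap_dfr(reports, function(rep, nm) {
    cells <- tibble::as_tibble(rep)
    vals <- stats::setNames(
      cells$accuracy,
      sprintf("%s_%g_%g", ifelse(cells$diagnosis == 1, "AD", "CN"),
              cells$age_lo, cells$age_hi))
    dplyr::bind_cols(tibble::tibble(method = nm), tibble::as_tibble_row(vals),
                     tibble::tibble(overall = attr(rep, "overall")$accuracy,
                                    worst_group = worst_group_accuracy(rep)))
  })
  num <- names(rows)[vapply(rows, is.numeric, logical(1))]
  best <- vapply(num, function(cl) {
    v <- rows[[cl]]
    if (all(is.na(v))) NA_character_ else rows$method[which.max(v)]
  }, character(1))
  attr(rows, "best_per_column") <- best
  rows
}
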