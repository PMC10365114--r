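#' Persist a toy dataset to a directory
#'
#' Writes `metadata.csv` (all scalar columns), `images.rds` (the image
#' list), and `provenance.yaml` (the generating configuration), so a run's
#' dataset artifact is reproducible and inspectable.
#'
#' @param dataset A `toy_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_toy_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- tibble::as_tibble(dataset)
  meta$image <- NULL
  readr::write_csv(meta, file.path(dir, "metadata.csv"))
  saveRDS(dataset$image, file.path(dir, "images.rds"))
  cfg <- attr(dataset, "render_cfg")
  yaml::write_yaml(
    list(render_cfg = unclass(cfg),
         provenance = attr(dataset, "provenance"),
         age_bins = attr(dataset, "age_bins")),
    file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Read a toy dataset written by [write_toy_dataset()]
#'
#' @param dir Directory containing `metadata.csv`, `images.rds`,
#'   `provenance.yaml`.
#' @return A `toy_dataset`.
#' @export
read_toy_dataset <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE)
  meta$image <- readRDS(file.path(dir, "images.rds"))
  side <- yaml::read_yaml(file.path(dir, "provenance.yaml"))
  cfg <- side$render_cfg
  numeric_pairs <- c("base_outer", "base_vent", "vent_growth", "age_range")
  for (nm in numeric_pairs) cfg[[nm]] <- as.numeric(cfg[[nm]])
  cfg <- structure(cfg, class = "render_config")
  new_toy_dataset(meta, cfg, side$provenance,
                  age_bins = as.numeric(side$age_bins))
}

#' Read 2D slices from NIfTI volumes with a metadata table
#'
#' Optional ingestion path for real image data: one axial slice per volume,
#' intensity-rescaled to `[-1, 1]`, joined with a delimited metadata table
#' carrying `sample_id`, `subject_id`, `age`, `diagnosis`, `split` and
#' `file`.  Requires the RNifti package.  Counterfactual generation is not
#' available for ingested data (no subject geometry), but classification,
#' selection and evaluation are.
#'
#' @param metadata_csv Path to the metadata table; its `file` column names
#'   the NIfTI volumes (relative paths resolved against the table's
#'   directory).
#' @param slice Axial slice index, or `NULL` for the middle slice.
#' @param size Target side length; slices are cropped/padded to square
#'   `size x size`.
#' @return A tibble shaped like a `toy_dataset` (without subject geometry).
#' @export
read_nifti_slices <- function(metadata_csv, slice = NULL, size = 64) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("Reading NIfTI volumes requires the RNifti package.")
  }
  meta <- readr::read_csv(metadata_csv, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "subject_id", "age", "diagnosis",
                  "split", "file") %in% names(meta)))
  base <- dirname(metadata_csv)
  meta$image <- purrr::map(meta$file, function(f) {
    path <- if (file.exists(f)) f else file.path(base, f)
    vol <- RNifti::readNifti(path)
    z <- slice %||% ceiling(dim(vol)[3] / 2)
    sl <- vol[, , z]
    hi <- stats::quantile(sl, 0.995)
    sl <- clip(sl, 0, hi)
    sl <- if (hi > 0) 2 * sl / hi - 1 else sl - 1
    # center-crop or zero-pad to size x size
    out <- matrix(-1, size, size)
    rx <- seq_len(min(size, nrow(sl))); ry <- seq_len(min(size, ncol(sl)))
    out[rx, ry] <- sl[rx, ry]
    out
  })
  meta$file <- NULL
  meta
}
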