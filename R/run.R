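#' Save / load an epoched recording
#'
#' The trial tensor is written as a gzip-compressed TSV (one row per trial,
#' channels-major flattening) with a JSON sidecar carrying sampling rate,
#' labels, channel names and window.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param path_prefix output prefix; writes `<prefix>.tsv.gz` and
#'   `<prefix>.json`.
#' @return `path_prefix`, invisibly.
#' @export
write_epochs <- function(epochs, path_prefix) {
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, nrow = d[1L])   # trial x (channel*sample)
  con <- gzfile(paste0(path_prefix, ".tsv.gz"), "w")
  utils::write.table(flat, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(fs = epochs$fs, labels = epochs$labels,
         channel_names = epochs$channel_names, window = epochs$window,
         dim = d),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path_prefix)
}

#' @rdname write_epochs
#' @return `read_epochs` returns the reconstructed [epoched_eeg()].
#' @export
read_epochs <- function(path_prefix) {
  side <- jsonlite::read_json(paste0(path_prefix, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(gzfile(paste0(path_prefix, ".tsv.gz")),
                                      sep = "\t", header = FALSE))
  data <- array(flat, dim = side$dim)
  epoched_eeg(data, side$labels, side$fs, side$channel_names, side$window)
}

#' Run the full pipeline and write its artifacts
#'
#' Cross-validates the pipeline on the given epochs, then writes the fold
#' metrics, their summary, and a config snapshot to `out_dir`. Deterministic
#' given `seed`.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param config an [mi_pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @param n_folds,n_repeats,seed passed to [cross_validate()].
#' @return the [cross_validate()] report, invisibly.
#' @export
run_pipeline <- function(epochs, config = mi_pipeline_config(), out_dir,
                         n_folds = 5L, n_repeats = 5L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- cross_validate(epochs, config, n_folds, n_repeats, seed)
  utils::write.table(report$results, file.path(out_dir, "cv_folds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(mean = as.list(report$mean), sd = as.list(report$sd),
         n_folds = n_folds, n_repeats = n_repeats, seed = seed),
    file.path(out_dir, "cv_report.json"), auto_unbox = TRUE, digits = NA
  )
  snap <- config
  snap$preprocess <- unclass(snap$preprocess)
  snap$bands_def <- unclass(snap$bands_def)
  jsonlite::write_json(unclass(snap), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
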