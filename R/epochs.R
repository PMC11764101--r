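#' Epoched EEG container
#'
#' Bundles a trial tensor with its class labels, sampling rate, channel names
#' and the analysis window relative to the cue. All downstream stages of the
#' pipeline consume this container.
#'
#' @param data numeric array `[n_trials x n_channels x n_samples]`, in
#'   microvolts.
#' @param labels integer class label per trial (binary decoding expects two
#'   distinct values, conventionally 0/1).
#' @param fs sampling rate in Hz.
#' @param channel_names optional character vector of channel names; defaults
#'   to `ch1..chN`.
#' @param window numeric length-2 vector `(start_s, end_s)` relative to the
#'   cue; must satisfy `n_samples == round((end_s - start_s) * fs)`.
#' @return object of class `mi_epochs` with elements `data`, `labels`, `fs`,
#'   `channel_names`, `window`.
#' @export
epoched_eeg <- function(data, labels, fs, channel_names = NULL, window = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array [trials x channels x samples]")
  }
  d <- dim(data)
  labels <- as.integer(labels)
  if (d[1L] != length(labels)) stop("number of trials must equal length(labels)")
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  channel_names <- channel_names %||% paste0("ch", seq_len(d[2L]))
  if (length(channel_names) != d[2L]) stop("`channel_names` must have one entry per channel")
  window <- window %||% c(0, d[3L] / fs)
  if (length(window) != 2L || window[2L] <= window[1L]) {
    stop("`window` must be (start_s, end_s) with end_s > start_s")
  }
  if (round(diff(window) * fs) != d[3L]) {
    stop("window duration is inconsistent with the sample count at fs = ", fs)
  }
  structure(
    list(data = data, labels = labels, fs = fs,
         channel_names = as.character(channel_names), window = as.numeric(window)),
    class = "mi_epochs"
  )
}

#' @export
print.mi_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched EEG: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  window: [%g, %g] s; classes: %s\n", x$window[1L], x$window[2L],
              paste(names(table(x$labels)), table(x$labels), sep = ":", collapse = ", ")))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1L]
n_channels <- function(epochs) dim(epochs$data)[2L]
n_samples <- function(epochs) dim(epochs$data)[3L]

#' Subset trials of an epoched recording
#'
#' @param epochs an [epoched_eeg()] object.
#' @param idx trial indices to keep.
#' @return a new `mi_epochs` with the selected trials.
#' @export
subset_epochs <- function(epochs, idx) {
  epoched_eeg(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
              epochs$fs, epochs$channel_names, epochs$window)
}

# Single-trial channel x sample matrix.
trial_matrix <- function(epochs, t) {
  matrix(epochs$data[t, , ], nrow = n_channels(epochs))
}

#' Cut epochs out of a continuous recording
#'
#' Windows are taken relative to each event onset using 0-based sample
#' indexing and half-open intervals: trial `t` holds samples
#' `[onset + start_s * fs, onset + end_s * fs)`.
#'
#' @param continuous numeric matrix `[n_channels x n_samples]`.
#' @param fs sampling rate in Hz.
#' @param events data frame or 2-column matrix with columns
#'   `onset_sample` (0-based) and `label`.
#' @param cfg a [preprocess_config()]; its `epoch_window` defines the cut.
#' @param channel_names optional channel names.
#' @return an [epoched_eeg()] object.
#' @export
extract_epochs <- function(continuous, fs, events, cfg = preprocess_config(),
                           channel_names = NULL) {
  if (!is.matrix(continuous)) stop("`continuous` must be a channels x samples matrix")
  events <- as.data.frame(events)
  if (ncol(events) < 2L) stop("`events` needs columns (onset_sample, label)")
  names(events)[1:2] <- c("onset_sample", "label")
  win <- cfg$epoch_window
  n_keep <- round((win[2L] - win[1L]) * fs)
  first0 <- events$onset_sample + round(win[1L] * fs)   # 0-based inclusive
  last0 <- first0 + n_keep                              # 0-based exclusive
  bad <- which(first0 < 0 | last0 > ncol(continuous))
  if (length(bad)) {
    stop("epoch window exceeds recording bounds for event(s): ",
         paste(bad, collapse = ", "))
  }
  data <- array(0, dim = c(nrow(events), nrow(continuous), n_keep))
  for (t in seq_len(nrow(events))) {
    data[t, , ] <- continuous[, (first0[t] + 1L):last0[t], drop = FALSE]
  }
  epoched_eeg(data, events$label, fs, channel_names %||% rownames(continuous),
              window = win)
}
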