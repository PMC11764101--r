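#' Preprocessing configuration
#'
#' @param band numeric `(low_hz, high_hz)` pass band; the default 8--30 Hz
#'   covers the mu and beta rhythms carrying ERD/ERS.
#' @param filter_order Butterworth order (the effective attenuation doubles
#'   under the zero-phase forward-backward pass).
#' @param epoch_window numeric `(start_s, end_s)` relative to the cue.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(band = c(8, 30), filter_order = 5L,
                              epoch_window = c(0.5, 3.5)) {
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L]) {
    stop("`band` must be (low_hz, high_hz) with 0 < low < high")
  }
  if (filter_order < 1L) stop("`filter_order` must be >= 1")
  structure(list(band = as.numeric(band), filter_order = as.integer(filter_order),
                 epoch_window = as.numeric(epoch_window)),
            class = "preprocess_config")
}

# Forward-backward IIR filtering with odd-length reflection padding, applied
# to a single numeric vector. Padding length is 3 * max(len(a), len(b)).
filtfilt_reflect <- function(b, a, x) {
  npad <- 3L * max(length(a), length(b))
  n <- length(x)
  if (n <= npad) {
    stop("signal too short for zero-phase filtering (need > ", npad, " samples)")
  }
  front <- 2 * x[1L] - x[(npad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- as.numeric(signal::filter(b, a, c(front, x, back)))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(npad + 1L):(npad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward (zero-phase response,
#' squared magnitude) with odd reflection padding at both ends.
#' Accepts a vector, a channels x samples matrix, or an [epoched_eeg()]
#' object (filtered trial by trial).
#'
#' @param x numeric vector, matrix (channels x samples), or `mi_epochs`.
#' @param fs sampling rate in Hz (taken from the object for `mi_epochs`).
#' @param cfg a [preprocess_config()].
#' @return filtered object of the same shape/class as the input.
#' @export
bandpass_filter <- function(x, fs = NULL, cfg = preprocess_config()) {
  if (inherits(x, "mi_epochs")) fs <- x$fs
  if (is.null(fs)) stop("`fs` is required")
  band <- cfg$band
  if (band[2L] >= fs / 2) {
    stop("band edge ", band[2L], " Hz must be below the Nyquist frequency ", fs / 2, " Hz")
  }
  bw <- signal::butter(cfg$filter_order, band / (fs / 2), type = "pass")
  fb <- function(v) filtfilt_reflect(bw$b, bw$a, v)
  if (inherits(x, "mi_epochs")) {
    out <- x
    for (t in seq_len(n_trials(x))) {
      out$data[t, , ] <- t(apply(trial_matrix(x, t), 1L, fb))
    }
    return(out)
  }
  if (is.matrix(x)) return(t(apply(x, 1L, fb)))
  fb(as.numeric(x))
}

# Polyphase resampling of a vector from fs_in to fs_out (rational ratio).
resample_to <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  p <- fs_out; q <- fs_in
  if (p == round(p) && q == round(q)) {
    g <- gcd2(round(p), round(q))
    p <- round(p) / g; q <- round(q) / g
  } else {
    stop("non-integer sampling rates are not supported for resampling")
  }
  as.numeric(signal::resample(x, p, q))
}
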