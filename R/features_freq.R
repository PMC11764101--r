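#' Rhythm band definition
#'
#' @param alpha,beta numeric `(low_hz, high_hz)` limits of the mu/alpha and
#'   beta rhythm bands. Defaults 8--13 and 13--30 Hz; bands are half-open
#'   `[low, high)` and must not overlap.
#' @return list of class `band_definition`.
#' @export
band_definition <- function(alpha = c(8, 13), beta = c(13, 30)) {
  for (b in list(alpha, beta)) {
    if (length(b) != 2L || b[2L] <= b[1L] || b[1L] < 0) {
      stop("band limits must be (low_hz, high_hz) with 0 <= low < high")
    }
  }
  if (max(alpha[1L], beta[1L]) < min(alpha[2L], beta[2L])) {
    if (!(alpha[2L] <= beta[1L] || beta[2L] <= alpha[1L])) {
      stop("alpha and beta bands must not overlap")
    }
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "band_definition")
}

# Band energy of the unnormalized DFT: sum of |X(k)|^2 over positive-frequency
# bins whose frequency lies in [low, high) Hz. No one-sided doubling.
dft_band_energy <- function(x, fs, band) {
  Tn <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(Tn) - 1L) * fs / Tn
  keep <- freqs >= band[1L] & freqs < band[2L] & freqs <= fs / 2
  sum(Mod(X[keep])^2)
}

#' Frequency-domain features
#'
#' Per channel: band power spectral density and band energy of the alpha and
#' beta rhythms, computed from the unnormalized DFT as
#' `energy = sum |X(k)|^2` over bins in the band and `psd = energy / T`.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param bands a [band_definition()].
#' @return an `"FD"` [domain_features()] table with `4 * n_channels` columns
#'   named `<channel>:{psd_alpha,psd_beta,energy_alpha,energy_beta}`.
#' @export
frequency_domain_features <- function(epochs, bands = band_definition()) {
  fs <- epochs$fs
  for (b in list(bands$alpha, bands$beta)) {
    if (b[2L] > fs / 2) stop("band edge ", b[2L], " Hz outside [0, fs/2)")
  }
  nch <- n_channels(epochs)
  Tn <- n_samples(epochs)
  out <- matrix(0, n_trials(epochs), 4L * nch)
  for (t in seq_len(n_trials(epochs))) {
    X <- trial_matrix(epochs, t)
    for (ch in seq_len(nch)) {
      ea <- dft_band_energy(X[ch, ], fs, bands$alpha)
      eb <- dft_band_energy(X[ch, ], fs, bands$beta)
      out[t, (ch - 1L) * 4L + 1:4] <- c(ea / Tn, eb / Tn, ea, eb)
    }
  }
  feats <- c("psd_alpha", "psd_beta", "energy_alpha", "energy_beta")
  nm <- as.vector(t(outer(epochs$channel_names, feats, paste, sep = ":")))
  domain_features(out, "FD", nm)
}
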