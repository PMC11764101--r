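# Daubechies-4 (8-tap) decomposition filters, low-pass then high-pass by the
# quadrature-mirror relation g[k] = (-1)^k h[L-1-k]. Orthonormal, so the
# periodized transform conserves energy exactly.
db4_dec_lo <- c(
  -0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
  -0.187034811718881140, -0.027983769416983850, 0.630880767929590400,
  0.714846570552541500, 0.230377813308855230
)

wavelet_filters <- function(wavelet = "db4") {
  if (!identical(wavelet, "db4")) stop("only the db4 wavelet is implemented")
  lo <- db4_dec_lo
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(lo = lo, hi = hi)
}

# One analysis step of the periodized DWT: circular convolution with the
# decomposition filters followed by dyadic down-sampling.
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  L <- length(lo)
  idx <- outer(2L * (seq_len(n %/% 2L) - 1L), seq_len(L) - 1L, `+`) %% n + 1L
  M <- matrix(x[idx], nrow = n %/% 2L)
  list(approx = as.numeric(M %*% lo), detail = as.numeric(M %*% hi))
}

#' Periodized discrete wavelet transform
#'
#' Multi-level Mallat decomposition with periodic signal extension and an
#' orthonormal wavelet, so total coefficient energy equals signal energy
#' exactly. The input length must be divisible by `2^n_levels`.
#'
#' @param x numeric vector.
#' @param wavelet wavelet name; `"db4"` is implemented.
#' @param n_levels number of decomposition levels.
#' @return list with `approx` (deepest approximation `A_L`) and `details`
#'   (list `D1..DL`, finest first).
#' @export
dwt_periodized <- function(x, wavelet = "db4", n_levels = 4L) {
  x <- as.numeric(x)
  if (length(x) %% 2L^n_levels != 0L) {
    stop("signal length must be divisible by 2^n_levels for the periodized DWT")
  }
  if (length(x) / 2L^n_levels < 1L) stop("too few samples for ", n_levels, " levels")
  f <- wavelet_filters(wavelet)
  details <- vector("list", n_levels)
  a <- x
  for (j in seq_len(n_levels)) {
    s <- dwt_step(a, f$lo, f$hi)
    details[[j]] <- s$detail
    a <- s$approx
  }
  names(details) <- paste0("D", seq_len(n_levels))
  list(approx = a, details = details)
}

#' Time-frequency domain features (wavelet sub-band energies)
#'
#' Per channel, the summed squared detail coefficients of a db4 Mallat
#' decomposition at the levels mapped to the alpha and beta rhythms
#' (default: `D4` for alpha, `D3` for beta, the mapping used with 100 Hz
#' recordings). Signals at other sampling rates are resampled to 100 Hz
#' first so the level-to-rhythm mapping is preserved; trailing samples are
#' truncated to a multiple of `2^n_levels` for the periodized transform.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param wavelet wavelet name (db4).
#' @param n_levels decomposition depth, default 4.
#' @param level_map list with integer `alpha` and `beta` detail levels.
#' @return a `"TFD"` [domain_features()] table with `2 * n_channels` columns
#'   named `<channel>:{dwt_energy_alpha,dwt_energy_beta}`.
#' @export
timefrequency_features <- function(epochs, wavelet = "db4", n_levels = 4L,
                                   level_map = list(alpha = 4L, beta = 3L)) {
  if (level_map$alpha > n_levels || level_map$beta > n_levels) {
    stop("`level_map` levels must not exceed `n_levels`")
  }
  nch <- n_channels(epochs)
  out <- matrix(0, n_trials(epochs), 2L * nch)
  block <- 2L^n_levels
  for (t in seq_len(n_trials(epochs))) {
    X <- trial_matrix(epochs, t)
    for (ch in seq_len(nch)) {
      x <- resample_to(X[ch, ], epochs$fs, 100)
      keep <- (length(x) %/% block) * block
      if (keep < block) stop("too few samples for ", n_levels, " wavelet levels")
      w <- dwt_periodized(x[seq_len(keep)], wavelet, n_levels)
      out[t, (ch - 1L) * 2L + 1:2] <- c(
        sum(w$details[[level_map$alpha]]^2),
        sum(w$details[[level_map$beta]]^2)
      )
    }
  }
  feats <- c("dwt_energy_alpha", "dwt_energy_beta")
  nm <- as.vector(t(outer(epochs$channel_names, feats, paste, sep = ":")))
  domain_features(out, "TFD", nm)
}
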