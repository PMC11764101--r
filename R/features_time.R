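#' Higuchi fractal dimension of a time series
#'
#' Estimates the fractal dimension from curve lengths at down-sampling
#' intervals `l = 1..l_max`: for each interval and offset `m`, the
#' normalized curve length \eqn{L_m(l)} is accumulated, lengths are averaged
#' over offsets, and the dimension is the least-squares slope of
#' \eqn{\ln L(l)} against \eqn{\ln(1/l)}. Values near 1 indicate a smooth
#' curve, values near 2 a plane-filling (noise-like) signal.
#'
#' @param x numeric vector (length must be at least `2 * l_max`).
#' @param l_max maximum down-sampling interval; free tuning parameter,
#'   default 10.
#' @return scalar dimension estimate. A constant signal has no curve length
#'   at any scale; it returns 1.0 (the dimension of a degenerate line) with a
#'   warning.
#' @export
higuchi_fd <- function(x, l_max = 10L) {
  x <- as.numeric(x)
  Tn <- length(x)
  if (l_max < 2L) stop("`l_max` must be >= 2")
  if (Tn < 2L * l_max) stop("signal length must be at least 2 * l_max")
  if (max(x) - min(x) < .Machine$double.eps * max(1, abs(x[1L]))) {
    warning("constant signal: Higuchi fractal dimension is degenerate, returning 1.0")
    return(1.0)
  }
  L <- numeric(l_max)
  for (l in seq_len(l_max)) {
    Lm <- numeric(l)
    for (m in seq_len(l)) {
      sub <- x[seq.int(m, Tn, by = l)]
      Q <- length(sub) - 1L
      if (Q < 1L) {
        Lm[m] <- NA_real_
      } else {
        Lm[m] <- sum(abs(diff(sub))) * (Tn - 1) / (Q * l) / l
      }
    }
    L[l] <- mean(Lm, na.rm = TRUE)
  }
  ok <- is.finite(L) & L > 0
  if (sum(ok) < 2L) {
    warning("degenerate curve lengths: returning 1.0")
    return(1.0)
  }
  ll <- log(1 / seq_len(l_max))[ok]
  unname(stats::coef(stats::lm.fit(cbind(1, ll), log(L[ok])))[2L])
}

#' Time-domain features
#'
#' Per channel: mean, population variance, root mean square, and Higuchi
#' fractal dimension -- 4 features per channel.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param l_max Higuchi interval bound, see [higuchi_fd()].
#' @return a `"TD"` [domain_features()] table with `4 * n_channels` columns
#'   named `<channel>:{mean,var,rms,hfd}`.
#' @export
time_domain_features <- function(epochs, l_max = 10L) {
  Tn <- n_samples(epochs)
  if (Tn < 2L * l_max) stop("`l_max` too large for ", Tn, " samples per trial")
  nch <- n_channels(epochs)
  feats <- c("mean", "var", "rms", "hfd")
  out <- matrix(0, n_trials(epochs), 4L * nch)
  for (t in seq_len(n_trials(epochs))) {
    X <- trial_matrix(epochs, t)
    for (ch in seq_len(nch)) {
      x <- X[ch, ]
      out[t, (ch - 1L) * 4L + 1:4] <- c(
        mean(x),
        mean((x - mean(x))^2),
        sqrt(mean(x^2)),
        higuchi_fd(x, l_max)
      )
    }
  }
  nm <- as.vector(t(outer(epochs$channel_names, feats, paste, sep = ":")))
  domain_features(out, "TD", nm)
}
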