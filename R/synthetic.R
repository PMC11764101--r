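# 1/f-shaped noise: white noise whose spectrum is scaled by f^{-1/2}
# (power slope -1), normalized to unit standard deviation.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)            # symmetric over positive/negative bins
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# Narrow-band oscillation: band-pass filtered white noise with edge samples
# discarded, unit standard deviation.
narrowband_noise <- function(n, fs, band) {
  pad <- fs
  w <- stats::rnorm(n + 2L * pad)
  cfg <- preprocess_config(band = band, filter_order = 4L, epoch_window = c(0, 1))
  x <- bandpass_filter(w, fs, cfg)[(pad + 1L):(pad + n)]
  as.numeric(scale(x))
}

#' Synthetic motor-imagery EEG configuration
#'
#' Describes band-limited oscillatory EEG with class-dependent, spatially
#' lateralized alpha/beta power modulation (ERD/ERS) over configurable
#' channels, on top of 1/f plus white broadband noise.
#'
#' @param n_trials_per_class trials per class (labels 0 and 1, balanced).
#' @param n_channels number of channels.
#' @param fs sampling rate (Hz).
#' @param duration_s epoch duration (s).
#' @param alpha_band,beta_band oscillation bands (Hz).
#' @param erd_channels list mapping class (`"0"`, `"1"`) to channel indices
#'   whose oscillatory amplitude is attenuated during that class (the
#'   contralateral desynchronization).
#' @param ers_channels like `erd_channels` but amplified (ipsilateral
#'   synchronization); defaults to the opposite class's ERD channels.
#' @param erd_depth fractional amplitude reduction in `[0, 1]` on ERD
#'   channels (power scales by `(1 - depth)^2`).
#' @param beta_erd_depth attenuation applied to the beta oscillation;
#'   defaults to `erd_depth`.
#' @param ers_gain fractional amplitude increase (>= 0) on ERS channels.
#' @param alpha_amp,beta_amp baseline oscillation amplitudes (relative to
#'   the unit-variance noise components).
#' @param noise_sd broadband noise scale (1/f component; white noise enters
#'   at half this scale).
#' @param lateralized when FALSE the class-dependent attenuation is applied
#'   to every channel, so the class signal is purely spectral with no
#'   spatial structure.
#' @param seed integer seed; generation is bit-reproducible.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_trials_per_class = 100L, n_channels = 8L,
                             fs = 100, duration_s = 3,
                             alpha_band = c(8, 12), beta_band = c(18, 26),
                             erd_channels = list("0" = c(5L, 6L), "1" = c(2L, 3L)),
                             ers_channels = NULL,
                             erd_depth = 0.6, beta_erd_depth = erd_depth,
                             ers_gain = 0, alpha_amp = 1, beta_amp = 0.6,
                             noise_sd = 1, lateralized = TRUE, seed = 1L) {
  if (erd_depth < 0 || erd_depth > 1) stop("`erd_depth` must lie in [0, 1]")
  if (ers_gain < 0) stop("`ers_gain` must be >= 0")
  if (any(unlist(erd_channels) > n_channels)) stop("`erd_channels` indices exceed n_channels")
  if (fs <= 2 * max(alpha_band, beta_band)) stop("`fs` must exceed twice the highest band edge")
  ers_channels <- ers_channels %||% list("0" = erd_channels[["1"]],
                                         "1" = erd_channels[["0"]])
  structure(
    list(n_trials_per_class = as.integer(n_trials_per_class),
         n_channels = as.integer(n_channels), fs = fs, duration_s = duration_s,
         alpha_band = alpha_band, beta_band = beta_band,
         erd_channels = erd_channels, ers_channels = ers_channels,
         erd_depth = erd_depth, beta_erd_depth = beta_erd_depth,
         ers_gain = ers_gain, alpha_amp = alpha_amp, beta_amp = beta_amp,
         noise_sd = noise_sd, lateralized = lateralized, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate synthetic motor-imagery EEG with ERD/ERS structure
#'
#' Each trial is the sum of narrow-band alpha and beta oscillations (filtered
#' Gaussian noise, so spectra and fractal statistics are non-degenerate),
#' with per-channel amplitudes modulated by class according to the ERD/ERS
#' layout, plus 1/f-shaped and white noise.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `epochs` (an [epoched_eeg()]) and `manifest` (ground
#'   truth: modulated channels, depths, bands).
#' @export
generate_mi_eeg <- function(cfg = synthetic_config()) {
  n <- 2L * cfg$n_trials_per_class
  Tn <- round(cfg$duration_s * cfg$fs)
  labels <- rep(c(0L, 1L), cfg$n_trials_per_class)
  data <- array(0, dim = c(n, cfg$n_channels, Tn))
  amp_mod <- function(ch, cls, depth) {
    key <- as.character(cls)
    mod <- 1
    if (!cfg$lateralized) {
      if (cls == 0L) mod <- mod * (1 - depth)
    } else {
      if (ch %in% cfg$erd_channels[[key]]) mod <- mod * (1 - depth)
      if (ch %in% cfg$ers_channels[[key]]) mod <- mod * (1 + cfg$ers_gain)
    }
    mod
  }
  with_seed(cfg$seed, {
    labels <- labels[sample.int(n)]
    for (t in seq_len(n)) {
      cls <- labels[t]
      for (ch in seq_len(cfg$n_channels)) {
        a <- cfg$alpha_amp * amp_mod(ch, cls, cfg$erd_depth) *
          narrowband_noise(Tn, cfg$fs, cfg$alpha_band)
        b <- cfg$beta_amp * amp_mod(ch, cls, cfg$beta_erd_depth) *
          narrowband_noise(Tn, cfg$fs, cfg$beta_band)
        noise <- cfg$noise_sd * (pink_noise(Tn) + 0.5 * stats::rnorm(Tn))
        data[t, ch, ] <- a + b + noise
      }
    }
  })
  names8 <- c("FC3", "C3", "CP3", "Cz", "FC4", "C4", "CP4", "Pz")
  ch_names <- if (cfg$n_channels == 8L) names8 else paste0("ch", seq_len(cfg$n_channels))
  epochs <- epoched_eeg(data, labels, cfg$fs, ch_names,
                        window = c(0.5, 0.5 + cfg$duration_s))
  manifest <- list(erd_channels = cfg$erd_channels, ers_channels = cfg$ers_channels,
                   erd_depth = cfg$erd_depth, beta_erd_depth = cfg$beta_erd_depth,
                   ers_gain = cfg$ers_gain, alpha_band = cfg$alpha_band,
                   beta_band = cfg$beta_band, lateralized = cfg$lateralized,
                   seed = cfg$seed)
  list(epochs = epochs, manifest = manifest)
}

#' Generate feature-level fixtures with per-domain planted effects
#'
#' Draws standard-normal feature blocks per domain and shifts the class
#' means of the first `n_informative` columns by the domain's effect size,
#' giving direct control of which domain carries class signal.
#'
#' @param n total number of trials (balanced labels 0/1).
#' @param per_domain_effect named numeric vector of class-mean shifts, one
#'   per domain, e.g. `c(TD = 0, FD = 0, TFD = 0, SD = 1)`.
#' @param n_features columns per domain table.
#' @param n_informative leading columns receiving the shift.
#' @param seed integer seed.
#' @return list with `tables` (named list of [domain_features()]), `labels`,
#'   and `manifest` (informative columns per domain).
#' @export
generate_feature_tables <- function(n = 100L,
                                    per_domain_effect = c(TD = 1, FD = 1, TFD = 1, SD = 1),
                                    n_features = 12L, n_informative = 3L,
                                    seed = 1L) {
  if (any(per_domain_effect < 0)) stop("effect sizes must be >= 0")
  if (n %% 2L != 0L) stop("`n` must be even for balanced classes")
  labels <- rep(c(0L, 1L), n / 2L)
  tables <- list()
  with_seed(seed, {
    labels <- labels[sample.int(n)]
    for (d in names(per_domain_effect)) {
      x <- matrix(stats::rnorm(n * n_features), n, n_features)
      eff <- per_domain_effect[[d]]
      for (j in seq_len(n_informative)) {
        x[, j] <- x[, j] + eff * (labels - 0.5)
      }
      tables[[d]] <- domain_features(x, d, paste0(tolower(d), "_f", seq_len(n_features)))
    }
  })
  list(tables = tables, labels = labels,
       manifest = list(informative = seq_len(n_informative),
                       effects = per_domain_effect, seed = seed))
}
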