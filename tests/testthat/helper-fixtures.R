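# Small in-code fixtures shared across test files.

# Epochs whose trials are plain white noise (no class structure).
noise_epochs <- function(n_trials = 10L, n_channels = 4L, n_samp = 200L,
                         fs = 100, seed = 42L) {
  set.seed(seed)
  data <- array(rnorm(n_trials * n_channels * n_samp),
                dim = c(n_trials, n_channels, n_samp))
  epoched_eeg(data, rep_len(c(0L, 1L), n_trials), fs)
}

# Two-channel epochs engineered so the class mean covariances are exactly
# diag(4,1)/5 and diag(1,4)/5 after trace normalization. Rows are zero-mean
# and orthogonal so per-filter variances stay non-degenerate.
toy_csp_epochs <- function(n_per_class = 4L) {
  mk <- function(s1, s2) {
    rbind(s1 * c(1, -1, 1, -1), s2 * c(1, 1, -1, -1))
  }
  trials <- c(replicate(n_per_class, mk(2, 1), simplify = FALSE),
              replicate(n_per_class, mk(1, 2), simplify = FALSE))
  data <- array(0, dim = c(2L * n_per_class, 2L, 4L))
  for (t in seq_along(trials)) data[t, , ] <- trials[[t]]
  epoched_eeg(data, rep(c(0L, 1L), each = n_per_class), fs = 4)
}

# Random symmetric positive-definite matrix with unit trace.
random_spd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  C <- crossprod(A) + 0.05 * diag(d)
  C / sum(diag(C))
}

# Feature table where the first 3 of 10 columns are noisy copies of the label.
planted_selection_data <- function(n = 60L, seed = 1L) {
  set.seed(seed)
  lab <- rep(c(0L, 1L), n / 2L)
  x <- matrix(rnorm(n * 10L), n, 10L)
  for (j in 1:3) x[, j] <- lab + rnorm(n, sd = 0.1)
  list(x = x, labels = lab)
}

# Composite + significant tables for stacking tests.
stacking_fixture <- function(n = 80L, effects = c(TD = 2, FD = 2, TFD = 2, SD = 2),
                             seed = 1L, K = 3L) {
  gt <- generate_feature_tables(n = n, per_domain_effect = effects, seed = seed)
  sig <- lapply(gt$tables, function(t) unclass(t)[, , drop = FALSE])
  comp <- lapply(names(sig), function(d) {
    rot <- fit_rotation(sig[[d]], K = K, labels = gt$labels, seed = seed)
    compose_features(sig[[d]], apply_rotation(rot, sig[[d]]))
  })
  names(comp) <- names(sig)
  list(comp = comp, sig = sig, labels = gt$labels)
}
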