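# Trace-normalized single-trial spatial covariance.
trial_covariance <- function(X) {
  C <- X %*% t(X)
  tr <- sum(diag(C))
  if (tr <= 0) stop("trial covariance has non-positive trace")
  C / tr
}

class_mean_covariance <- function(epochs, cls) {
  idx <- which(epochs$labels == cls)
  C <- 0
  for (t in idx) C <- C + trial_covariance(trial_matrix(epochs, t))
  C / length(idx)
}

#' Common spatial patterns from two class covariance matrices
#'
#' Whitens the composite covariance `Cc = C1 + C2` via
#' `P = Lambda^{-1/2} Uc'`, eigendecomposes `S1 = P C1 P'` and returns the
#' projection `W = B' P` with rows ordered by descending eigenvalue of `S1`.
#' Because `S1 + S2 = I` after whitening, the first rows maximize class-1
#' variance share and the last rows maximize class-2's.
#'
#' @param C1,C2 symmetric positive semi-definite class mean covariances.
#' @return list with `W` (projection matrix, rows = spatial filters) and
#'   `eigenvalues` (class-1 variance shares, descending).
#' @export
csp_from_covariances <- function(C1, C2) {
  Cc <- C1 + C2
  Cc <- (Cc + t(Cc)) / 2
  nch <- nrow(Cc)
  ec <- eigen(Cc, symmetric = TRUE)
  tol <- 1e-10 * max(ec$values)
  if (any(ec$values <= tol)) {
    warning("rank-deficient composite covariance: applying diagonal regularization")
    eps <- 1e-10 * sum(diag(Cc)) / nch
    ec <- eigen(Cc + eps * diag(nch), symmetric = TRUE)
  }
  P <- diag(1 / sqrt(ec$values), nch) %*% t(ec$vectors)
  S1 <- P %*% C1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  eb <- eigen(S1, symmetric = TRUE)
  list(W = t(eb$vectors) %*% P, eigenvalues = eb$values)
}

#' Fit a CSP spatial filter model
#'
#' @param epochs an [epoched_eeg()] object with exactly two classes, already
#'   filtered to the band of interest. Class 1 of the decomposition is the
#'   numerically smaller label.
#' @param m number of filter pairs to retain (first `m` and last `m` rows of
#'   `W`); requires `2 * m <= n_channels`.
#' @param band optional `(low_hz, high_hz)` tag recorded in the model and in
#'   feature names.
#' @return object of class `csp_model` with `W`, `eigenvalues`, `m`, `band`,
#'   `classes`, `n_channels`.
#' @export
fit_csp <- function(epochs, m = 2L, band = NULL) {
  classes <- sort(unique(epochs$labels))
  if (length(classes) != 2L) stop("CSP requires exactly two classes, got ", length(classes))
  if (2L * m > n_channels(epochs)) stop("need 2 * m <= number of channels")
  fit <- csp_from_covariances(class_mean_covariance(epochs, classes[1L]),
                              class_mean_covariance(epochs, classes[2L]))
  structure(list(W = fit$W, eigenvalues = fit$eigenvalues, m = as.integer(m),
                 band = band, classes = classes, n_channels = n_channels(epochs)),
            class = "csp_model")
}

#' Log-variance CSP features
#'
#' Projects each trial through the retained spatial filters and returns
#' `f_p = log(var(Z_p) / sum_i var(Z_i))` over the `2m` retained rows, so
#' `sum_p exp(f_p) = 1` per trial.
#'
#' @param model a [fit_csp()] model.
#' @param epochs epochs with matching channel count (filtered to the model's
#'   band).
#' @return an `"SD"` [domain_features()] table with `2m` columns.
#' @export
apply_csp <- function(model, epochs) {
  if (n_channels(epochs) != model$n_channels) {
    stop("channel count mismatch: model has ", model$n_channels,
         ", epochs have ", n_channels(epochs))
  }
  nch <- model$n_channels
  ret <- c(seq_len(model$m), (nch - model$m + 1L):nch)
  Wr <- model$W[ret, , drop = FALSE]
  out <- matrix(0, n_trials(epochs), length(ret))
  for (t in seq_len(n_trials(epochs))) {
    Z <- Wr %*% trial_matrix(epochs, t)
    v <- rowMeans((Z - rowMeans(Z))^2)
    out[t, ] <- log(v / sum(v))
  }
  prefix <- if (is.null(model$band)) "" else
    sprintf("band_%g_%g:", model$band[1L], model$band[2L])
  domain_features(out, "SD", paste0(prefix, "csp_", seq_along(ret)))
}

#' Default filter-bank sub-bands: 8--32 Hz in 4 Hz steps
#'
#' @return list of six `(low_hz, high_hz)` pairs.
#' @export
filterbank_bands <- function() {
  lapply(seq(8, 28, by = 4), function(lo) c(lo, lo + 4))
}

#' Filter-bank CSP spatial-domain features
#'
#' Band-pass filters the (broadband) epochs into each sub-band, fits one CSP
#' model per band, and concatenates the per-band log-variance features.
#'
#' @param epochs broadband [epoched_eeg()] (two classes).
#' @param bands list of `(low_hz, high_hz)` pairs; default [filterbank_bands()].
#' @param m filter pairs per band (features per band = `2m`).
#' @param filter_order Butterworth order for the per-band filters.
#' @return list with `features` (an `"SD"` table, `length(bands) * 2m`
#'   columns) and `models` (per-band `csp_model`s).
#' @export
filterbank_csp <- function(epochs, bands = filterbank_bands(), m = 2L,
                           filter_order = 5L) {
  if (!length(bands)) stop("`bands` must contain at least one band")
  models <- vector("list", length(bands))
  tabs <- vector("list", length(bands))
  for (i in seq_along(bands)) {
    cfg <- preprocess_config(band = bands[[i]], filter_order = filter_order,
                             epoch_window = epochs$window)
    filtered <- bandpass_filter(epochs, cfg = cfg)
    models[[i]] <- fit_csp(filtered, m = m, band = bands[[i]])
    tabs[[i]] <- apply_csp(models[[i]], filtered)
  }
  vals <- do.call(cbind, lapply(tabs, feature_matrix))
  nms <- unlist(lapply(tabs, colnames))
  list(features = domain_features(vals, "SD", nms), models = models)
}

#' Apply fitted filter-bank CSP models to new epochs
#'
#' @param models list of `csp_model`s from [filterbank_csp()].
#' @param epochs broadband epochs to transform.
#' @param filter_order Butterworth order (must match the fit).
#' @return an `"SD"` [domain_features()] table.
#' @export
apply_filterbank_csp <- function(models, epochs, filter_order = 5L) {
  tabs <- lapply(models, function(mod) {
    cfg <- preprocess_config(band = mod$band, filter_order = filter_order,
                             epoch_window = epochs$window)
    apply_csp(mod, bandpass_filter(epochs, cfg = cfg))
  })
  vals <- do.call(cbind, lapply(tabs, feature_matrix))
  domain_features(vals, "SD", unlist(lapply(tabs, colnames)))
}
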