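#' Full pipeline configuration
#'
#' Collects every tunable stage parameter: preprocessing band and window,
#' rhythm bands, Higuchi bound, wavelet depth, CSP pairs and filter-bank
#' layout, per-domain selection size `Na`, rotation subspace count `K` and
#' resample fraction, base classifier kind, LDA supplement switch, and the
#' stacking internals.
#'
#' @param band,filter_order,epoch_window see [preprocess_config()].
#' @param alpha,beta rhythm bands, see [band_definition()].
#' @param l_max Higuchi interval bound.
#' @param wavelet,n_levels,level_map wavelet feature settings, see
#'   [timefrequency_features()].
#' @param csp_m CSP filter pairs per sub-band.
#' @param bands filter-bank sub-bands, see [filterbank_bands()].
#' @param na significant features retained per domain (clamped to the domain
#'   width when larger); default 8 suits the 8-channel synthetic montage.
#' @param K rotation subspaces (clamped to `min(K, na)` inside the pipeline).
#' @param resample_fraction rotation PCA trial fraction.
#' @param base_kind first-layer classifier.
#' @param lda_supplement feed the pooled-significant-feature LDA coordinate
#'   to the meta-classifier.
#' @param oof_folds internal stacking folds.
#' @param hidden_units,max_epochs meta-perceptron settings.
#' @return list of class `mi_pipeline_config`.
#' @export
mi_pipeline_config <- function(band = c(8, 30), filter_order = 5L,
                               epoch_window = c(0.5, 3.5),
                               alpha = c(8, 13), beta = c(13, 30),
                               l_max = 10L, wavelet = "db4", n_levels = 4L,
                               level_map = list(alpha = 4L, beta = 3L),
                               csp_m = 2L, bands = filterbank_bands(),
                               na = 8L, K = 7L, resample_fraction = 0.75,
                               base_kind = "random_forest",
                               lda_supplement = TRUE, oof_folds = 5L,
                               hidden_units = 100L, max_epochs = 200L) {
  structure(list(
    preprocess = preprocess_config(band, filter_order, epoch_window),
    bands_def = band_definition(alpha, beta),
    l_max = as.integer(l_max), wavelet = wavelet,
    n_levels = as.integer(n_levels), level_map = level_map,
    csp_m = as.integer(csp_m), bands = bands,
    na = as.integer(na), K = as.integer(K),
    resample_fraction = resample_fraction, base_kind = base_kind,
    lda_supplement = lda_supplement, oof_folds = as.integer(oof_folds),
    hidden_units = as.integer(hidden_units), max_epochs = as.integer(max_epochs)
  ), class = "mi_pipeline_config")
}

#' Extract the label-free feature ingredients once per dataset
#'
#' TD/FD/TFD tables and the per-sub-band filtered epochs are deterministic
#' per-trial functions that use no labels, so they can be shared across
#' cross-validation folds without leakage; only the supervised stages (CSP,
#' selection, rotation, LDA, classifiers) are refit per fold.
#'
#' @param epochs an [epoched_eeg()] object (broadband or 8--30 Hz filtered).
#' @param config an [mi_pipeline_config()].
#' @return list with `td`, `fd`, `tfd` tables and `banded` (filtered epochs
#'   per filter-bank sub-band).
#' @export
extract_domain_features <- function(epochs, config = mi_pipeline_config()) {
  banded <- lapply(config$bands, function(b) {
    cfg <- preprocess_config(band = b, filter_order = config$preprocess$filter_order,
                             epoch_window = epochs$window)
    bandpass_filter(epochs, cfg = cfg)
  })
  list(
    td = time_domain_features(epochs, config$l_max),
    fd = frequency_domain_features(epochs, config$bands_def),
    tfd = timefrequency_features(epochs, config$wavelet, config$n_levels,
                                 config$level_map),
    banded = banded
  )
}

# SD features for a trial subset: CSP fitted on the (training) subset of each
# pre-filtered band, applied to the requested indices.
fit_sd_models <- function(pre, config, train_idx) {
  lapply(seq_along(pre$banded), function(i) {
    fit_csp(subset_epochs(pre$banded[[i]], train_idx), m = config$csp_m,
            band = config$bands[[i]])
  })
}

sd_features <- function(pre, models, idx) {
  tabs <- lapply(seq_along(models), function(i) {
    apply_csp(models[[i]], subset_epochs(pre$banded[[i]], idx))
  })
  vals <- do.call(cbind, lapply(tabs, feature_matrix))
  domain_features(vals, "SD", unlist(lapply(tabs, colnames)))
}

#' Fit the full decoding pipeline
#'
#' Runs, on the training trials only: filter-bank CSP, per-domain RFE-RF
#' selection to `Na` features, local rotation + composite fusion, and the
#' stacking ensemble with LDA-supplemented meta-features.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param config an [mi_pipeline_config()].
#' @param seed integer master seed for all stochastic stages.
#' @param train_idx trial indices to train on (default: all).
#' @param pre optional precomputed [extract_domain_features()] result.
#' @return object of class `mi_pipeline_model`.
#' @export
fit_mi_pipeline <- function(epochs, config = mi_pipeline_config(), seed = 1L,
                            train_idx = NULL, pre = NULL) {
  pre <- pre %||% extract_domain_features(epochs, config)
  train_idx <- train_idx %||% seq_len(n_trials(epochs))
  labels_tr <- epochs$labels[train_idx]
  csp_models <- fit_sd_models(pre, config, train_idx)
  tables <- list(
    TD = feature_matrix(pre$td)[train_idx, , drop = FALSE],
    FD = feature_matrix(pre$fd)[train_idx, , drop = FALSE],
    TFD = feature_matrix(pre$tfd)[train_idx, , drop = FALSE],
    SD = feature_matrix(sd_features(pre, csp_models, train_idx))
  )
  selections <- list(); rotations <- list()
  sig_tables <- list(); comp_tables <- list()
  for (d in names(tables)) {
    na_d <- min(config$na, ncol(tables[[d]]))
    sel <- rfe_rf(tables[[d]], labels_tr, na_d, seed = seed + match(d, names(tables)))
    sig <- tables[[d]][, sel$selected_indices, drop = FALSE]
    rot <- fit_rotation(sig, K = min(config$K, na_d),
                        resample_fraction = config$resample_fraction,
                        labels = labels_tr,
                        seed = seed + 10L * match(d, names(tables)))
    selections[[d]] <- sel
    rotations[[d]] <- rot
    sig_tables[[d]] <- sig
    comp_tables[[d]] <- compose_features(sig, apply_rotation(rot, sig))
  }
  stacked <- fit_stacking(comp_tables, sig_tables, labels_tr,
                          base_kind = config$base_kind,
                          oof_folds = config$oof_folds,
                          lda_supplement = config$lda_supplement,
                          hidden_units = config$hidden_units,
                          max_epochs = config$max_epochs,
                          seed = seed + 97L)
  structure(list(config = config, csp_models = csp_models,
                 selections = selections, rotations = rotations,
                 stacked = stacked, seed = as.integer(seed)),
            class = "mi_pipeline_model")
}

#' Predict with a fitted pipeline
#'
#' @param model an [fit_mi_pipeline()] model.
#' @param epochs epochs to classify.
#' @param idx trial indices to classify (default: all).
#' @param pre optional precomputed [extract_domain_features()] result for
#'   `epochs`.
#' @return list with `labels` and `prob` as in [predict_stacking()].
#' @export
predict_mi_pipeline <- function(model, epochs, idx = NULL, pre = NULL) {
  pre <- pre %||% extract_domain_features(epochs, model$config)
  idx <- idx %||% seq_len(n_trials(epochs))
  tables <- list(
    TD = feature_matrix(pre$td)[idx, , drop = FALSE],
    FD = feature_matrix(pre$fd)[idx, , drop = FALSE],
    TFD = feature_matrix(pre$tfd)[idx, , drop = FALSE],
    SD = feature_matrix(sd_features(pre, model$csp_models, idx))
  )
  sig_tables <- list(); comp_tables <- list()
  for (d in names(tables)) {
    sig <- tables[[d]][, model$selections[[d]]$selected_indices, drop = FALSE]
    sig_tables[[d]] <- sig
    comp_tables[[d]] <- compose_features(sig, apply_rotation(model$rotations[[d]], sig))
  }
  predict_stacking(model$stacked, comp_tables, sig_tables)
}
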