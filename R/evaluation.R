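#' Binary confusion counts
#'
#' @param true,pred label vectors of equal length.
#' @param positive the label treated as the positive class; defaults to the
#'   numerically larger label (precision/recall depend on this choice).
#' @return list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN` and
#'   the `positive` label.
#' @export
confusion_counts <- function(true, pred, positive = NULL) {
  if (length(true) != length(pred)) stop("`true` and `pred` must have equal length")
  if (!length(true)) stop("no predictions to evaluate")
  positive <- positive %||% max(true)
  tp <- sum(pred == positive & true == positive)
  fp <- sum(pred == positive & true != positive)
  tn <- sum(pred != positive & true != positive)
  fn <- sum(pred != positive & true == positive)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, positive = positive),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2 * Prec * Rec / (Prec + Rec)`. A metric whose denominator is zero
#' is reported as 0 with a warning.
#'
#' @param counts a [confusion_counts()] object (or list with TP/FP/TN/FN).
#' @return named numeric vector `c(Acc, Prec, Rec, F1)`.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, FP, TN, FN) < 0)) stop("confusion counts must be non-negative")
    n <- TP + FP + TN + FN
    if (n == 0) stop("no predictions to evaluate")
    safe_div <- function(num, den, what) {
      if (den == 0) {
        warning(what, " undefined (zero denominator): reporting 0")
        0
      } else num / den
    }
    prec <- safe_div(TP, TP + FP, "precision")
    rec <- safe_div(TP, TP + FN, "recall")
    f1 <- safe_div(2 * prec * rec, prec + rec, "F1")
    c(Acc = (TP + TN) / n, Prec = prec, Rec = rec, F1 = f1)
  })
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' For each repeat, trials are split into stratified folds; every supervised
#' stage (CSP, selection, rotation, LDA, base and meta classifiers) is refit
#' on the training folds only, and metrics are computed on the held-out
#' fold. The label-free feature ingredients are computed once and shared.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param config an [mi_pipeline_config()].
#' @param n_folds folds per repeat (train:test 4:1 at the default 5).
#' @param n_repeats independent reshuffles.
#' @param seed integer master seed.
#' @param pre optional [extract_domain_features()] result for `epochs`;
#'   these ingredients are label-free, so reusing them (e.g. across label
#'   permutations) cannot leak.
#' @return object of class `cv_report`: `results` (one row per repeat x
#'   fold with Acc/Prec/Rec/F1), `mean`, `sd`, `config`, `seed`.
#' @export
cross_validate <- function(epochs, config = mi_pipeline_config(),
                           n_folds = 5L, n_repeats = 5L, seed = 1L,
                           pre = NULL) {
  pre <- pre %||% extract_domain_features(epochs, config)
  rows <- list()
  for (r in seq_len(n_repeats)) {
    folds <- make_stratified_folds(epochs$labels, n_folds, seed = seed + 1000L * r)
    for (f in seq_len(n_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      model <- fit_mi_pipeline(epochs, config,
                               seed = seed + 1000L * r + 10L * f,
                               train_idx = tr, pre = pre)
      pred <- predict_mi_pipeline(model, epochs, idx = te, pre = pre)
      m <- suppressWarnings(compute_metrics(confusion_counts(epochs$labels[te],
                                                             pred$labels)))
      rows[[length(rows) + 1L]] <- data.frame(repeat_ = r, fold = f, t(m))
    }
  }
  results <- do.call(rbind, rows)
  metrics <- c("Acc", "Prec", "Rec", "F1")
  structure(list(results = results,
                 mean = colMeans(results[metrics]),
                 sd = apply(results[metrics], 2L, stats::sd),
                 n_folds = n_folds, n_repeats = n_repeats,
                 config = config, seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation (seed %d)\n",
              x$n_repeats, x$n_folds, x$seed))
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  invisible(x)
}

#' Accuracy as a function of the number of selected features
#'
#' Reruns [cross_validate()] for each `Na` in the grid and reports the mean
#' accuracy, tracing the rise-then-plateau behaviour of backward feature
#' selection.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param config base [mi_pipeline_config()]; its `na` is overridden.
#' @param na_grid integer vector of feature counts (non-empty).
#' @param n_folds,n_repeats,seed passed to [cross_validate()].
#' @return data frame with columns `na` and `mean_acc`.
#' @export
feature_count_sweep <- function(epochs, config = mi_pipeline_config(), na_grid,
                                n_folds = 5L, n_repeats = 1L, seed = 1L) {
  if (!length(na_grid)) stop("`na_grid` must be non-empty")
  pre <- extract_domain_features(epochs, config)
  acc <- vapply(na_grid, function(na) {
    cfg <- config
    cfg$na <- as.integer(na)
    cross_validate(epochs, cfg, n_folds, n_repeats, seed, pre = pre)$mean[["Acc"]]
  }, 0)
  data.frame(na = as.integer(na_grid), mean_acc = acc)
}
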