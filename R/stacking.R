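# ---- base classifiers --------------------------------------------------

fit_base <- function(x, y, kind) {
  x <- as.matrix(x)
  switch(kind,
    random_forest = list(kind = kind,
                         fit = randomForest::randomForest(x, y, ntree = 100L)),
    svm_rbf = {
      std <- fit_standardizer(x)
      xs <- apply_standardizer(std, x)
      list(kind = kind, std = std,
           fit = e1071::svm(xs, y, kernel = "radial", cost = 1,
                            gamma = 1 / ncol(xs), probability = TRUE))
    },
    svm_linear = {
      std <- fit_standardizer(x)
      xs <- apply_standardizer(std, x)
      list(kind = kind, std = std,
           fit = e1071::svm(xs, y, kernel = "linear", cost = 1,
                            probability = TRUE))
    },
    stop("unknown base classifier kind: ", kind)
  )
}

predict_base_prob <- function(model, x, levels) {
  x <- as.matrix(x)
  if (model$kind == "random_forest") {
    p <- stats::predict(model$fit, x, type = "prob")
  } else {
    xs <- apply_standardizer(model$std, x)
    pr <- stats::predict(model$fit, xs, probability = TRUE)
    p <- attr(pr, "probabilities")
  }
  p <- p[, levels, drop = FALSE]      # enforce ascending class order
  p / rowSums(p)
}

# ---- LDA supplementary features ----------------------------------------

#' Fisher linear discriminant features
#'
#' Projects the pooled significant features onto the `C - 1` directions
#' maximizing between-class over within-class scatter. For the binary case
#' the direction is the closed form `Sw^{-1} (mu_2 - mu_1)` (classes in
#' ascending label order), so swapping the two labels negates the
#' projection. When the within-class scatter is (near) singular it is shrunk
#' toward its average diagonal before inversion.
#'
#' @param x numeric matrix `[n x p]` of features.
#' @param labels class labels; exactly two classes are supported.
#' @return list of class `lda_projector`: `w` (`p x 1` unit-norm direction),
#'   `center` (feature means), `levels`, and `projected` (`n x 1` training
#'   projection).
#' @export
lda_features <- function(x, labels) {
  x <- as.matrix(x)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("LDA supplementary features support exactly two classes")
  lv <- levels(y)
  mu1 <- colMeans(x[y == lv[1L], , drop = FALSE])
  mu2 <- colMeans(x[y == lv[2L], , drop = FALSE])
  xc <- x
  xc[y == lv[1L], ] <- sweep(x[y == lv[1L], , drop = FALSE], 2L, mu1)
  xc[y == lv[2L], ] <- sweep(x[y == lv[2L], , drop = FALSE], 2L, mu2)
  Sw <- crossprod(xc) / max(1L, nrow(x) - 2L)
  if (nrow(x) <= ncol(x) || rcond(Sw) < 1e-10) {
    warning("within-class scatter is ill-conditioned: applying shrinkage")
    gamma <- 0.1
    Sw <- (1 - gamma) * Sw + gamma * mean(diag(Sw)) * diag(ncol(x))
  }
  w <- solve(Sw, mu2 - mu1)
  w <- w / sqrt(sum(w^2))
  center <- colMeans(x)
  proj <- structure(list(w = matrix(w, ncol = 1L), center = center, levels = lv),
                    class = "lda_projector")
  proj$projected <- project_lda(proj, x)
  proj
}

#' Project features through a fitted LDA direction
#'
#' @param proj an [lda_features()] projector.
#' @param x matrix with matching column count.
#' @return `n x (C - 1)` matrix of discriminant coordinates.
#' @export
project_lda <- function(proj, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(proj$center)) stop("feature width mismatch in LDA projection")
  sweep(x, 2L, proj$center) %*% proj$w
}

# ---- stacking ----------------------------------------------------------

meta_input <- function(prob_blocks, lda_proj) {
  m <- do.call(cbind, prob_blocks)
  if (!is.null(lda_proj)) m <- cbind(m, lda_proj)
  m
}

#' Fit the two-layer stacking ensemble
#'
#' First layer: one base classifier per feature domain, trained on that
#' domain's composite features. Meta-training probabilities are produced
#' out-of-fold (stratified internal split) so the meta-classifier never sees
#' in-sample base predictions; the base models are then refit on all data.
#' Second layer: a single-hidden-layer perceptron trained on the
#' concatenated per-domain probability vectors, optionally supplemented by
#' the LDA projection of the pooled significant features.
#'
#' @param composite_tables named list (domain -> composite feature matrix).
#' @param significant_tables named list (domain -> significant feature
#'   matrix), same domain order; used for the LDA supplement.
#' @param labels class labels shared by all tables (binary).
#' @param base_kind `"random_forest"`, `"svm_rbf"` or `"svm_linear"`.
#' @param oof_folds internal folds for out-of-fold meta-training
#'   probabilities.
#' @param lda_supplement add the LDA discriminant coordinate to the meta
#'   input (TRUE) or train on probabilities alone (FALSE).
#' @param hidden_units hidden layer width of the perceptron meta-classifier.
#' @param max_epochs optimizer iteration cap for the meta-classifier.
#' @param seed integer seed covering folds, base fits and meta
#'   initialization.
#' @return object of class `stacked_model`.
#' @export
fit_stacking <- function(composite_tables, significant_tables, labels,
                         base_kind = c("random_forest", "svm_rbf", "svm_linear"),
                         oof_folds = 5L, lda_supplement = TRUE,
                         hidden_units = 100L, max_epochs = 200L, seed = 1L) {
  base_kind <- match.arg(base_kind)
  domains <- names(composite_tables)
  if (is.null(domains) || any(!nzchar(domains))) stop("`composite_tables` must be a named list")
  if (!setequal(domains, names(significant_tables))) {
    stop("composite and significant tables must cover the same domains")
  }
  significant_tables <- significant_tables[domains]
  n <- length(labels)
  if (any(vapply(composite_tables, nrow, 0L) != n)) {
    stop("all composite tables must have one row per trial")
  }
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("labels contain a single class")
  lv <- levels(y)
  C <- nlevels(y)
  with_seed(seed, {
    folds <- make_stratified_folds(labels, oof_folds,
                                   seed = sample.int(.Machine$integer.max, 1L))
    oof <- lapply(domains, function(d) matrix(0, n, C))
    names(oof) <- domains
    for (f in seq_len(oof_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      for (d in domains) {
        bm <- fit_base(composite_tables[[d]][tr, , drop = FALSE], y[tr], base_kind)
        oof[[d]][te, ] <- predict_base_prob(bm, composite_tables[[d]][te, , drop = FALSE], lv)
      }
    }
    lda <- NULL
    if (lda_supplement) {
      lda <- lda_features(do.call(cbind, significant_tables), labels)
    }
    mx <- meta_input(oof, if (is.null(lda)) NULL else lda$projected)
    std <- fit_standardizer(mx)
    mxs <- apply_standardizer(std, mx)
    meta <- nnet::nnet(mxs, nnet::class.ind(y), size = hidden_units,
                       softmax = TRUE, maxit = max_epochs, decay = 1e-4,
                       trace = FALSE, MaxNWts = 100000L)
    base_models <- lapply(domains, function(d) {
      fit_base(composite_tables[[d]], y, base_kind)
    })
    names(base_models) <- domains
    structure(list(base_models = base_models, base_kind = base_kind,
                   lda_projector = lda, meta_model = meta, meta_std = std,
                   domains = domains, levels = lv, n_classes = C,
                   oof_folds = as.integer(oof_folds),
                   lda_supplement = lda_supplement, seed = as.integer(seed)),
              class = "stacked_model")
  })
}

#' Predict with a fitted stacking ensemble
#'
#' @param model a [fit_stacking()] model.
#' @param composite_tables named list of composite feature matrices
#'   (same domains and widths as at fit time).
#' @param significant_tables named list of significant feature matrices
#'   (needed when the model carries an LDA supplement).
#' @return list with `labels` (argmax class, ties toward the lower class
#'   index) and `prob` (`n x C` matrix, rows summing to 1).
#' @export
predict_stacking <- function(model, composite_tables, significant_tables = NULL) {
  probs <- lapply(model$domains, function(d) {
    tab <- composite_tables[[d]]
    if (is.null(tab)) stop("missing composite table for domain ", d)
    predict_base_prob(model$base_models[[d]], tab, model$levels)
  })
  names(probs) <- model$domains
  lda_proj <- NULL
  if (!is.null(model$lda_projector)) {
    if (is.null(significant_tables)) stop("significant tables required for the LDA supplement")
    sig <- do.call(cbind, significant_tables[model$domains])
    lda_proj <- project_lda(model$lda_projector, sig)
  }
  mxs <- apply_standardizer(model$meta_std, meta_input(probs, lda_proj))
  p <- stats::predict(model$meta_model, mxs)
  p <- p / rowSums(p)
  colnames(p) <- model$levels
  idx <- max.col(p, ties.method = "first")
  lab <- as.integer(model$levels[idx])
  list(labels = lab, prob = p)
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("Stacked ensemble: %s base classifiers over {%s}%s; meta = %d-unit MLP\n",
              x$base_kind, paste(x$domains, collapse = ", "),
              if (x$lda_supplement) " + LDA supplement" else "",
              x$meta_model$n[2L]))
  invisible(x)
}

#' Per-domain contribution rates from the meta-classifier weights
#'
#' For each meta input `i`, the importance is
#' `sum_h |W_in[i, h]| * sum_o |W_out[h, o]|` over the perceptron's hidden
#' units. A domain's contribution is the summed importance of its class
#' probability inputs, normalized over the four domains to percentages. The
#' LDA supplement's share of the total weight mass is excluded from that
#' normalization and reported separately (attribute `lda_share`).
#'
#' @param model a [fit_stacking()] model with a single-hidden-layer
#'   perceptron meta-classifier.
#' @return named numeric vector of domain percentages summing to 100, with
#'   attribute `lda_share` (percent of total importance on the LDA input).
#' @export
contribution_rates <- function(model) {
  meta <- model$meta_model
  if (!inherits(meta, "nnet") || length(meta$n) != 3L) {
    stop("contribution rates require a one-hidden-layer perceptron meta-classifier")
  }
  p <- meta$n[1L]; H <- meta$n[2L]; C_out <- meta$n[3L]
  wts <- meta$wts
  W_in <- matrix(0, p, H)
  for (h in seq_len(H)) {
    off <- (h - 1L) * (p + 1L)
    W_in[, h] <- wts[(off + 2L):(off + p + 1L)]   # skip bias
  }
  W_out <- matrix(0, H, C_out)
  base_off <- H * (p + 1L)
  for (o in seq_len(C_out)) {
    off <- base_off + (o - 1L) * (H + 1L)
    W_out[, o] <- wts[(off + 2L):(off + H + 1L)]
  }
  s_h <- rowSums(abs(W_out))
  imp <- as.numeric(abs(W_in) %*% s_h)
  C <- model$n_classes
  dom_imp <- vapply(seq_along(model$domains), function(d) {
    sum(imp[((d - 1L) * C + 1L):(d * C)])
  }, 0)
  names(dom_imp) <- model$domains
  out <- 100 * dom_imp / sum(dom_imp)
  lda_share <- if (p > length(model$domains) * C) {
    100 * sum(imp[(length(model$domains) * C + 1L):p]) / sum(imp)
  } else NA_real_
  attr(out, "lda_share") <- lda_share
  out
}
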