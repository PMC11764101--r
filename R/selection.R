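#' Recursive feature elimination with random-forest importance
#'
#' Backward selection: fit a random forest, rank features by mean impurity
#' decrease, drop the single least-important feature, and refit until
#' `target_count` features remain. Ties in importance are broken toward the
#' lower column index for determinism.
#'
#' @param features a [domain_features()] table or plain numeric matrix.
#' @param labels class labels (two or more classes, at least two trials per
#'   class).
#' @param target_count number of features to retain (`Na`).
#' @param num_trees forest size per iteration.
#' @param seed integer seed; the full elimination path is reproducible.
#' @return object of class `selection_result`: `selected_indices` (ascending
#'   column indices into the input), `target_count`, and `elimination_trace`
#'   (data frame of `removed_index`, `importance` in removal order).
#' @export
rfe_rf <- function(features, labels, target_count, num_trees = 100L, seed = 1L) {
  x <- as.matrix(features)
  p <- ncol(x)
  if (target_count > p) {
    stop("`target_count` (", target_count, ") exceeds the number of features (", p, ")")
  }
  if (target_count < 1L) stop("`target_count` must be >= 1")
  y <- factor(labels)
  if (any(table(y) < 2L)) stop("need at least two trials per class")
  cols <- seq_len(p)
  removed <- integer(0)
  removed_imp <- numeric(0)
  with_seed(seed, {
    while (length(cols) > target_count) {
      rf <- randomForest::randomForest(x[, cols, drop = FALSE], y,
                                       ntree = num_trees)
      imp <- rf$importance[, "MeanDecreaseGini"]
      worst <- which.min(imp)            # ties -> lowest index
      removed <- c(removed, cols[worst])
      removed_imp <- c(removed_imp, unname(imp[worst]))
      cols <- cols[-worst]
    }
  })
  structure(
    list(selected_indices = cols, target_count = as.integer(target_count),
         elimination_trace = data.frame(removed_index = removed,
                                        importance = removed_imp)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("RFE-RF selection: kept %d features after %d eliminations\n",
              length(x$selected_indices), nrow(x$elimination_trace)))
  invisible(x)
}
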