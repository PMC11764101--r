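#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded fits never perturb user code.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that every class is spread
#' as evenly as possible across folds.
#'
#' @param labels class label per observation.
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:k`, one per observation.
#' @export
make_stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.vector(labels)
  n <- length(labels)
  if (any(table(labels) < k)) {
    stop("each class needs at least ", k, " observations for ", k, "-fold splitting")
  }
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Column standardizer used in front of scale-sensitive learners (SVM, MLP).
fit_standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, x) {
  scale(x, center = std$center, scale = std$scale)[, , drop = FALSE]
}

assert_finite_matrix <- function(x, what = "matrix") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
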