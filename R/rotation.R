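# Class-stratified subsample of ceil(frac * n_c) rows per class, without
# replacement; plain subsample when labels are absent.
stratified_rows <- function(n, frac, labels = NULL) {
  if (is.null(labels)) return(sort(sample.int(n, ceiling(frac * n))))
  rows <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    rows <- c(rows, idx[sample.int(length(idx), ceiling(frac * length(idx)))])
  }
  sort(rows)
}

# Orthonormal completion: extend the columns of O to a full basis of R^M.
complete_basis <- function(O, M) {
  if (ncol(O) >= M) return(O[, seq_len(M), drop = FALSE])
  q <- qr.Q(qr(cbind(O, diag(M))))[, seq_len(M), drop = FALSE]
  q[, seq_len(ncol(O))] <- O
  # re-orthogonalize remaining columns against O
  qr.Q(qr(q))[, seq_len(M), drop = FALSE]
}

# Deterministic PCA sign: largest-magnitude loading of each component positive.
fix_signs <- function(O) {
  for (j in seq_len(ncol(O))) {
    i <- which.max(abs(O[, j]))
    if (O[i, j] < 0) O[, j] <- -O[, j]
  }
  O
}

#' Fit a local rotation transformation
#'
#' Randomly partitions the feature space into `K` disjoint subspaces, draws a
#' 75% (class-stratified) trial subsample per subspace, runs PCA on the
#' subsample's columns keeping all components, and assembles the per-block
#' coefficient matrices into one orthogonal rotation matrix aligned with the
#' original column order. When `Na` is not divisible by `K`, the remainder is
#' spread one feature per block over the first blocks.
#'
#' @param significant numeric matrix `[n x Na]` of selected features.
#' @param K number of subspaces (`K <= Na`).
#' @param resample_fraction fraction of trials entering each block's PCA.
#' @param labels optional class labels enabling stratified resampling.
#' @param seed integer seed; partition, subsamples and the assembled matrix
#'   are reproducible.
#' @return object of class `rotation_transform`: `subspace_assignment`
#'   (list of column-index blocks), `block_coefficients` (per-block
#'   orthonormal matrices), `R` (the assembled `Na x Na` orthogonal matrix in
#'   original column order), `K`, `seed`.
#' @export
fit_rotation <- function(significant, K, resample_fraction = 0.75,
                         labels = NULL, seed = 1L) {
  x <- as.matrix(significant)
  Na <- ncol(x)
  n <- nrow(x)
  if (K > Na) stop("`K` (", K, ") must not exceed the number of features (", Na, ")")
  if (K < 1L) stop("`K` must be >= 1")
  with_seed(seed, {
    perm <- sample.int(Na)
    sizes <- rep(Na %/% K, K)
    r <- Na %% K
    if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
    blocks <- split(perm, rep(seq_len(K), times = sizes))
    coeffs <- vector("list", K)
    R <- matrix(0, Na, Na)
    for (j in seq_len(K)) {
      bidx <- blocks[[j]]
      M <- length(bidx)
      rows <- stratified_rows(n, resample_fraction, labels)
      V <- x[rows, bidx, drop = FALSE]
      if (all(apply(V, 2L, stats::sd) < 1e-12)) {
        warning("zero-variance subspace (block ", j, "): using identity coefficients")
        O <- diag(M)
      } else {
        pc <- stats::prcomp(V, center = TRUE, scale. = FALSE)
        O <- complete_basis(pc$rotation, M)
        O <- fix_signs(O)
      }
      coeffs[[j]] <- O
      R[bidx, bidx] <- O
    }
    structure(list(subspace_assignment = blocks, block_coefficients = coeffs,
                   R = R, K = as.integer(K),
                   resample_fraction = resample_fraction, seed = as.integer(seed)),
              class = "rotation_transform")
  })
}

#' Apply a fitted rotation to a feature matrix
#'
#' `F_rotated = F %*% R`; the transform fitted on training data is reused
#' unchanged on test data.
#'
#' @param tr a [fit_rotation()] transform.
#' @param significant numeric matrix with the same column count as at fit
#'   time.
#' @return rotated matrix of identical dimensions.
#' @export
apply_rotation <- function(tr, significant) {
  x <- as.matrix(significant)
  if (ncol(x) != ncol(tr$R)) {
    stop("feature count mismatch: transform expects ", ncol(tr$R),
         " columns, got ", ncol(x))
  }
  out <- x %*% tr$R
  colnames(out) <- paste0("rot_", seq_len(ncol(out)))
  out
}

#' Compose rotated and significant features
#'
#' Column-wise concatenation `[F_rotated | F_rfe]` with per-column origin
#' tags; the extended space feeds the per-domain base classifiers.
#'
#' @param significant matrix of selected (significant) features.
#' @param rotated matrix from [apply_rotation()], same row count.
#' @return matrix of class `composite_features` with an `origin` attribute
#'   (`"rotated"` / `"significant"` per column).
#' @export
compose_features <- function(significant, rotated) {
  significant <- as.matrix(significant)
  rotated <- as.matrix(rotated)
  if (nrow(significant) != nrow(rotated)) {
    stop("row count mismatch between significant and rotated features")
  }
  if (is.null(colnames(significant))) {
    colnames(significant) <- paste0("sig_", seq_len(ncol(significant)))
  }
  out <- cbind(rotated, significant)
  structure(out,
            origin = c(rep("rotated", ncol(rotated)),
                       rep("significant", ncol(significant))),
            class = c("composite_features", "matrix", "array"))
}
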