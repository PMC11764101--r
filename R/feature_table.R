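#' Per-trial feature table tagged with its domain
#'
#' @param values numeric matrix `[n_trials x n_features]`.
#' @param domain one of `"TD"`, `"FD"`, `"TFD"`, `"SD"`.
#' @param feature_names unique character names, one per column.
#' @return matrix of class `domain_features` with a `domain` attribute.
#' @export
domain_features <- function(values, domain, feature_names = colnames(values)) {
  domain <- match.arg(domain, c("TD", "FD", "TFD", "SD"))
  values <- as.matrix(values)
  if (is.null(feature_names)) stop("feature names are required")
  if (length(feature_names) != ncol(values)) stop("one feature name per column required")
  if (anyDuplicated(feature_names)) stop("feature names must be unique within a table")
  assert_finite_matrix(values, paste0(domain, " feature table"))
  colnames(values) <- feature_names
  structure(values, domain = domain, class = c("domain_features", "matrix", "array"))
}

#' @export
print.domain_features <- function(x, ...) {
  cat(sprintf("%s feature table: %d trials x %d features\n",
              attr(x, "domain"), nrow(x), ncol(x)))
  invisible(x)
}

# Strip the class so matrix algebra stays plain.
feature_matrix <- function(ft) {
  m <- unclass(ft)
  attr(m, "domain") <- NULL
  m
}

#' Export / import a feature table as delimited text with a JSON sidecar
#'
#' The values go to a TSV (header = feature names); domain tag and optional
#' labels go to `<path>.json`.
#'
#' @param ft a [domain_features()] table.
#' @param path TSV path.
#' @param labels optional per-trial labels stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, labels = NULL) {
  utils::write.table(feature_matrix(ft), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- list(domain = attr(ft, "domain"), feature_names = colnames(ft))
  if (!is.null(labels)) side$labels <- as.integer(labels)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @return `read_feature_table` returns a list with elements `table` and
#'   `labels` (NULL when absent from the sidecar).
#' @export
read_feature_table <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                        check.names = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(table = domain_features(values, side$domain, side$feature_names),
       labels = side$labels)
}
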