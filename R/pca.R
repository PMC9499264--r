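#' Principal component analysis of a treatment x parameter matrix
#'
#' Column-centered (and, by default, unit-scaled) singular value
#' decomposition. Standardization is the default because trial parameters
#' mix incommensurate units (cm, g, percent, SPAD units); it makes the
#' analysis a correlation-matrix PCA. Component signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param x Numeric matrix or data frame, observations in rows (at least
#'   2 x 2, no missing values).
#' @param standardize Scale columns to unit variance (default `TRUE`).
#' @param center Center columns (default `TRUE`).
#' @return A `pca_result`: `scores` (observation x component), `loadings`
#'   (variable x component), `sdev`, and `var_explained` (non-increasing
#'   fractions summing to 1).
#' @export
pca <- function(x, standardize = TRUE, center = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least 2 observations and 2 variables")
  if (anyNA(x)) stop("x contains missing values; impute or drop before PCA")
  if (standardize) {
    sdv <- apply(x, 2L, stats::sd)
    if (any(sdv == 0)) {
      stop("zero-variance column(s) cannot be standardized: ",
           paste(colnames(x)[sdv == 0], collapse = ", "))
    }
  }
  p <- stats::prcomp(x, center = center, scale. = standardize)
  for (k in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, k]))
    if (p$rotation[j, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation, sdev = p$sdev,
                 var_explained = ve),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result: ", nrow(x$scores), " observations, ",
      length(x$var_explained), " components\n", sep = "")
  pct <- round(100 * x$var_explained, 2)
  cat("variance explained (%): ", paste(pct, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write PCA results as TSV files
#'
#' @param x A `pca_result`.
#' @param dir Output directory; writes `pca_scores.tsv`,
#'   `pca_loadings.tsv` and `pca_variance.tsv`.
#' @param prefix Filename prefix (default `"pca"`).
#' @export
write_pca <- function(x, dir, prefix = "pca") {
  w <- function(m, name) {
    df <- data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(prefix, "_", name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  w(x$scores, "scores")
  w(x$loadings, "loadings")
  ve <- data.frame(component = paste0("PC", seq_along(x$var_explained)),
                   sdev = x$sdev, var_explained = x$var_explained)
  utils::write.table(ve, file.path(dir, paste0(prefix, "_variance.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
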