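# Dimensionality reduction: PCA on the z-scored fight-metric matrix and
# classical scaling (PCoA) on DTW dissimilarity matrices. The first three
# dimensions are retained for downstream clustering and regression.

new_ordination <- function(ids, scores, eigenvalues, var_explained, method,
                           loadings = NULL) {
  k <- min(3L, ncol(scores))
  scores <- scores[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("Dim", seq_len(k))
  rownames(scores) <- ids
  structure(list(ids = ids, scores = scores, eigenvalues = eigenvalues,
                 var_explained = var_explained,
                 cumulative_variance_dim1_3 = sum(var_explained[seq_len(k)]),
                 method = method, loadings = loadings),
            class = "fight_ordination")
}

#' @export
print.fight_ordination <- function(x, ...) {
  cat(sprintf("<fight_ordination> %s, %d fish, %d dims retained\n",
              toupper(x$method), length(x$ids), ncol(x$scores)))
  cat(sprintf("  variance explained: %s (Dim1-3 cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$var_explained[
                seq_len(min(3, length(x$var_explained)))]), collapse = ", "),
              100 * x$cumulative_variance_dim1_3))
  invisible(x)
}

# Flip component signs so the largest-magnitude loading (or coordinate) of
# each axis is positive; makes results reproducible across BLAS libraries.
fix_signs <- function(vectors, scores) {
  for (k in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, k]))
    if (vectors[i, k] < 0) {
      vectors[, k] <- -vectors[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(vectors = vectors, scores = scores)
}

#' Principal component analysis of the fight-metric matrix
#'
#' Eigendecomposition of the sample covariance of the z-scored metrics
#' (equivalently, correlation-matrix PCA). Scores are the projections of the
#' fish onto the eigenvectors; the first three components are retained.
#' Component signs follow the convention that the largest-magnitude loading
#' of each component is positive.
#'
#' @param x A [metrics_matrix()] result or a z-scored numeric matrix
#'   (fish x metric) with row names.
#' @return A `fight_ordination` (method `"pca"`).
#' @export
pca_ordination <- function(x) {
  z <- if (inherits(x, "fight_metrics_matrix")) x$z else as.matrix(x)
  n <- nrow(z)
  if (n < 3L) abort_fd("PCA needs at least 3 fish", "fd_size_error")
  if (any(apply(z, 2, stats::sd) == 0)) {
    abort_fd("degenerate (constant) metric column", "fd_degenerate_error")
  }
  eg <- eigen(stats::cov(z), symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  scores <- z %*% eg$vectors
  fx <- fix_signs(eg$vectors, scores)
  rownames(fx$vectors) <- colnames(z)
  new_ordination(rownames(z), fx$scores, vals, vals / sum(vals), "pca",
                 loadings = fx$vectors)
}

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical metric scaling: the squared dissimilarities are double-centered
#' (\eqn{B = -\tfrac12 J D^2 J}) and eigendecomposed; coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues.
#' DTW dissimilarities are generally non-Euclidean, so negative eigenvalues
#' can occur; they are dropped without correction, and variance fractions
#' use the sum of the positive eigenvalues as denominator. Both conventions
#' are recorded on the result.
#'
#' @param m A [pairwise_dissimilarity()] result or a labelled symmetric
#'   matrix with zero diagonal.
#' @return A `fight_ordination` (method `"pcoa"`).
#' @export
pcoa_ordination <- function(m) {
  vals <- if (inherits(m, "dtw_dissimilarity")) m$values else as.matrix(m)
  n <- nrow(vals)
  if (n < 3L) abort_fd("PCoA needs at least 3 fish", "fd_size_error")
  if (max(abs(vals - t(vals))) > 1e-9 || any(abs(diag(vals)) > 1e-12)) {
    abort_fd("input must be symmetric with zero diagonal",
             "fd_integrity_error")
  }
  ids <- rownames(vals)
  if (is.null(ids)) ids <- paste0("obs", seq_len(n))
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% vals^2 %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- which(eg$values > tol)
  if (length(pos) == 0L) {
    abort_fd("no positive eigenvalues; degenerate geometry",
             "fd_degenerate_error")
  }
  coords <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), length(pos))
  fx <- fix_signs(coords, coords)
  out <- new_ordination(ids, fx$scores, eg$values[pos],
                        eg$values[pos] / sum(eg$values[pos]), "pcoa")
  out$all_eigenvalues <- eg$values
  out$coordinates <- fx$scores  # full positive-eigenvalue embedding
  out$negative_eigenvalue_convention <- "dropped; no Lingoes/Cailliez correction"
  out
}
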