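#' Dynamic time warping alignment of two processed series
#'
#' Aligns two (possibly unequal-length) series with the symmetric step
#' pattern that weights diagonal moves double:
#' \deqn{g(i,j) = \min\{g(i-1,j) + d_{ij},\; g(i,j-1) + d_{ij},\;
#'       g(i-1,j-1) + 2 d_{ij}\},\qquad g(1,1) = d_{11},}
#' where the local distance \eqn{d_{ij}} is the absolute difference for
#' univariate series and the Euclidean norm of the component difference for
#' multivariate (X/Y/Z) series. No windowing constraint is imposed: fights
#' are short, so the full cost table is cheap. Both the unnormalized
#' cumulative cost and the cost divided by `N + M` are returned, together
#' with one optimal warping path (ties broken by preferring the diagonal
#' step, then the step consuming series `a`).
#'
#' @param a,b [make_variant()] results sharing variant and channels, or bare
#'   numeric vectors / matrices (rows = time steps).
#' @return Object of class `dtw_alignment` with elements `distance`,
#'   `normalized_distance`, `path` (two-column index matrix), `n`, `m`.
#' @export
dtw_align <- function(a, b) {
  if (inherits(a, "processed_series") && inherits(b, "processed_series")) {
    if (a$variant != b$variant || a$channels != b$channels) {
      abort_fd(sprintf("variant mismatch: %s/%s vs %s/%s", a$variant,
                       a$channels, b$variant, b$channels), "fd_pairing_error")
    }
    a <- a$values
    b <- b$values
  }
  am <- if (is.matrix(a)) a else matrix(a, ncol = 1)
  bm <- if (is.matrix(b)) b else matrix(b, ncol = 1)
  n <- nrow(am)
  m <- nrow(bm)
  if (n < 1L || m < 1L) abort_fd("empty series", "fd_size_error")
  if (ncol(am) != ncol(bm)) abort_fd("dimension mismatch", "fd_pairing_error")

  # local cost matrix
  d <- matrix(0, n, m)
  for (k in seq_len(ncol(am))) {
    d <- d + outer(am[, k], bm[, k], `-`)^2
  }
  d <- sqrt(d)

  g <- matrix(Inf, n, m)
  g[1, 1] <- d[1, 1]
  if (n > 1) g[2:n, 1] <- cumsum(d[2:n, 1]) + d[1, 1]
  if (m > 1) g[1, 2:m] <- cumsum(d[1, 2:m]) + d[1, 1]
  if (n > 1 && m > 1) {
    for (j in 2:m) {
      for (i in 2:n) {
        g[i, j] <- min(g[i - 1, j] + d[i, j],
                       g[i, j - 1] + d[i, j],
                       g[i - 1, j - 1] + 2 * d[i, j])
      }
    }
  }

  # backtrack one optimal path; prefer diagonal, then the step consuming `a`
  path <- matrix(0L, n + m, 2)
  i <- n; j <- m; k <- n + m
  path[k, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    if (i == 1L) {
      j <- j - 1L
    } else if (j == 1L) {
      i <- i - 1L
    } else {
      cand <- c(g[i - 1, j - 1] + 2 * d[i, j],
                g[i - 1, j] + d[i, j],
                g[i, j - 1] + d[i, j])
      pick <- which(abs(cand - g[i, j]) < 1e-12)[1]
      if (is.na(pick)) pick <- which.min(cand)
      if (pick == 1L) { i <- i - 1L; j <- j - 1L }
      else if (pick == 2L) i <- i - 1L
      else j <- j - 1L
    }
    k <- k - 1L
    path[k, ] <- c(i, j)
  }
  path <- path[k:(n + m), , drop = FALSE]
  colnames(path) <- c("a", "b")
  structure(list(distance = g[n, m],
                 normalized_distance = g[n, m] / (n + m),
                 path = path, n = n, m = m),
            class = "dtw_alignment")
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf(
    "<dtw_alignment> %d x %d: distance %.4f (normalized %.4f), path %d steps\n",
    x$n, x$m, x$distance, x$normalized_distance, nrow(x$path)))
  invisible(x)
}

#' Pairwise DTW dissimilarity matrix for one processing variant
#'
#' Builds the processed series for every fish and aligns all `n(n-1)/2`
#' pairs, yielding a symmetric dissimilarity matrix with zero diagonal. The
#' unnormalized DTW distance is stored by default; the length-normalized
#' matrix is always computed alongside.
#'
#' @param dataset A [capture_dataset()] with at least 2 fish.
#' @param variant,channels Processing combination (see [variant_grid()]).
#' @param normalized If `TRUE`, `values` holds the normalized distances.
#' @param window High-pass window, s.
#' @return Object of class `dtw_dissimilarity` with elements `ids`, `values`
#'   (the default matrix), `unnormalized`, `normalized`, `variant`,
#'   `channels`.
#' @export
pairwise_dissimilarity <- function(dataset, variant, channels,
                                   normalized = FALSE, window = 4) {
  ids <- names(dataset$traces)
  n <- length(ids)
  if (n < 2L) abort_fd("need at least 2 fish", "fd_size_error")
  series <- lapply(dataset$traces, make_variant, variant = variant,
                   channels = channels, window = window)
  un <- matrix(0, n, n, dimnames = list(ids, ids))
  no <- un
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- tryCatch(dtw_align(series[[i]], series[[j]]),
                     error = function(e) {
                       abort_fd(sprintf("alignment failed for pair (%s, %s): %s",
                                        ids[i], ids[j], conditionMessage(e)),
                                "fd_pairing_error")
                     })
      un[i, j] <- un[j, i] <- al$distance
      no[i, j] <- no[j, i] <- al$normalized_distance
    }
  }
  structure(list(ids = ids, values = if (normalized) no else un,
                 unnormalized = un, normalized = no,
                 variant = variant, channels = channels),
            class = "dtw_dissimilarity")
}

#' @export
print.dtw_dissimilarity <- function(x, ...) {
  cat(sprintf("<dtw_dissimilarity> %s/%s, %d fish, mean off-diagonal %.3f\n",
              x$variant, x$channels, length(x$ids),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' @export
as.matrix.dtw_dissimilarity <- function(x, ...) x$values

#' @export
as.dist.dtw_dissimilarity <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}
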