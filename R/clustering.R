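# Agglomerative clustering of fights and gap-statistic selection of the
# number of clusters.

# Coerce the many things users pass (ordination, DTW dissimilarity, square
# matrix, point matrix, dist) into a `dist` object.
as_fight_dist <- function(x) {
  if (inherits(x, "dist")) return(x)
  if (inherits(x, "fight_ordination")) return(stats::dist(x$scores))
  if (inherits(x, "dtw_dissimilarity")) return(stats::as.dist(x$values))
  m <- as.matrix(x)
  if (nrow(m) == ncol(m) && max(abs(diag(m))) < 1e-12 &&
      max(abs(m - t(m))) < 1e-9) {
    return(stats::as.dist(m))
  }
  stats::dist(m)
}

#' Ward agglomerative clustering of fights
#'
#' Hierarchical agglomeration by Ward's method applied to the input
#' distances as-is (the un-squared "Ward D" convention, appropriate for the
#' Euclidean distances arising from ordination scores). Labels for `k`
#' groups come from cutting the tree after `n - k` merges.
#'
#' @param x Distances (a `dist`, a symmetric zero-diagonal matrix or a
#'   [pairwise_dissimilarity()]) or points (a numeric matrix or a
#'   [pca_ordination()] / [pcoa_ordination()] result, in which case
#'   Euclidean distances between score rows are used).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Object of class `fight_clusters` with elements `ids`, `tree`
#'   (the `hclust`), `merge_heights`, `labels`, `k`.
#' @export
ward_cluster <- function(x, k) {
  d <- as_fight_dist(x)
  n <- attr(d, "Size")
  if (n < 2L) abort_fd("need at least 2 fish", "fd_size_error")
  if (k < 1L || k > n) {
    abort_fd(sprintf("k = %s out of range [1, %d]", k, n),
             "fd_parameter_error")
  }
  ids <- attr(d, "Labels")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  tree <- stats::hclust(d, method = "ward.D")
  labels <- stats::cutree(tree, k = k)
  names(labels) <- ids
  structure(list(ids = ids, tree = tree, merge_heights = tree$height,
                 labels = labels, k = as.integer(k)),
            class = "fight_clusters")
}

#' @export
print.fight_clusters <- function(x, ...) {
  cat(sprintf("<fight_clusters> Ward D, %d fish cut at k = %d\n",
              length(x$ids), x$k))
  print(split(x$ids, x$labels))
  invisible(x)
}

# Pooled within-cluster dispersion: sum over clusters of (sum of squared
# pairwise distances within) / (2 * cluster size).
ward_fun <- function(x, k) {
  list(cluster = stats::cutree(stats::hclust(stats::dist(x),
                                             method = "ward.D"), k = k))
}

#' Gap statistic over candidate numbers of clusters
#'
#' Compares the observed log pooled within-cluster dispersion (squared
#' pairwise distances) against `B` reference datasets drawn uniformly over
#' each observed feature's range, clustering both with the same Ward
#' procedure as [ward_cluster()]. The bootstrap standard error carries the
#' usual `sqrt(1 + 1/B)` factor.
#'
#' @param x Points matrix (typically the retained Dim1--Dim3 ordination
#'   scores) or a `fight_ordination`.
#' @param k_max Largest k searched; default `min(6, n - 1)`.
#' @param B Number of reference replicates (default 100).
#' @param seed Optional seed for the reference draws.
#' @return Object of class `gap_profile`: data frame columns `k`, `logW`,
#'   `E_logW`, `gap`, `se`, plus attribute `chosen_k` (see [choose_k()]).
#' @export
gap_statistic <- function(x, k_max = NULL, B = 100, seed = NULL) {
  pts <- if (inherits(x, "fight_ordination")) x$scores else as.matrix(x)
  n <- nrow(pts)
  if (n < 3L) abort_fd("need at least 3 fish", "fd_size_error")
  if (is.null(k_max)) k_max <- min(6L, n - 1L)
  if (k_max < 1L || k_max > n - 1L) {
    abort_fd("k_max must be in [1, n - 1]", "fd_parameter_error")
  }
  cg <- with_seed(seed,
                  cluster::clusGap(pts, FUNcluster = ward_fun, K.max = max(k_max, 2L),
                                   B = B, d.power = 2, spaceH0 = "original",
                                   verbose = FALSE))
  tab <- as.data.frame(cg$Tab)[seq_len(k_max), ]
  prof <- data.frame(k = seq_len(k_max), logW = tab$logW,
                     E_logW = tab$E.logW, gap = tab$gap, se = tab$SE.sim)
  class(prof) <- c("gap_profile", "data.frame")
  attr(prof, "B") <- B
  attr(prof, "chosen_k") <- choose_k(prof)
  prof
}

#' Select the number of clusters from a gap profile
#'
#' The smallest k whose gap is at least the gap at k + 1 minus its standard
#' error; if no k satisfies the rule the k maximizing the gap is returned.
#' A choice of 1 is a valid outcome, reported as "no discrete clusters".
#'
#' @param profile A [gap_statistic()] result (or data frame with `gap`,
#'   `se`).
#' @return Chosen k (integer).
#' @export
choose_k <- function(profile) {
  gap <- profile$gap
  se <- profile$se
  kk <- length(gap)
  if (kk == 0L) abort_fd("empty gap profile", "fd_parameter_error")
  if (kk == 1L) return(1L)
  for (k in seq_len(kk - 1L)) {
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) return(as.integer(profile$k[k]))
  }
  as.integer(profile$k[which.max(gap)])
}

#' @export
print.gap_profile <- function(x, ...) {
  ck <- attr(x, "chosen_k")
  cat(sprintf("<gap_profile> B = %s; chosen k = %d%s\n", attr(x, "B"), ck,
              if (ck == 1L) " (no discrete clusters)" else ""))
  print.data.frame(round(as.data.frame(x), 4))
  invisible(x)
}
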