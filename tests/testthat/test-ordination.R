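test_that("PCA of collinear metrics concentrates variance on Dim1", {
  withr::with_seed(51, {
    t <- rnorm(10)
    z <- outer(t, c(1, -2, 0.5))  # rank-1 data
    z <- scale(z)[, ]
    rownames(z) <- paste0("f", 1:10)
    ord <- pca_ordination(z)
    expect_equal(ord$var_explained[1], 1, tolerance = 1e-10)
  })
})

test_that("PCA scores are uncorrelated with eigenvalue variances and
           reconstruct the input", {
  withr::with_seed(52, {
    z <- scale(matrix(rnorm(14 * 7), 14, 7))[, ]
    rownames(z) <- paste0("f", 1:14)
    ord <- pca_ordination(z)
    eg <- eigen(cov(z), symmetric = TRUE)
    full_scores <- z %*% eg$vectors
    expect_equal(unname(diag(cov(full_scores))), eg$values,
                 tolerance = 1e-10)
    off <- cov(full_scores); diag(off) <- 0
    expect_lt(max(abs(off)), 1e-10)
    # full-rank reconstruction
    expect_equal(full_scores %*% t(eg$vectors), z, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # retained dims and variance bookkeeping
    expect_equal(colnames(ord$scores), c("Dim1", "Dim2", "Dim3"))
    expect_true(all(diff(ord$eigenvalues) <= 1e-12))
    expect_equal(sum(ord$var_explained), 1, tolerance = 1e-12)
    # sign convention: largest-magnitude loading positive
    for (k in 1:3) {
      l <- ord$loadings[, k]
      expect_gt(l[which.max(abs(l))], 0)
    }
  })
})

test_that("PCoA recovers 1-D geometry and the equilateral triangle", {
  # three points on a line at 0, d/2, d
  d <- 3.4
  m <- as.matrix(dist(c(0, d / 2, d)))
  dimnames(m) <- list(letters[1:3], letters[1:3])
  ord <- pcoa_ordination(m)
  expect_equal(as.matrix(dist(ord$coordinates)), m, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(length(ord$eigenvalues), 1)  # collinear: one positive dim

  # equilateral triangle with unit side: two positive eigenvalues of 0.5
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  ord2 <- pcoa_ordination(tri)
  expect_equal(ord2$eigenvalues, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("PCoA embeds Euclidean distance matrices exactly", {
  withr::with_seed(53, {
    for (n in c(6, 10, 12)) {
      pts <- matrix(rnorm(n * 4), n, 4)
      rownames(pts) <- paste0("p", seq_len(n))
      m <- as.matrix(dist(pts))
      ord <- pcoa_ordination(m)
      expect_equal(as.matrix(dist(ord$coordinates)), m, tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_true(all(ord$all_eigenvalues > -1e-9))
    }
  })
  expect_error(pcoa_ordination(matrix(0, 3, 3)), class = "fd_degenerate_error")
})

test_that("Ward clustering separates well-spaced 1-D groups", {
  m <- as.matrix(dist(c(0, 1, 5, 6)))
  dimnames(m) <- list(paste0("p", 1:4), paste0("p", 1:4))
  cl <- ward_cluster(m, 2)
  expect_equal(unname(cl$labels), c(1, 1, 2, 2))
  expect_equal(cl$merge_heights[1:2], c(1, 1))

  cl4 <- ward_cluster(m, 4)
  expect_equal(length(unique(cl4$labels)), 4)
  expect_error(ward_cluster(m, 5), class = "fd_parameter_error")
})

test_that("Ward merge heights match the Lance-Williams recursion oracle", {
  withr::with_seed(54, {
    for (rep in 1:10) {
      pts <- matrix(rnorm(8 * 3), 8, 3)
      d <- dist(pts)
      cl <- ward_cluster(as.matrix(d) * (1 - diag(8)), 2)
      expect_equal(cl$merge_heights, ward_oracle_heights(d),
                   tolerance = 1e-10)
    }
  })
})

test_that("Ward labels are invariant to input ordering", {
  withr::with_seed(55, {
    pts <- matrix(rnorm(12 * 3), 12, 3,
                  dimnames = list(paste0("f", 1:12), NULL))
    cl1 <- ward_cluster(pts, 3)
    perm <- sample(12)
    cl2 <- ward_cluster(pts[perm, ], 3)
    # same partition: compare co-membership of every pair
    ids <- rownames(pts)
    same1 <- outer(cl1$labels[ids], cl1$labels[ids], `==`)
    same2 <- outer(cl2$labels[ids], cl2$labels[ids], `==`)
    expect_equal(same1, same2)
  })
})

test_that("gap profile is seed-reproducible and k_max = 1 is trivial", {
  ds <- default_dataset()
  ord <- pca_ordination(metrics_matrix(ds))
  g1 <- gap_statistic(ord, B = 20, seed = 7)
  g2 <- gap_statistic(ord, B = 20, seed = 7)
  expect_equal(g1, g2)
  expect_true(all(g1$se > 0))

  gk1 <- gap_statistic(ord, k_max = 1, B = 10, seed = 3)
  expect_equal(attr(gk1, "chosen_k"), 1L)
})

test_that("choose_k applies the one-standard-error rule with argmax fallback", {
  prof <- data.frame(k = 1:2, gap = c(0.5, 0.2), se = c(0.1, 0.1))
  expect_equal(choose_k(prof), 1L)

  prof2 <- data.frame(k = 1:3, gap = c(0.1, 0.5, 0.45),
                      se = c(0.05, 0.05, 0.05))
  expect_equal(choose_k(prof2), 2L)

  prof3 <- data.frame(k = 1:4, gap = c(0.1, 0.2, 0.3, 0.4),
                      se = rep(1e-6, 4))
  expect_equal(choose_k(prof3), 4L)
})
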