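test_that("design has the documented predictor sets", {
  ds <- default_dataset()
  mm <- metrics_matrix(ds)
  ord <- pca_ordination(mm)

  d1 <- build_design(ds, ord, include_duration = TRUE)
  expect_equal(colnames(d1$X),
               c("Dim1", "Dim2", "Dim3", "species_coho", "body_mass",
                 "water_temp", "fight_duration"))
  d2 <- build_design(ds, ord, include_duration = FALSE)
  expect_equal(ncol(d2$X), 6)

  # responses normalized, covariates standardized
  expect_equal(colnames(d1$Y), c("blood_ph", "lactate"))
  expect_lt(abs(mean(d1$X[, "body_mass"])), 1e-10)
  expect_equal(sd(d1$X[, "water_temp"]), 1, tolerance = 1e-10)

  # missing physiology is reported by fish id
  ds2 <- ds
  ds2$records$lactate_mmol_l[3] <- NA
  bad_id <- ds2$records$fish_id[3]
  expect_error(build_design(ds2, ord), class = "fd_missing_physiology_error",
               regexp = bad_id)
})

test_that("fits are seed-reproducible and summaries self-consistent", {
  sim <- simulate_design_truth(30, beta_dim = c(0.5, 0, -0.5, 0.5, 0, -0.5),
                               seed = 61)
  f1 <- fit_linkage(sim$design, chains = 2, warmup = 200, draws = 200,
                    seed = 99)
  f2 <- fit_linkage(sim$design, chains = 2, warmup = 200, draws = 200,
                    seed = 99)
  expect_identical(f1$draws, f2$draws)

  s <- summary(f1)
  expect_true(all(c("mean", "median", "ci_lower", "ci_upper", "rhat",
                    "ess_ratio") %in% names(s)))
  # significance sets are exactly the CI-excludes-zero parameters
  sig <- s$parameter[sign(s$ci_lower) == sign(s$ci_upper)]
  dimsig <- grep("^Dim", sig, value = TRUE)
  expect_setequal(f1$significant_dims, dimsig)
  # rho constrained to (-1, 1)
  expect_true(all(f1$draws[, "rho"] > -1 & f1$draws[, "rho"] < 1))
  # coef returns an intercept+predictors by responses matrix
  expect_equal(dim(coef(f1)), c(7, 2))
})

test_that("Bayesian R2 lies in [0,1] and tracks signal strength", {
  sim0 <- simulate_design_truth(60, beta_dim = rep(0, 6), sigma = c(1, 1),
                                seed = 62)
  f0 <- fit_linkage(sim0$design, chains = 2, warmup = 300, draws = 300,
                    seed = 1)
  r0 <- bayes_r2(f0)
  expect_true(all(r0$draws >= 0 & r0$draws <= 1))

  sim1 <- simulate_design_truth(60, beta_dim = rep(1, 6),
                                sigma = c(0.05, 0.05), seed = 62)
  f1 <- fit_linkage(sim1$design, chains = 2, warmup = 300, draws = 300,
                    seed = 1)
  r1 <- bayes_r2(f1)
  expect_gt(r1$model, 0.95)
  expect_gt(r1$model, r0$model)
})

test_that("kfold partitions every fish exactly once and is deterministic", {
  sim <- simulate_design_truth(20, beta_dim = c(1, 0, 0, 0, 0, 1), seed = 63)
  k1 <- kfold_ic(sim$design, folds = 5, chains = 2, warmup = 200,
                 draws = 200, seed = 5)
  k2 <- kfold_ic(sim$design, folds = 5, chains = 2, warmup = 200,
                 draws = 200, seed = 5)
  expect_identical(k1$ic, k2$ic)
  expect_equal(sort(unique(k1$fold_assignment)), 1:5)
  expect_equal(length(k1$fold_assignment), 20)
  expect_equal(max(table(k1$fold_assignment)) -
                 min(table(k1$fold_assignment)), 0)
  expect_error(kfold_ic(sim$design, folds = 30), class = "fd_parameter_error")
})

test_that("vector fitting recovers perfect alignment and bounds p", {
  ds <- default_dataset()
  ord <- pca_ordination(metrics_matrix(ds))
  v <- data.frame(aligned = ord$scores[, 1],
                  ph = ds$records$blood_ph)
  ev <- envfit_vectors(ord, v, permutations = 999, seed = 71)
  al <- ev[ev$variable == "aligned", ]
  expect_equal(al$r2, 1, tolerance = 1e-10)
  expect_equal(abs(al$Dim1), 1, tolerance = 1e-8)
  expect_equal(al$p_value, 0.001)
  expect_true(all(ev$p_value >= 1 / 1000))
  expect_true(all(ev$r2 >= 0 & ev$r2 <= 1))

  vbad <- data.frame(const = rep(1, 14))
  expect_error(envfit_vectors(ord, vbad), class = "fd_degenerate_error")
})

test_that("marginal effects are flat for null predictors, monotone for
           strong ones, with a band containing the median", {
  ds <- default_dataset()
  ord <- pcoa_ordination(pairwise_dissimilarity(ds, "raw", "Y"))
  design <- build_design(ds, ord)
  fit <- fit_linkage(design, chains = 2, warmup = 300, draws = 300,
                     seed = 8)
  me <- marginal_effects(fit, "Dim1", grid_size = 20)
  expect_equal(nrow(me), 40)  # 20 points x 2 responses
  expect_true(all(me$lower <= me$median + 1e-12 &
                    me$median <= me$upper + 1e-12))
  # flatness vs band width for a predictor the data do not support:
  # spread of the median curve should not exceed the credible band height
  for (r in unique(me$response)) {
    sub <- me[me$response == r, ]
    band <- mean(sub$upper - sub$lower)
    expect_lt(diff(range(sub$median)), max(1.5 * band, 1e-6))
  }
  expect_error(marginal_effects(fit, "nope"), class = "fd_parameter_error")
})

test_that("correlogram is a symmetric unit-diagonal 8 x 8 matrix and
           reproduces exact linear dependencies", {
  ds <- default_dataset()
  cg <- correlogram(ds)
  expect_equal(dim(cg), c(8, 8))
  expect_equal(diag(cg), setNames(rep(1, 8), colnames(cg)))
  expect_equal(cg, t(cg), tolerance = 1e-15)

  # constant ActVSum makes total effort an exact multiple of duration
  rows <- lapply(ds$traces, function(tr) {
    tr$actvsum <- rep(1.0, length(tr$times))
    fight_metrics(tr)
  })
  raw <- do.call(rbind, rows)
  expect_equal(cor(raw$total_effort, raw$fight_duration), 1,
               tolerance = 1e-12)
})
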