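test_that("burst counting matches run-length and transition oracles", {
  expect_equal(count_bursts(c(1.0, 1.2, 1.1)), 0)
  expect_equal(count_bursts(c(1.3, 1.3, 1.0, 1.26)), 2)
  expect_error(count_bursts(numeric(0)), class = "fd_size_error")

  # strictly positive series with threshold 0 is one long burst;
  # in-range series never exceeds threshold 2
  expect_equal(count_bursts(runif(20, 0.1, 2), threshold = 0), 1)
  expect_equal(count_bursts(runif(20, 0, 2), threshold = 2), 0)

  # random 0/2 sequences: count equals number of FALSE->TRUE transitions
  withr::with_seed(4, {
    for (rep in 1:20) {
      x <- sample(c(0, 2), 30, replace = TRUE)
      above <- x > 1.25
      trans <- sum(diff(c(FALSE, above)) == 1)
      expect_equal(count_bursts(x), trans)
    }
  })

  # minimum run length filters single-sample spikes
  expect_equal(count_bursts(c(1.3, 1.0, 1.3, 1.3), min_run = 2), 1)
})

test_that("basic metrics: mean, CV, total effort and scaling behaviour", {
  tr <- make_trace(n = 3, actvsum = c(1, 1, 1))
  m <- fight_metrics(tr, duration = 6)
  expect_equal(m$mean_actvsum, 1)
  expect_equal(m$cv_actvsum, 0)
  expect_equal(m$total_effort, 3)
  expect_equal(m$fight_duration, 6)

  tr2 <- make_trace(n = 3, actvsum = c(0.5, 1.5, 1.0))
  m2 <- fight_metrics(tr2)
  expect_equal(m2$mean_actvsum, 1)
  expect_equal(m2$total_effort, 3)
  expect_equal(m2$cv_actvsum, 0.5)  # sample SD of (0.5, 1.5, 1.0) = 0.5

  # scaling ActVSum by c scales mean and total, leaves CV unchanged
  a <- c(0.2, 0.8, 0.4, 0.6, 1.0)
  m3 <- fight_metrics(make_trace(n = 5, actvsum = a))
  m4 <- fight_metrics(make_trace(n = 5, actvsum = 2 * a))
  expect_equal(m4$mean_actvsum, 2 * m3$mean_actvsum)
  expect_equal(m4$total_effort, 2 * m3$total_effort)
  expect_equal(m4$cv_actvsum, m3$cv_actvsum)
})

test_that("phase intensities use floor(n/3) samples from each end", {
  ph <- phase_intensities(c(3, 3, 3, 1, 1, 1, 2, 2, 2))
  expect_equal(unname(ph), c(3, 2, 1.5))

  expect_equal(unname(phase_intensities(rep(0.7, 9))["ratio"]), 1)

  # n = 4: floor(4/3) = 1 sample from each end
  ph4 <- phase_intensities(c(2, 9, 9, 0.5))
  expect_equal(unname(ph4["early"]), 2)
  expect_equal(unname(ph4["late"]), 0.5)

  # time reversal inverts the ratio when thirds tile the series
  a <- c(1.2, 1.4, 1.0, 0.6, 0.9, 0.8)
  r1 <- phase_intensities(a)["ratio"]
  r2 <- phase_intensities(rev(a))["ratio"]
  expect_equal(unname(r1 * r2), 1)

  expect_error(phase_intensities(c(1, 2)), class = "fd_size_error")
})

test_that("fatigue index is the non-negative post-peak OLS decline", {
  expect_equal(fatigue_index(c(0.1, 0.2, 0.3, 0.4)), 0)  # monotone rise
  expect_equal(fatigue_index(c(2.0, 1.5, 1.0, 0.5)), 0.5)  # exact line

  # noisy post-peak decline recovered within 2 SE (closed-form OLS oracle)
  withr::with_seed(9, {
    n_post <- 40
    x <- c(0.5, 2, 2 - 0.1 * seq_len(n_post) + rnorm(n_post, 0, 0.1))
    p <- which.max(x)
    idx <- p:length(x)
    fitl <- lm(x[idx] ~ idx)
    se <- summary(fitl)$coefficients[2, 2]
    expect_equal(fatigue_index(x), max(0, -unname(coef(fitl)[2])),
                 tolerance = 1e-10)
    expect_lt(abs(fatigue_index(x) - 0.1), 2 * se)
  })

  # rising tail after peak: negative decline clamps to zero
  expect_equal(fatigue_index(c(2, 1.9, 1.95, 2.0, 2.0)), 0)
})

test_that("inter-axis correlations match the textbook formula", {
  tr <- make_trace(n = 50, seed = 21)
  tr$jerk_y <- tr$jerk_x
  tr$jerk_z <- tr$jerk_x
  r <- inter_axis_correlations(tr)
  expect_equal(unname(r), rep(1, 4))

  tr2 <- make_trace(n = 50, seed = 22)
  tr2$jerk_y <- -tr2$jerk_x
  expect_equal(unname(inter_axis_correlations(tr2)["r_xy"]), -1)

  tr3 <- make_trace(n = 50, seed = 23)
  r3 <- inter_axis_correlations(tr3)
  expect_equal(unname(r3["r_xy"]), oracle_pearson(tr3$jerk_x, tr3$jerk_y),
               tolerance = 1e-12)
  expect_equal(unname(r3["r_xz"]), oracle_pearson(tr3$jerk_x, tr3$jerk_z),
               tolerance = 1e-12)

  tr4 <- make_trace(n = 10, seed = 24)
  tr4$jerk_z <- rep(0.3, 10)
  expect_error(inter_axis_correlations(tr4), class = "fd_degenerate_error")
})

test_that("metrics matrix is 14 x 7, z-scored, without fight duration", {
  ds <- default_dataset()
  mm <- metrics_matrix(ds)
  expect_equal(dim(mm$z), c(14, 7))
  expect_false("fight_duration" %in% colnames(mm$z))
  expect_true(all(abs(colMeans(mm$z)) < 1e-10))
  expect_true(all(abs(apply(mm$z, 2, sd) - 1) < 1e-10))
  expect_equal(length(mm$fight_duration), 14)
  expect_true(all(c("fight_duration", colnames(mm$z)) %in% names(mm$raw)))
})
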