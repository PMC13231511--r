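# Bayesian bivariate Gaussian regression linking movement dimensions to
# post-capture physiology (normalized blood pH and plasma lactate), with
# K-fold IC model comparison, Bayesian R2, envfit-style vector fitting and
# marginal effects.

linkage_model_string <- "
model {
  for (i in 1:n) {
    y[i, 1:2] ~ dmnorm(mu[i, 1:2], Omega[1:2, 1:2])
    mu[i, 1] <- inprod(X[i, ], beta[, 1])
    mu[i, 2] <- inprod(X[i, ], beta[, 2])
  }
  for (j in 1:p) {
    for (r in 1:2) { beta[j, r] ~ dnorm(0, 0.04) }   # Normal(0, 5)
  }
  for (r in 1:2) { sigma[r] ~ dt(0, 0.16, 3) T(0,) } # half-t(3, 0, 2.5)
  rho ~ dunif(-1, 1)
  Sigma[1, 1] <- sigma[1] * sigma[1]
  Sigma[2, 2] <- sigma[2] * sigma[2]
  Sigma[1, 2] <- rho * sigma[1] * sigma[2]
  Sigma[2, 1] <- Sigma[1, 2]
  Omega[1:2, 1:2] <- inverse(Sigma[1:2, 1:2])
}
"

#' Build the regression design linking movement to physiology
#'
#' Responses are blood pH and plasma lactate, each normalized by the
#' ordered-quantile transform ([normalize_response()]); the stored inverse
#' mappings allow predictions to be reported on the original scales.
#' Predictors are the three retained ordination dimensions plus the
#' covariates: a species indicator (chinook reference, coho = 1), z-scored
#' body mass and z-scored water temperature, and z-scored fight duration
#' only when `include_duration = TRUE` (the summary-metrics pipeline, whose
#' metrics collapse temporal information).
#'
#' @param dataset A [capture_dataset()] with complete physiology.
#' @param ordination A [pca_ordination()] or [pcoa_ordination()] result
#'   whose ids are contained in the dataset.
#' @param include_duration Add the z-scored fight duration column?
#' @return Object of class `linkage_design`: `ids`, `Y` (n x 2 normalized
#'   responses), `X` (n x p predictors), `transforms` (orq objects for
#'   blood_ph and lactate), `include_duration`.
#' @export
build_design <- function(dataset, ordination, include_duration = FALSE) {
  ids <- ordination$ids
  rec <- dataset$records
  if (!all(ids %in% rec$fish_id)) {
    abort_fd("ordination contains fish absent from the dataset",
             "fd_validation_error")
  }
  rec <- rec[match(ids, rec$fish_id), , drop = FALSE]
  miss <- ids[!is.finite(rec$blood_ph) | !is.finite(rec$lactate_mmol_l) |
                !is.finite(rec$body_mass_kg)]
  if (length(miss) > 0L) {
    abort_fd(sprintf("missing physiology or body mass for fish: %s",
                     paste(miss, collapse = ", ")),
             "fd_missing_physiology_error")
  }
  t_ph <- normalize_response(rec$blood_ph)
  t_la <- normalize_response(rec$lactate_mmol_l)
  Y <- cbind(blood_ph = t_ph$scores, lactate = t_la$scores)
  X <- cbind(ordination$scores[, 1:min(3, ncol(ordination$scores)),
                               drop = FALSE],
             species_coho = as.numeric(rec$species == "coho"),
             body_mass = zscore(rec$body_mass_kg),
             water_temp = zscore(rec$water_temp_c))
  if (include_duration) {
    X <- cbind(X, fight_duration = zscore(rec$fight_duration_s))
  }
  rownames(X) <- ids
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    drop <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L]
    abort_fd(sprintf("design is rank deficient (collinear columns: %s)",
                     paste(drop, collapse = ", ")), "fd_collinearity_error")
  }
  structure(list(ids = ids, Y = Y, X = X,
                 transforms = list(blood_ph = t_ph, lactate = t_la),
                 include_duration = include_duration),
            class = "linkage_design")
}

#' @export
print.linkage_design <- function(x, ...) {
  cat(sprintf("<linkage_design> %d fish, %d predictors: %s\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

run_linkage_mcmc <- function(Y, X, chains, warmup, draws, seed) {
  p <- ncol(X) + 1L
  Xi <- cbind(intercept = 1, X)
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((seed * 1009 + ch) %% 2147483629 + 1))
  })
  jm <- rjags::jags.model(textConnection(linkage_model_string),
                          data = list(y = Y, X = Xi, n = nrow(Y), p = p),
                          inits = inits, n.chains = chains, quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  rjags::coda.samples(jm, c("beta", "sigma", "rho"), n.iter = draws,
                      progress.bar = "none")
}

#' Fit the Bayesian bivariate physiology model
#'
#' Samples the posterior of the bivariate Gaussian regression
#' \eqn{y_i = \beta_0 + \beta_{dim} D_i + \beta_{cov} X_i + \varepsilon_i}
#' (identity links; residual correlation \eqn{\rho} between the two
#' responses estimated jointly) by MCMC. Priors are weakly informative on
#' the normalized/standardized scale: Normal(0, 5) on intercepts and
#' coefficients, half-Student-t(3, 0, 2.5) on residual SDs, uniform(-1, 1)
#' on \eqn{\rho}. Convergence is summarized by the split-chain
#' Gelman--Rubin statistic and effective-sample-size ratios; an rhat above
#' 1.05 attaches a non-fatal convergence warning to the fit.
#'
#' @param design A [build_design()] result.
#' @param chains Number of chains (default 4).
#' @param warmup Warm-up iterations per chain (default 3000).
#' @param draws Retained iterations per chain (default 1000).
#' @param seed Integer seed; fits are bit-reproducible given a seed.
#' @return Object of class `linkage_fit`; see [summary.linkage_fit()].
#' @export
fit_linkage <- function(design, chains = 4, warmup = 3000, draws = 1000,
                        seed = 1) {
  samp <- run_linkage_mcmc(design$Y, design$X, chains, warmup, draws, seed)
  mat <- as.matrix(samp)
  pnames <- c("intercept", colnames(design$X))
  p <- length(pnames)
  resp <- colnames(design$Y)
  cn <- colnames(mat)
  # reorder beta draws into named columns <predictor>:<response>
  ord <- c(vapply(seq_len(2), function(r) {
    vapply(seq_len(p), function(j) sprintf("beta[%d,%d]", j, r), character(1))
  }, character(p)))
  beta_draws <- mat[, ord, drop = FALSE]
  colnames(beta_draws) <- as.vector(outer(pnames, resp,
                                          function(a, b) paste(a, b, sep = ":")))
  extra <- mat[, c("sigma[1]", "sigma[2]", "rho"), drop = FALSE]
  colnames(extra) <- c(paste0("sigma_", resp), "rho")
  all_draws <- cbind(beta_draws, extra)

  per_chain <- lapply(samp, function(ch) {
    m <- as.matrix(ch)[, c(ord, "sigma[1]", "sigma[2]", "rho"), drop = FALSE]
    colnames(m) <- colnames(all_draws)
    m
  })
  rhat <- vapply(colnames(all_draws), function(nm) {
    split_rhat(do.call(cbind, lapply(per_chain, function(m) m[, nm])))
  }, numeric(1))
  ess <- coda::effectiveSize(samp)[c(ord, "sigma[1]", "sigma[2]", "rho")]
  names(ess) <- colnames(all_draws)
  total <- chains * draws

  qs <- t(apply(all_draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  summ <- data.frame(parameter = colnames(all_draws),
                     mean = colMeans(all_draws),
                     median = qs[, 2], ci_lower = qs[, 1], ci_upper = qs[, 3],
                     rhat = rhat, ess_ratio = as.numeric(ess) / total,
                     row.names = NULL, stringsAsFactors = FALSE)
  sig <- summ$parameter[sign(summ$ci_lower) == sign(summ$ci_upper) &
                          summ$ci_lower != 0]
  dims <- paste0("Dim", 1:3)
  is_dim <- vapply(strsplit(sig, ":"), function(s) s[1] %in% dims, logical(1))
  covs <- setdiff(pnames, c("intercept", dims))
  is_cov <- vapply(strsplit(sig, ":"), function(s) s[1] %in% covs, logical(1))

  fit <- structure(list(
    draws = all_draws, per_chain = per_chain, summary = summ,
    predictors = pnames, responses = resp,
    rho = summ[summ$parameter == "rho",
               c("mean", "median", "ci_lower", "ci_upper")],
    significant_dims = sig[is_dim], significant_covariates = sig[is_cov],
    design = design,
    settings = list(chains = chains, warmup = warmup, draws = draws,
                    seed = seed)),
    class = "linkage_fit")
  if (any(rhat > 1.05, na.rm = TRUE)) {
    attr(fit, "convergence_warning") <- sprintf(
      "max split-chain rhat %.3f > 1.05", max(rhat, na.rm = TRUE))
  }
  fit
}

#' @export
print.linkage_fit <- function(x, ...) {
  cat(sprintf(
    "<linkage_fit> bivariate Gaussian, %d fish, %d predictors, %d x %d draws\n",
    nrow(x$design$Y), length(x$predictors) - 1L, x$settings$chains,
    x$settings$draws))
  cat(sprintf("  residual correlation rho = %.2f [%.2f, %.2f]\n",
              x$rho$median, x$rho$ci_lower, x$rho$ci_upper))
  cat(sprintf("  significant dims: %s; significant covariates: %s\n",
              if (length(x$significant_dims)) paste(x$significant_dims,
                                                    collapse = ", ") else "none",
              if (length(x$significant_covariates))
                paste(x$significant_covariates, collapse = ", ") else "none"))
  cw <- attr(x, "convergence_warning")
  if (!is.null(cw)) cat("  WARNING:", cw, "\n")
  invisible(x)
}

#' @export
summary.linkage_fit <- function(object, ...) object$summary

#' @export
coef.linkage_fit <- function(object, ...) {
  p <- length(object$predictors)
  m <- matrix(object$summary$mean[seq_len(2 * p)], p, 2,
              dimnames = list(object$predictors, object$responses))
  m
}

#' Posterior predictions of the linear predictor
#'
#' @param object A [fit_linkage()] result.
#' @param newdata Matrix of predictor values (columns as in the design);
#'   defaults to the training design.
#' @param draws_out Return per-draw predictions (`TRUE`) or the posterior
#'   median surface (`FALSE`, default).
#' @param ... Unused.
#' @return With `draws_out = FALSE`, an n x 2 matrix of posterior medians of
#'   the linear predictor per response; otherwise a list of two
#'   draws x n matrices.
#' @export
predict.linkage_fit <- function(object, newdata = NULL, draws_out = FALSE,
                                ...) {
  X <- if (is.null(newdata)) object$design$X else {
    as.matrix(newdata)[, colnames(object$design$X), drop = FALSE]
  }
  Xi <- cbind(1, X)
  p <- length(object$predictors)
  out <- lapply(seq_len(2), function(r) {
    B <- object$draws[, ((r - 1) * p + 1):(r * p), drop = FALSE]
    B %*% t(Xi)  # draws x n
  })
  names(out) <- object$responses
  if (draws_out) return(out)
  med <- vapply(out, function(m) apply(m, 2, stats::median),
                numeric(nrow(Xi)))
  colnames(med) <- object$responses
  med
}

#' @export
residuals.linkage_fit <- function(object, ...) {
  object$design$Y - predict(object)
}

#' K-fold cross-validation information criterion
#'
#' Partitions the fish into `folds` random folds (balanced to within one
#' fish), refits the model on each training remainder with the same MCMC
#' settings and evaluates the log pointwise predictive density of the
#' held-out rows under the posterior (log of the mean over draws of the
#' bivariate Gaussian density). The criterion is
#' \eqn{-2 \sum_i \mathrm{lppd}_i}; lower means better out-of-sample
#' prediction.
#'
#' @param design A [build_design()] result.
#' @param folds Number of folds (default 10).
#' @param chains,warmup,draws MCMC settings for each refit.
#' @param seed Seed controlling both the fold assignment and the refits.
#' @return Object of class `kfold_ic`: list with `ic`, `fold_assignment`,
#'   `lppd` (per fish).
#' @export
kfold_ic <- function(design, folds = 10, chains = 4, warmup = 3000,
                     draws = 1000, seed = 1) {
  n <- nrow(design$Y)
  if (n < folds) {
    abort_fd(sprintf("n = %d < folds = %d; reduce the number of folds",
                     n, folds), "fd_parameter_error")
  }
  assign <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  lppd <- numeric(n)
  p <- ncol(design$X) + 1L
  for (f in seq_len(folds)) {
    test <- which(assign == f)
    train <- which(assign != f)
    samp <- run_linkage_mcmc(design$Y[train, , drop = FALSE],
                             design$X[train, , drop = FALSE],
                             chains, warmup, draws,
                             seed = sub_seed(seed, paste0("fold", f)))
    mat <- as.matrix(samp)
    b1 <- mat[, sprintf("beta[%d,1]", seq_len(p)), drop = FALSE]
    b2 <- mat[, sprintf("beta[%d,2]", seq_len(p)), drop = FALSE]
    s1 <- mat[, "sigma[1]"]; s2 <- mat[, "sigma[2]"]; rho <- mat[, "rho"]
    Xi <- cbind(1, design$X[test, , drop = FALSE])
    for (ii in seq_along(test)) {
      mu <- cbind(b1 %*% Xi[ii, ], b2 %*% Xi[ii, ])
      yrep <- matrix(design$Y[test[ii], ], nrow(mu), 2, byrow = TRUE)
      lppd[test[ii]] <- log_mean_exp(dbinorm_log(yrep, mu, s1, s2, rho))
    }
  }
  structure(list(ic = -2 * sum(lppd), fold_assignment = assign, lppd = lppd,
                 folds = folds),
            class = "kfold_ic")
}

#' @export
print.kfold_ic <- function(x, ...) {
  cat(sprintf("<kfold_ic> %d folds: IC = %.2f (lower = better)\n",
              x$folds, x$ic))
  invisible(x)
}

#' Bayesian R-squared
#'
#' For each posterior draw and response, the variance of the linear
#' predictor over fish divided by that variance plus the draw's residual
#' variance. Summarized by the posterior median per response; the
#' model-level value is the mean of the two responses' medians.
#'
#' @param fit A [fit_linkage()] result.
#' @return List with `per_response` (named medians), `model` (their mean)
#'   and `draws` (draws x 2 matrix).
#' @export
bayes_r2 <- function(fit) {
  lin <- predict(fit, draws_out = TRUE)
  p <- length(fit$predictors)
  r2 <- vapply(seq_len(2), function(r) {
    varmu <- apply(lin[[r]], 1, stats::var)
    sig <- fit$draws[, paste0("sigma_", fit$responses[r])]
    varmu / (varmu + sig^2)
  }, numeric(nrow(fit$draws)))
  colnames(r2) <- fit$responses
  meds <- apply(r2, 2, stats::median)
  list(per_response = meds, model = mean(meds), draws = r2)
}

#' Fit physiology vectors onto an ordination
#'
#' Least-squares projection of each physiological variable onto the
#' retained ordination dimensions (the envfit procedure): the squared
#' multiple correlation measures alignment and significance comes from
#' permuting the variable across fish.
#'
#' @param ordination A `fight_ordination`.
#' @param variables Named data frame or matrix of variables (rows matching
#'   the ordination ids), e.g. blood pH and lactate.
#' @param permutations Number of permutations (default 999).
#' @param seed Optional seed.
#' @return Data frame (class `vector_fit`) with one row per variable:
#'   direction cosines per dimension, `r2` and permutation `p_value`
#'   (never below `1/(permutations + 1)`).
#' @export
envfit_vectors <- function(ordination, variables, permutations = 999,
                           seed = NULL) {
  sc <- ordination$scores
  if (nrow(sc) < 3L) abort_fd("need at least 3 fish", "fd_size_error")
  v <- as.matrix(variables)
  if (nrow(v) != nrow(sc)) abort_fd("variable rows must match ordination ids",
                                    "fd_size_error")
  if (any(apply(v, 2, stats::sd) == 0)) {
    abort_fd("constant variable; vector fit undefined", "fd_degenerate_error")
  }
  ef <- with_seed(seed,
                  vegan::envfit(sc, as.data.frame(v),
                                permutations = permutations))
  arr <- ef$vectors$arrows
  out <- data.frame(variable = rownames(arr), arr,
                    r2 = ef$vectors$r, p_value = ef$vectors$pvals,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("vector_fit", "data.frame")
  out
}

#' Marginal effect of one predictor on the physiology responses
#'
#' Evaluates the posterior of the linear predictor over a grid spanning the
#' observed range of one predictor, holding every other column at its mean
#' (the species indicator at the chinook reference), and back-transforms
#' the predictions to the original physiology scales through the stored
#' inverse normalization. Reported as the posterior median with a 95%
#' credible band.
#'
#' @param fit A [fit_linkage()] result.
#' @param predictor Name of a design column (e.g. `"Dim2"`,
#'   `"water_temp"`).
#' @param grid_size Number of grid points (default 50).
#' @return Data frame with columns `predictor`, `value`, `response`,
#'   `median`, `lower`, `upper` on the original response scales.
#' @export
marginal_effects <- function(fit, predictor, grid_size = 50) {
  X <- fit$design$X
  if (!predictor %in% colnames(X)) {
    abort_fd(sprintf("unknown predictor '%s'", predictor),
             "fd_parameter_error")
  }
  grid <- seq(min(X[, predictor]), max(X[, predictor]),
              length.out = grid_size)
  base <- colMeans(X)
  base["species_coho"] <- 0  # reference level
  Xnew <- matrix(base, grid_size, ncol(X), byrow = TRUE,
                 dimnames = list(NULL, colnames(X)))
  Xnew[, predictor] <- grid
  lin <- predict(fit, newdata = Xnew, draws_out = TRUE)
  resp_map <- c(blood_ph = "blood_ph", lactate = "lactate")
  out <- do.call(rbind, lapply(names(lin), function(r) {
    tr <- fit$design$transforms[[resp_map[[r]]]]
    back <- matrix(predict(tr, as.vector(lin[[r]]), inverse = TRUE),
                   nrow(lin[[r]]), ncol(lin[[r]]))
    data.frame(predictor = predictor, value = grid, response = r,
               median = apply(back, 2, stats::median),
               lower = apply(back, 2, stats::quantile, 0.025),
               upper = apply(back, 2, stats::quantile, 0.975),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlogram of fight, environment and physiology variables
#'
#' Pearson correlations across the eight headline variables: number of
#' bursts, fight duration, mean ActVSum, total effort, water temperature,
#' fork length, lactate and blood pH.
#'
#' @param dataset A [capture_dataset()] with complete physiology.
#' @param metrics Optional [metrics_matrix()] result (recomputed if
#'   omitted).
#' @return Symmetric 8 x 8 correlation matrix with unit diagonal.
#' @export
correlogram <- function(dataset, metrics = NULL) {
  if (is.null(metrics)) metrics <- metrics_matrix(dataset)
  raw <- metrics$raw
  rec <- dataset$records[match(raw$fish_id, dataset$records$fish_id), ]
  tab <- data.frame(n_bursts = raw$n_bursts,
                    fight_duration = raw$fight_duration,
                    mean_actvsum = raw$mean_actvsum,
                    total_effort = raw$total_effort,
                    water_temp = rec$water_temp_c,
                    fork_length = rec$fork_length_cm,
                    lactate = rec$lactate_mmol_l,
                    blood_ph = rec$blood_ph)
  if (any(!is.finite(as.matrix(tab)))) {
    abort_fd("correlogram requires complete cases on all 8 variables",
             "fd_validation_error")
  }
  if (any(vapply(tab, function(x) stats::sd(x) == 0, logical(1)))) {
    abort_fd("degenerate (constant) variable in correlogram",
             "fd_degenerate_error")
  }
  stats::cor(as.matrix(tab))
}
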