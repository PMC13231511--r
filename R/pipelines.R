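# End-to-end comparison of the 13 analysis pipelines: the jerk-summary
# (PCA) pipeline plus the 12 DTW processing combinations (PCoA), each
# feeding Ward clustering with gap-statistic k selection and the Bayesian
# physiology linkage.

#' Enumerate the 13 analysis pipelines
#'
#' The jerk-summary pipeline (PCA of the metric matrix; fight duration as
#' an extra covariate in its linkage model) plus the 12 DTW variants (PCoA
#' of each dissimilarity matrix; no duration covariate, since the
#' sequence-to-sequence alignment already encodes temporal dynamics).
#'
#' @return 13-row data frame: `name`, `variant`, `channels`, `ordination`,
#'   `include_duration`.
#' @export
pipeline_specs <- function() {
  g <- variant_grid()
  tag <- c(raw = "raw", highpass = "hp", derivative = "d1")
  dtw <- data.frame(name = paste(tag[g$variant], g$channels, sep = "_"),
                    variant = g$variant, channels = g$channels,
                    ordination = "pcoa", include_duration = FALSE,
                    stringsAsFactors = FALSE)
  rbind(data.frame(name = "summary", variant = NA_character_,
                   channels = NA_character_, ordination = "pca",
                   include_duration = TRUE, stringsAsFactors = FALSE),
        dtw)
}

#' Default fitting settings
#'
#' Reduced-effort settings (the package default) keep a full 13-pipeline
#' comparison at desk scale; `reduced = FALSE` restores the full settings
#' (4 chains, 3000 warm-up and 1000 retained iterations, 100 gap bootstrap
#' replicates, 999 permutations).
#'
#' @param reduced Use the reduced-effort settings? Default `TRUE`.
#' @param folds K-fold folds (default 10).
#' @return Named list of settings.
#' @export
fit_settings <- function(reduced = TRUE, folds = 10) {
  if (reduced) {
    list(chains = 2, warmup = 500, draws = 500, gap_B = 50,
         permutations = 199, folds = folds)
  } else {
    list(chains = 4, warmup = 3000, draws = 1000, gap_B = 100,
         permutations = 999, folds = folds)
  }
}

#' Run one analysis pipeline end to end
#'
#' Ordination (PCA of summary metrics or PCoA of the DTW dissimilarity for
#' the spec's variant), Ward clustering with gap-statistic selection of k,
#' then the Bayesian physiology linkage with K-fold IC, Bayesian R2 and
#' vector fitting.
#'
#' @param dataset A [capture_dataset()].
#' @param spec One row of [pipeline_specs()] (or a pipeline name).
#' @param settings A [fit_settings()] list.
#' @param seed Master seed; per-stage sub-seeds are derived from it and the
#'   pipeline name, so pipelines do not perturb each other.
#' @param burst_threshold Burst threshold for the summary pipeline.
#' @return List with `row` (one [compare_all()] table row) and `artifacts`
#'   (ordination, clusters, gap profile, fit, kfold, r2, vector fits,
#'   dissimilarity when applicable).
#' @export
run_pipeline <- function(dataset, spec, settings = fit_settings(),
                         seed = 1, burst_threshold = 1.25) {
  if (is.character(spec)) {
    sp <- pipeline_specs()
    spec <- sp[sp$name == spec, ]
    if (nrow(spec) != 1L) abort_fd("unknown pipeline name",
                                   "fd_parameter_error")
  }
  pseed <- sub_seed(seed, spec$name)
  dm <- NULL
  if (spec$ordination == "pca") {
    mm <- metrics_matrix(dataset, threshold = burst_threshold)
    ord <- pca_ordination(mm)
  } else {
    dm <- pairwise_dissimilarity(dataset, spec$variant, spec$channels)
    ord <- pcoa_ordination(dm)
  }
  gp <- gap_statistic(ord, B = settings$gap_B,
                      seed = sub_seed(pseed, "gap"))
  k <- attr(gp, "chosen_k")
  cl <- ward_cluster(ord, k)
  design <- build_design(dataset, ord,
                         include_duration = spec$include_duration)
  fit <- fit_linkage(design, chains = settings$chains,
                     warmup = settings$warmup, draws = settings$draws,
                     seed = sub_seed(pseed, "fit"))
  kf <- kfold_ic(design, folds = settings$folds, chains = settings$chains,
                 warmup = settings$warmup, draws = settings$draws,
                 seed = sub_seed(pseed, "kfold"))
  r2 <- bayes_r2(fit)
  rec <- dataset$records[match(ord$ids, dataset$records$fish_id), ]
  ev <- envfit_vectors(ord, data.frame(blood_ph = rec$blood_ph,
                                       lactate = rec$lactate_mmol_l),
                       permutations = settings$permutations,
                       seed = sub_seed(pseed, "envfit"))
  fmt <- function(x) if (length(x)) paste(x, collapse = "; ") else "none"
  row <- data.frame(
    method = spec$name,
    cumulative_variance_pct = 100 * ord$cumulative_variance_dim1_3,
    kfold_ic = kf$ic,
    bayes_r2 = r2$model,
    significant_dims = fmt(fit$significant_dims),
    significant_covariates = fmt(fit$significant_covariates),
    chosen_k = k,
    stringsAsFactors = FALSE)
  list(row = row,
       artifacts = list(ordination = ord, gap_profile = gp, clusters = cl,
                        design = design, fit = fit, kfold = kf,
                        bayes_r2 = r2, vectors = ev, dissimilarity = dm))
}

#' Compare all 13 pipelines
#'
#' Runs every pipeline on the dataset and assembles the comparison table,
#' sorted by K-fold IC ascending (lower = better out-of-sample
#' prediction). Cumulative variance is reported but never used for
#' ranking. A pipeline failure marks its row `failed` and leaves the
#' others intact.
#'
#' @param dataset A [capture_dataset()].
#' @param settings A [fit_settings()] list.
#' @param seed Master seed fanned out per pipeline.
#' @param burst_threshold Burst threshold for the summary pipeline.
#' @param keep_artifacts Attach the per-pipeline artifact lists?
#' @return Data frame of class `pipeline_comparison`, 13 rows, columns
#'   `method`, `cumulative_variance_pct`, `kfold_ic`, `bayes_r2`,
#'   `significant_dims`, `significant_covariates`, `chosen_k`, `status`.
#' @export
compare_all <- function(dataset, settings = fit_settings(), seed = 1,
                        burst_threshold = 1.25, keep_artifacts = FALSE) {
  specs <- pipeline_specs()
  arts <- list()
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    res <- tryCatch({
      out <- run_pipeline(dataset, sp, settings, seed, burst_threshold)
      if (keep_artifacts) arts[[sp$name]] <<- out$artifacts
      cbind(out$row, status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(method = sp$name, cumulative_variance_pct = NA_real_,
                 kfold_ic = NA_real_, bayes_r2 = NA_real_,
                 significant_dims = NA_character_,
                 significant_covariates = NA_character_,
                 chosen_k = NA_integer_,
                 status = paste0("failed: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  tab <- do.call(rbind, rows)
  if (all(tab$status != "ok")) {
    abort_fd("all pipelines failed", "fd_validation_error")
  }
  tab <- tab[order(is.na(tab$kfold_ic), tab$kfold_ic), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("pipeline_comparison", "data.frame")
  if (keep_artifacts) attr(tab, "artifacts") <- arts
  tab
}

#' @export
print.pipeline_comparison <- function(x, ...) {
  cat(sprintf("<pipeline_comparison> %d pipelines (sorted by K-fold IC)\n",
              nrow(x)))
  show <- as.data.frame(x)
  show$cumulative_variance_pct <- round(show$cumulative_variance_pct, 1)
  show$kfold_ic <- round(show$kfold_ic, 1)
  show$bayes_r2 <- round(show$bayes_r2, 2)
  print.data.frame(show)
  invisible(x)
}

#' Write the standard artifact files for one pipeline run
#'
#' Emits the per-pipeline CSV/JSON artifacts (dissimilarity matrix,
#' ordination scores, gap profile, cluster labels, model summary) under
#' `out_dir`, tagged with the pipeline name.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- result$artifacts
  name <- result$row$method
  paths <- character(0)
  pth <- function(f) file.path(out_dir, f)
  if (!is.null(a$dissimilarity)) {
    p <- pth(sprintf("dissimilarity_%s.csv", name))
    write_dissimilarity(a$dissimilarity, p)
    paths <- c(paths, p)
  }
  sc <- data.frame(fish_id = a$ordination$ids, a$ordination$scores,
                   check.names = FALSE)
  p <- pth(sprintf("ordination_scores_%s.csv", name))
  utils::write.csv(sc, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- pth(sprintf("gap_profile_%s.csv", name))
  utils::write.csv(as.data.frame(a$gap_profile), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- pth(sprintf("clusters_%s.csv", name))
  utils::write.csv(data.frame(fish_id = a$clusters$ids,
                              cluster = a$clusters$labels), p,
                   row.names = FALSE)
  paths <- c(paths, p)
  p <- pth(sprintf("model_summary_%s.json", name))
  jsonlite::write_json(
    list(summary = a$fit$summary,
         rho = a$fit$rho,
         kfold_ic = a$kfold$ic,
         bayes_r2 = as.list(a$bayes_r2$per_response),
         bayes_r2_model = a$bayes_r2$model,
         significant_dims = a$fit$significant_dims,
         significant_covariates = a$fit$significant_covariates,
         normalization = "ordered-quantile (r - 0.5)/n",
         pcoa_convention = "negative eigenvalues dropped"),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
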