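#' Count discrete activity bursts by run-length encoding
#'
#' A burst is a maximal run of consecutive samples whose ActVSum strictly
#' exceeds the threshold (default 1.25 g s^-1, a conservative choice pending
#' field validation). Runs shorter than `min_run` samples are ignored.
#'
#' @param actvsum ActVSum sequence, g s^-1.
#' @param threshold Burst threshold, g s^-1 (default 1.25).
#' @param min_run Minimum run length in samples counted as a burst
#'   (default 1).
#' @return Number of bursts.
#' @export
count_bursts <- function(actvsum, threshold = 1.25, min_run = 1L) {
  if (length(actvsum) == 0L) abort_fd("empty sequence", "fd_size_error")
  r <- rle(actvsum > threshold)
  sum(r$values & r$lengths >= min_run)
}

#' Early/late fight intensity and their ratio
#'
#' Early intensity is the mean ActVSum over the first third of the fight and
#' late intensity the mean over the final third; thirds are taken on sample
#' counts as `floor(n/3)` samples (minimum 1). Their ratio summarizes how
#' effort shifted over the fight (most fish fight harder early).
#'
#' @param actvsum ActVSum sequence, length >= 3.
#' @return Named vector `early`, `late`, `ratio` (g s^-1, g s^-1, unitless).
#' @export
phase_intensities <- function(actvsum) {
  n <- length(actvsum)
  if (n < 3L) abort_fd("need at least 3 samples", "fd_size_error")
  m <- max(1L, floor(n / 3))
  early <- mean(actvsum[seq_len(m)])
  late <- mean(actvsum[(n - m + 1):n])
  if (late == 0) abort_fd("late intensity is zero; ratio undefined",
                          "fd_degenerate_error")
  c(early = early, late = late, ratio = early / late)
}

#' Fatigue index: post-peak decline rate of ActVSum
#'
#' Finds the first global maximum of ActVSum and, when at least three
#' samples follow it, fits an ordinary-least-squares line to ActVSum versus
#' sample index from the peak (inclusive) to the end. The index is the
#' decline rate `max(0, -slope)` in g s^-1 per sample step; series with
#' fewer than three post-peak samples return 0.
#'
#' @param actvsum ActVSum sequence.
#' @return Non-negative decline rate per sample step.
#' @export
fatigue_index <- function(actvsum) {
  n <- length(actvsum)
  if (n == 0L) abort_fd("empty sequence", "fd_size_error")
  p <- which.max(actvsum)  # first global maximum
  if (n - p < 3L) return(0)
  idx <- p:n
  slope <- stats::cov(idx, actvsum[idx]) / stats::var(idx)
  max(0, -slope)
}

#' Pairwise Pearson correlations between the jerk axes
#'
#' The degree of synchronization across the X, Y and Z axes during a fight;
#' high values indicate directed, coordinated movement while low values
#' indicate erratic directional changes.
#'
#' @param trace A [jerk_trace()] with at least 3 samples and no constant
#'   axis.
#' @return Named vector `r_xy`, `r_yz`, `r_xz`, `mean_r`.
#' @export
inter_axis_correlations <- function(trace) {
  if (length(trace$times) < 3L) abort_fd("need >= 3 samples", "fd_size_error")
  axes <- list(x = trace$jerk_x, y = trace$jerk_y, z = trace$jerk_z)
  if (any(vapply(axes, function(a) stats::sd(a) == 0, logical(1)))) {
    abort_fd("constant jerk axis; correlation undefined",
             "fd_degenerate_error")
  }
  r <- c(r_xy = stats::cor(axes$x, axes$y),
         r_yz = stats::cor(axes$y, axes$z),
         r_xz = stats::cor(axes$x, axes$z))
  c(r, mean_r = mean(r))
}

#' Summary fight metrics for one fish
#'
#' Computes the per-fish fight summary: mean ActVSum and its coefficient of
#' variation, total effort (cumulative ActVSum over all samples), number of
#' discrete bursts, early and late intensity with their ratio, and the
#' fatigue index.
#'
#' @param trace A [jerk_trace()] with >= 3 samples.
#' @param duration Fight duration in s from the timed angling event
#'   (hook-up to netting); defaults to the trace time span plus one cadence.
#' @param threshold Burst threshold passed to [count_bursts()].
#' @param min_run Minimum burst run length in samples.
#' @return One-row data frame of metrics.
#' @export
fight_metrics <- function(trace, duration = NULL, threshold = 1.25,
                          min_run = 1L) {
  a <- trace$actvsum
  if (length(a) < 3L) abort_fd("trace too short for metrics", "fd_size_error")
  if (is.null(duration)) {
    duration <- trace$times[length(trace$times)] + trace$cadence
  }
  mu <- mean(a)
  if (mu == 0) abort_fd("mean ActVSum is zero; CV undefined",
                        "fd_degenerate_error")
  ph <- phase_intensities(a)
  data.frame(
    fish_id = trace$fish_id,
    fight_duration = duration,
    mean_actvsum = mu,
    cv_actvsum = stats::sd(a) / mu,
    total_effort = sum(a),
    n_bursts = count_bursts(a, threshold, min_run),
    early_intensity = unname(ph["early"]),
    late_intensity = unname(ph["late"]),
    early_late_ratio = unname(ph["ratio"]),
    fatigue_index = fatigue_index(a),
    stringsAsFactors = FALSE)
}

pca_metric_cols <- c("mean_actvsum", "cv_actvsum", "total_effort", "n_bursts",
                     "early_intensity", "late_intensity", "fatigue_index")

#' Fish-by-metric matrix for ordination and clustering
#'
#' Assembles the seven summary metrics for every fish and z-standardizes
#' each column. Fight duration is computed and kept as a side column but is
#' excluded from the matrix fed to PCA because it correlates strongly with
#' the other metrics.
#'
#' @param dataset A [capture_dataset()].
#' @param threshold Burst threshold, g s^-1.
#' @param min_run Minimum burst run length in samples.
#' @return Object of class `fight_metrics_matrix` with elements `z` (fish x
#'   7 z-scored matrix), `raw` (unscaled metrics incl. fight duration) and
#'   `fight_duration` (named vector).
#' @export
metrics_matrix <- function(dataset, threshold = 1.25, min_run = 1L) {
  rec <- dataset$records
  rows <- lapply(names(dataset$traces), function(id) {
    fight_metrics(dataset$traces[[id]],
                  duration = rec$fight_duration_s[rec$fish_id == id],
                  threshold = threshold, min_run = min_run)
  })
  raw <- do.call(rbind, rows)
  z <- sapply(pca_metric_cols, function(cn) {
    if (length(unique(raw[[cn]])) < 2L) {
      abort_fd(sprintf("metric '%s' is constant across fish", cn),
               "fd_degenerate_error")
    }
    zscore(raw[[cn]])
  })
  rownames(z) <- raw$fish_id
  structure(list(z = z, raw = raw,
                 fight_duration = stats::setNames(raw$fight_duration,
                                                  raw$fish_id)),
            class = "fight_metrics_matrix")
}

#' @export
print.fight_metrics_matrix <- function(x, ...) {
  cat(sprintf("<fight_metrics_matrix> %d fish x %d z-scored metrics\n",
              nrow(x$z), ncol(x$z)))
  print(round(x$raw[, -1], 3))
  invisible(x)
}
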