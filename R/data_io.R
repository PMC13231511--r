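#' Estimate body mass from fork length and girth
#'
#' Salmon body mass is estimated from the length--girth relationship
#' \eqn{Mass = FL \times girth^2 / 27120} with fork length and girth in cm
#' and mass in kg.
#'
#' @param fork_length Fork length in cm (snout to fork of the tail).
#' @param girth Girth in cm. Both arguments are vectorised.
#' @return Estimated body mass in kg.
#' @examples
#' estimate_mass(80, 40)  # ~4.72 kg
#' @export
estimate_mass <- function(fork_length, girth) {
  if (any(!is.finite(fork_length)) || any(!is.finite(girth)) ||
      any(fork_length <= 0) || any(girth <= 0)) {
    abort_fd("fork_length and girth must be positive and finite",
             "fd_domain_error")
  }
  fork_length * girth^2 / 27120
}

#' Convert tag-scale jerk to SI units
#'
#' The tag logs jerk in \eqn{g\,s^{-1}}; true jerk in \eqn{m\,s^{-3}} is
#' obtained by multiplying by standard gravitational acceleration. The
#' conversion is never applied implicitly anywhere in the package.
#'
#' @param x Jerk values in \eqn{g\,s^{-1}}.
#' @param g Gravitational constant, m s^-2.
#' @return Jerk in \eqn{m\,s^{-3}}.
#' @export
jerk_to_si <- function(x, g = 9.81) x * g

#' Construct a single-fish jerk trace
#'
#' A `jerk_trace` holds one fish's line-mounted tri-axial jerk recording:
#' times in seconds relative to hook-up, the three jerk axes (g s^-1) and the
#' tag's activity vector sum (ActVSum, bounded 0--2 g s^-1), all on a uniform
#' logging cadence (2 s for the tags emulated here).
#'
#' @param fish_id Fish identifier (scalar character).
#' @param times Strictly increasing, uniformly spaced times in seconds.
#' @param jerk_x,jerk_y,jerk_z Per-axis jerk, g s^-1.
#' @param actvsum Activity vector sum, g s^-1, within [0, 2].
#' @param cadence Sampling interval in s; inferred from the median time step
#'   when `NULL`.
#' @param tol Relative tolerance on uniform spacing (default 1%).
#' @return An object of class `jerk_trace`.
#' @export
jerk_trace <- function(fish_id, times, jerk_x, jerk_y, jerk_z, actvsum,
                       cadence = NULL, tol = 0.01) {
  n <- length(times)
  lens <- c(n, length(jerk_x), length(jerk_y), length(jerk_z), length(actvsum))
  if (length(unique(lens)) != 1L || n < 2L) {
    abort_fd("all trace channels must share the same length >= 2",
             "fd_size_error")
  }
  vals <- c(times, jerk_x, jerk_y, jerk_z, actvsum)
  if (any(!is.finite(vals))) {
    abort_fd(sprintf("trace '%s' contains missing or non-finite values",
                     fish_id), "fd_validation_error")
  }
  steps <- diff(times)
  if (any(steps <= 0)) {
    abort_fd(sprintf("times for fish '%s' must be strictly increasing",
                     fish_id), "fd_cadence_error")
  }
  if (is.null(cadence)) cadence <- stats::median(steps)
  if (any(abs(steps - cadence) > tol * cadence)) {
    bad <- which(abs(steps - cadence) > tol * cadence)[1]
    abort_fd(sprintf(
      "fish '%s': non-uniform sampling at step %d (%.4g s vs cadence %.4g s)",
      fish_id, bad, steps[bad], cadence), "fd_cadence_error")
  }
  if (any(actvsum < 0 | actvsum > 2)) {
    rows <- which(actvsum < 0 | actvsum > 2)
    abort_fd(sprintf("fish '%s': actvsum outside [0, 2] at rows %s",
                     fish_id, paste(rows, collapse = ", ")),
             "fd_range_error")
  }
  structure(
    list(fish_id = as.character(fish_id),
         times = as.numeric(times) - times[1],
         jerk_x = as.numeric(jerk_x), jerk_y = as.numeric(jerk_y),
         jerk_z = as.numeric(jerk_z), actvsum = as.numeric(actvsum),
         cadence = as.numeric(cadence)),
    class = "jerk_trace")
}

#' @export
print.jerk_trace <- function(x, ...) {
  cat(sprintf("<jerk_trace> fish %s: %d samples at %.3g s cadence (%.0f s)\n",
              x$fish_id, length(x$times), x$cadence,
              x$times[length(x$times)]))
  cat(sprintf("  mean ActVSum %.3f g/s, range [%.3f, %.3f]\n",
              mean(x$actvsum), min(x$actvsum), max(x$actvsum)))
  invisible(x)
}

#' @export
length.jerk_trace <- function(x) length(x$times)

trace_cols <- c("fish_id", "time_s", "jerk_x", "jerk_y", "jerk_z", "actvsum")

#' Read jerk trace CSV files
#'
#' Reads one CSV file (or every `*.csv` in a directory) with columns
#' `fish_id,time_s,jerk_x,jerk_y,jerk_z,actvsum` and returns one validated
#' [jerk_trace()] per fish. Rows are sorted by time before validation, so row
#' order in the file does not matter.
#'
#' @param path A CSV file or a directory of CSV files.
#' @return Named list of `jerk_trace` objects (names are fish ids).
#' @export
read_traces <- function(path) {
  if (length(path) != 1L || !file.exists(path)) {
    abort_fd(sprintf("path '%s' does not exist", path), "fd_schema_error")
  }
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0L) {
    abort_fd("no CSV files found", "fd_schema_error")
  }
  tabs <- lapply(files, utils::read.csv, stringsAsFactors = FALSE)
  tab <- do.call(rbind, tabs)
  missing <- setdiff(trace_cols, names(tab))
  if (length(missing) > 0L) {
    abort_fd(sprintf("trace CSV missing column(s): %s",
                     paste(missing, collapse = ", ")), "fd_schema_error")
  }
  traces <- lapply(split(tab, tab$fish_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    jerk_trace(d$fish_id[1], d$time_s, d$jerk_x, d$jerk_y, d$jerk_z,
               d$actvsum)
  })
  traces[order(names(traces))]
}

#' Read the fish metadata / physiology table
#'
#' Expects columns `fish_id, species, fork_length_cm, girth_cm, water_temp_c,
#' blood_ph, lactate_mmol_l` and optionally `fight_duration_s`. Body mass is
#' filled in through [estimate_mass()] whenever girth is present. `girth_cm`,
#' `blood_ph` and `lactate_mmol_l` may be empty (NA).
#'
#' @param path CSV file path.
#' @return A data frame with one validated row per fish and a `body_mass_kg`
#'   column.
#' @export
read_fish_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "species", "fork_length_cm", "girth_cm",
            "water_temp_c", "blood_ph", "lactate_mmol_l")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    abort_fd(sprintf("fish table missing column(s): %s",
                     paste(missing, collapse = ", ")), "fd_schema_error")
  }
  if (anyDuplicated(tab$fish_id)) {
    dup <- unique(tab$fish_id[duplicated(tab$fish_id)])
    abort_fd(sprintf("duplicate fish_id: %s", paste(dup, collapse = ", ")),
             "fd_duplicate_error")
  }
  bad_sp <- setdiff(unique(tab$species), c("chinook", "coho"))
  if (length(bad_sp) > 0L) {
    abort_fd(sprintf("unknown species label(s): %s",
                     paste(bad_sp, collapse = ", ")), "fd_validation_error")
  }
  if (any(!is.finite(tab$fork_length_cm)) || any(tab$fork_length_cm <= 0)) {
    abort_fd("fork_length_cm must be positive", "fd_validation_error")
  }
  if (any(tab$water_temp_c <= 0 | tab$water_temp_c >= 40)) {
    abort_fd("water_temp_c outside plausible range (0, 40)",
             "fd_validation_error")
  }
  tab$body_mass_kg <- NA_real_
  has_girth <- !is.na(tab$girth_cm)
  if (any(has_girth)) {
    tab$body_mass_kg[has_girth] <- estimate_mass(
      tab$fork_length_cm[has_girth], tab$girth_cm[has_girth])
  }
  tab <- tab[order(tab$fish_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Assemble a capture dataset
#'
#' Binds the per-fish jerk traces to the fish metadata table. The two key
#' sets must match exactly; ordination and clustering require at least three
#' fish.
#'
#' @param traces Named list of [jerk_trace()] objects.
#' @param records Fish table as returned by [read_fish_table()].
#' @return An object of class `capture_dataset`.
#' @export
capture_dataset <- function(traces, records) {
  ids_t <- sort(names(traces))
  ids_r <- sort(as.character(records$fish_id))
  if (!identical(ids_t, ids_r)) {
    abort_fd(sprintf(
      "trace/record fish ids differ (only in traces: %s; only in records: %s)",
      paste(setdiff(ids_t, ids_r), collapse = ", "),
      paste(setdiff(ids_r, ids_t), collapse = ", ")), "fd_validation_error")
  }
  records <- records[order(records$fish_id), , drop = FALSE]
  rownames(records) <- NULL
  if (!"fight_duration_s" %in% names(records)) {
    records$fight_duration_s <- vapply(traces[ids_t], function(tr) {
      tr$times[length(tr$times)] + tr$cadence
    }, numeric(1))
  }
  if (any(records$fight_duration_s <= 0)) {
    abort_fd("fight_duration_s must be positive", "fd_validation_error")
  }
  structure(list(traces = traces[ids_t], records = records),
            class = "capture_dataset")
}

#' @export
print.capture_dataset <- function(x, ...) {
  cat(sprintf("<capture_dataset> %d fish (%s)\n", length(x$traces),
              paste(table(x$records$species), names(table(x$records$species)),
                    collapse = ", ")))
  cat(sprintf("  fight durations %.0f-%.0f s; water temp %.1f-%.1f C\n",
              min(x$records$fight_duration_s),
              max(x$records$fight_duration_s),
              min(x$records$water_temp_c), max(x$records$water_temp_c)))
  invisible(x)
}

n_fish <- function(dataset) length(dataset$traces)

#' Write a dissimilarity matrix to CSV
#'
#' Writes a labelled square CSV (fish ids as header row and first column).
#' Values survive a write/read round trip to at least 12 significant digits.
#'
#' @param m A [pairwise_dissimilarity()] result or a labelled symmetric
#'   numeric matrix with zero diagonal.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(m, path) {
  vals <- if (inherits(m, "dtw_dissimilarity")) m$values else as.matrix(m)
  if (is.null(rownames(vals)) || nrow(vals) < 1L) {
    abort_fd("dissimilarity matrix must be labelled and non-empty (>= 1 fish)",
             "fd_integrity_error")
  }
  if (nrow(vals) != ncol(vals) ||
      max(abs(vals - t(vals))) > 1e-9 || any(abs(diag(vals)) > 1e-12)) {
    abort_fd("dissimilarity matrix must be symmetric with zero diagonal",
             "fd_integrity_error")
  }
  out <- data.frame(fish_id = rownames(vals),
                    format(vals, digits = 17, scientific = TRUE,
                           trim = TRUE),
                    check.names = FALSE)
  names(out) <- c("fish_id", colnames(vals))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dissimilarity matrix written by [write_dissimilarity()]
#'
#' @param path CSV path.
#' @return Labelled symmetric numeric matrix.
#' @export
read_dissimilarity <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  mode(vals) <- "numeric"
  dimnames(vals) <- list(ids, names(tab)[-1])
  if (max(abs(vals - t(vals))) > 1e-9) {
    abort_fd("matrix on disk is not symmetric", "fd_integrity_error")
  }
  vals
}
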