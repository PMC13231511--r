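#' Recompute the activity vector sum from the three jerk axes
#'
#' Element-wise vectorial magnitude \eqn{\sqrt{x^2+y^2+z^2}} clipped to the
#' tag scale [0, 2] g s^-1. The tags log their own ActVSum channel; this
#' recomputation is used only where that channel is absent (synthetic data).
#'
#' @param jerk_x,jerk_y,jerk_z Equal-length jerk sequences, g s^-1.
#' @return ActVSum sequence, g s^-1, in [0, 2].
#' @export
compute_actvsum <- function(jerk_x, jerk_y, jerk_z) {
  if (length(jerk_x) != length(jerk_y) || length(jerk_y) != length(jerk_z)) {
    abort_fd("jerk axes must have equal length", "fd_size_error")
  }
  pmin(sqrt(jerk_x^2 + jerk_y^2 + jerk_z^2), 2)
}

#' High-pass filter a jerk series by rolling-mean subtraction
#'
#' Subtracts a centered rolling mean taken over all samples within
#' `window / 2` seconds of each point (inclusive); the window shrinks at the
#' edges. At the default 4-s window and 2-s cadence this is a 3-point
#' centered mean, which removes the low-frequency fight envelope and
#' isolates the high-frequency burst content. A constant series maps to
#' zeros and the output has the same length as the input.
#'
#' @param series Numeric series.
#' @param cadence Sampling interval, s.
#' @param window Filter window, s (default 4); must be at least `cadence`.
#' @return Filtered series, same length.
#' @export
highpass <- function(series, cadence, window = 4) {
  if (window < cadence) {
    abort_fd("window must be >= cadence", "fd_parameter_error")
  }
  n <- length(series)
  if (n < 2L) abort_fd("series must have length >= 2", "fd_size_error")
  half <- floor(window / 2 / cadence + 1e-9)
  mu <- vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  series - mu
}

#' First forward difference of a series (snap, up to the g convention)
#'
#' Differencing a jerk axis yields snap, the fourth derivative of position.
#' Forward differences scaled by the cadence give a per-second rate of
#' length `n - 1`.
#'
#' @param series Numeric series, length >= 2.
#' @param cadence Sampling interval, s.
#' @return Difference series of length `length(series) - 1`.
#' @export
first_derivative <- function(series, cadence) {
  if (length(series) < 2L) {
    abort_fd("series must have length >= 2", "fd_size_error")
  }
  diff(series) / cadence
}

fd_variants <- c("raw", "highpass", "derivative")
fd_channels <- c("X", "Y", "Z", "XYZ")

#' Enumerate the 12 DTW processing combinations
#'
#' Three transforms (raw, 4-s high-pass, first derivative) crossed with the
#' three individual axes plus the multivariate X/Y/Z combination.
#'
#' @return A 12-row data frame with columns `variant` and `channels`.
#' @export
variant_grid <- function() {
  g <- expand.grid(channels = fd_channels, variant = fd_variants,
                   stringsAsFactors = FALSE)
  g[, c("variant", "channels")]
}

#' Build one processed series for a fish
#'
#' Applies a processing variant to the requested channel(s) of a jerk trace.
#' For `channels = "XYZ"` the transform is applied per axis and the result
#' assembled into a sequence of 3-vectors (an `n x 3` matrix).
#'
#' @param trace A [jerk_trace()].
#' @param variant One of `"raw"`, `"highpass"`, `"derivative"`.
#' @param channels One of `"X"`, `"Y"`, `"Z"`, `"XYZ"`.
#' @param window High-pass window in s (default 4).
#' @return An object of class `processed_series`.
#' @export
make_variant <- function(trace, variant, channels, window = 4) {
  if (!variant %in% fd_variants) {
    abort_fd(sprintf("unknown variant '%s'", variant), "fd_parameter_error")
  }
  if (!channels %in% fd_channels) {
    abort_fd(sprintf("unknown channels '%s'", channels), "fd_parameter_error")
  }
  axes <- switch(channels, X = "jerk_x", Y = "jerk_y", Z = "jerk_z",
                 XYZ = c("jerk_x", "jerk_y", "jerk_z"))
  cols <- lapply(axes, function(a) {
    x <- trace[[a]]
    switch(variant,
           raw = x,
           highpass = highpass(x, trace$cadence, window),
           derivative = first_derivative(x, trace$cadence))
  })
  values <- if (length(cols) == 1L) cols[[1]] else do.call(cbind, cols)
  structure(list(fish_id = trace$fish_id, variant = variant,
                 channels = channels, values = values,
                 cadence = trace$cadence),
            class = "processed_series")
}

#' @export
print.processed_series <- function(x, ...) {
  n <- if (is.matrix(x$values)) nrow(x$values) else length(x$values)
  cat(sprintf("<processed_series> fish %s, %s/%s, %d steps\n",
              x$fish_id, x$variant, x$channels, n))
  invisible(x)
}

#' z-standardize a numeric column
#'
#' Centers to mean zero and scales to unit sample standard deviation
#' (denominator n - 1).
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Standardized vector.
#' @export
zscore <- function(x) {
  if (length(unique(x)) < 2L) {
    abort_fd("column is constant; cannot z-standardize",
             "fd_degenerate_error")
  }
  (x - mean(x)) / stats::sd(x)
}

#' Rank-based inverse-normal (ordered-quantile) response normalization
#'
#' Maps the value with rank r among n to \eqn{\Phi^{-1}((r - 0.5)/n)}, with
#' ties sharing averaged ranks. The returned object carries an invertible
#' mapping: the inverse interpolates monotonically between the observed
#' (value, quantile) pairs and extrapolates linearly beyond the tails, so
#' model predictions can be carried back to the original response scale.
#'
#' @param x Numeric vector, length >= 3.
#' @return Object of class `orq_transform` with elements `scores` (the
#'   normalized values, same order as `x`) and `n`. Use [predict.orq_transform()]
#'   to map new values either way.
#' @export
normalize_response <- function(x) {
  n <- length(x)
  if (n < 3L) abort_fd("need at least 3 observations", "fd_size_error")
  if (any(!is.finite(x))) abort_fd("missing values in response",
                                   "fd_validation_error")
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 0.5) / n)
  ux <- sort(unique(x))
  uz <- stats::qnorm((rank(x, ties.method = "average")[match(ux, x)] - 0.5) / n)
  structure(list(scores = z, n = n, x_knots = ux, z_knots = uz),
            class = "orq_transform")
}

#' Map values through (or back through) an ordered-quantile transform
#'
#' @param object An [normalize_response()] result.
#' @param newdata Values to map.
#' @param inverse If `TRUE`, map normalized scores back to the response
#'   scale; otherwise map response values to the normal scale.
#' @param ... Unused.
#' @return Mapped numeric vector.
#' @export
predict.orq_transform <- function(object, newdata, inverse = FALSE, ...) {
  xk <- object$x_knots
  zk <- object$z_knots
  if (length(xk) == 1L) {
    abort_fd("degenerate transform (single unique value)",
             "fd_degenerate_error")
  }
  if (inverse) interp_extrap(zk, xk, newdata) else interp_extrap(xk, zk, newdata)
}

# Monotone linear interpolation with linear extrapolation continuing the
# terminal segments.
interp_extrap <- function(xs, ys, xout) {
  k <- length(xs)
  y <- stats::approx(xs, ys, xout = xout, rule = 2)$y
  lo <- xout < xs[1]
  hi <- xout > xs[k]
  if (any(lo)) {
    s <- (ys[2] - ys[1]) / (xs[2] - xs[1])
    y[lo] <- ys[1] + s * (xout[lo] - xs[1])
  }
  if (any(hi)) {
    s <- (ys[k] - ys[k - 1]) / (xs[k] - xs[k - 1])
    y[hi] <- ys[k] + s * (xout[hi] - xs[k])
  }
  y
}
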