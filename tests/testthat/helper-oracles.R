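# Independent oracles and fixture builders used across the suite. These are
# deliberately written against the definitions, not against the package
# implementations they check.

# --- trace / dataset fixtures -----------------------------------------------

make_trace <- function(id = "f1", n = 10, cadence = 2, seed = NULL,
                       actvsum = NULL) {
  build <- function() {
    x <- rnorm(n, 0, 0.5)
    y <- rnorm(n, 0, 0.5)
    z <- rnorm(n, 0, 0.5)
    a <- if (is.null(actvsum)) pmin(sqrt(x^2 + y^2 + z^2), 2) else actvsum
    jerk_trace(id, seq(0, by = cadence, length.out = n), x, y, z, a,
               cadence = cadence)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_scenario())
    cache
  }
})

small_settings <- function() {
  list(chains = 2, warmup = 300, draws = 300, gap_B = 20, permutations = 99,
       folds = 5)
}

# --- rolling-mean oracle for the high-pass filter ---------------------------

oracle_highpass <- function(x, cadence, window) {
  n <- length(x)
  t <- (seq_len(n) - 1) * cadence
  vapply(seq_len(n), function(i) {
    x[i] - mean(x[abs(t - t[i]) <= window / 2 + 1e-12])
  }, numeric(1))
}

# --- DTW oracles ------------------------------------------------------------

local_cost <- function(a, b) {
  am <- if (is.matrix(a)) a else matrix(a, ncol = 1)
  bm <- if (is.matrix(b)) b else matrix(b, ncol = 1)
  d <- matrix(0, nrow(am), nrow(bm))
  for (k in seq_len(ncol(am))) d <- d + outer(am[, k], bm[, k], `-`)^2
  sqrt(d)
}

delannoy <- function(n, m) {
  D <- matrix(1, n + 1, m + 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    D[i, j] <- D[i - 1, j] + D[i, j - 1] + D[i - 1, j - 1]
  }
  D[n + 1, m + 1]
}

# Full enumeration of every monotone warping path by depth-first search;
# diagonal steps weighted double, start cell costs d[1,1].
dtw_oracle_enum <- function(a, b) {
  d <- local_cost(a, b)
  n <- nrow(d); m <- ncol(d)
  best <- Inf
  rec <- function(i, j, acc) {
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1, j + 1, acc + 2 * d[i + 1, j + 1])
    if (i < n) rec(i + 1, j, acc + d[i + 1, j])
    if (j < m) rec(i, j + 1, acc + d[i, j + 1])
    invisible(NULL)
  }
  rec(1, 1, d[1, 1])
  best
}

# Top-down recursive minimisation over predecessor cells (memoised);
# independent of the package's bottom-up table fill.
dtw_oracle_recursive <- function(a, b) {
  d <- local_cost(a, b)
  n <- nrow(d); m <- ncol(d)
  memo <- matrix(NA_real_, n, m)
  f <- function(i, j) {
    if (i == 1 && j == 1) return(d[1, 1])
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- Inf
    if (i > 1) v <- min(v, f(i - 1, j) + d[i, j])
    if (j > 1) v <- min(v, f(i, j - 1) + d[i, j])
    if (i > 1 && j > 1) v <- min(v, f(i - 1, j - 1) + 2 * d[i, j])
    memo[i, j] <<- v
    v
  }
  f(n, m)
}

dtw_oracle <- function(a, b, enum_limit = 20000) {
  la <- if (is.matrix(a)) nrow(a) else length(a)
  lb <- if (is.matrix(b)) nrow(b) else length(b)
  if (delannoy(la - 1, lb - 1) <= enum_limit) {
    dtw_oracle_enum(a, b)
  } else {
    dtw_oracle_recursive(a, b)
  }
}

# --- Ward (Lance-Williams, un-squared distances) oracle ---------------------

ward_oracle_heights <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bv <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (ii < jj) {
          v <- dm[active[ii], active[jj]]
          if (v < bv) { bv <- v; best <- c(active[ii], active[jj]) }
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- bv
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k != i && k != j) {
        nk <- sizes[k]
        dm[i, k] <- dm[k, i] <-
          ((ni + nk) * dm[i, k] + (nj + nk) * dm[j, k] - nk * bv) /
          (ni + nj + nk)
      }
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# --- textbook Pearson correlation -------------------------------------------

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
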