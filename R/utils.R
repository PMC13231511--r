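# Internal helpers shared across modules.

# Classed conditions so callers and tests can discriminate failure modes.
abort_fd <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fightdyn_error", "error")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# restores the caller's .Random.seed. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_fd("`seed` must be a single integer or NULL", "fd_parameter_error")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed from a master seed and a label, kept below 2^31 so it
# is always a valid R integer. Adding a pipeline never shifts another's seed.
sub_seed <- function(master, label) {
  codes <- utf8ToInt(as.character(label))
  h <- as.double(master) %% 2147483587
  for (cc in codes) h <- (h * 131 + cc) %% 2147483587
  as.integer(h + 1)
}

# Log-density of a bivariate normal with sds (s1, s2) and correlation rho.
# `y` and `mu` are length-2; vectorised over rows when matrices.
dbinorm_log <- function(y, mu, s1, s2, rho) {
  z1 <- (y[, 1] - mu[, 1]) / s1
  z2 <- (y[, 2] - mu[, 2]) / s2
  omr2 <- 1 - rho^2
  -log(2 * pi) - log(s1) - log(s2) - 0.5 * log(omr2) -
    (z1^2 - 2 * rho * z1 * z2 + z2^2) / (2 * omr2)
}

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# Split-chain Gelman-Rubin statistic. `x` is an iterations x chains matrix of
# draws of one parameter; each chain is split in half before the B/W ratio.
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2L) return(NA_real_)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}
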