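# Internal numerical helpers shared across the samplers.

# Standard-normal draws truncated to (a, Inf), standardized scale.
# Inverse-CDF in log space so that draws stay finite and on the correct
# side even for a > 6 (survival probabilities underflow otherwise).
rtnorm_lower <- function(a, u = stats::runif(length(a))) {
  # S(z) = u * S(a) solved on the log scale
  log_sa <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(log(u) + log_sa, lower.tail = FALSE, log.p = TRUE)
  pmax(z, a) # guard against rounding just below the bound
}

# Standard-normal draws truncated to (-Inf, b).
rtnorm_upper <- function(b, u = stats::runif(length(b))) {
  log_fb <- stats::pnorm(b, log.p = TRUE)
  z <- stats::qnorm(log(u) + log_fb, log.p = TRUE)
  pmin(z, b)
}

# One-sided truncated normal with general mean/sd, lower = 0 side chosen
# by `positive`: TRUE -> (0, Inf), FALSE -> (-Inf, 0].
rtnorm_signed <- function(mean, sd = 1, positive, u = stats::runif(length(mean))) {
  a <- (0 - mean) / sd
  z <- ifelse(positive, rtnorm_lower(a, u), rtnorm_upper(a, u))
  mean + sd * z
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic child seed from a master seed and a stage name, so every
# stage of the pipeline draws from its own reproducible stream.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h * 362437 + 1013904223) %% 2147483647)
}

# Split R-hat (rank-free, Stan-style split PSRF) on a draws matrix with a
# chain id per row. Each chain is split in half before the between/within
# variance comparison.
split_rhat <- function(x, chain) {
  pieces <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    n <- length(v)
    if (n < 4L) return(NA_real_)
    h <- n %/% 2L
    pieces <- c(pieces, list(v[seq_len(h)], v[(n - h + 1L):n]))
  }
  m <- length(pieces)
  n <- min(lengths(pieces))
  pieces <- lapply(pieces, function(v) v[seq_len(n)])
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  # raw split-PSRF can fall below 1 by O(1/n) sampling noise; floor at 1
  max(sqrt(((n - 1) / n * W + B / n) / W), 1)
}

# Effective sample size via Geyer's initial positive sequence on the
# chain-pooled autocovariances (chains assumed same length).
ess_basic <- function(x, chain) {
  chains <- split(x, chain)
  n <- min(lengths(chains))
  chains <- lapply(chains, function(v) v[seq_len(n)])
  m <- length(chains)
  if (n < 4L) return(NA_real_)
  acov <- function(v) {
    v <- v - mean(v)
    stats::convolve(v, v, conj = TRUE, type = "open")[n:(2L * n - 1L)] / n
  }
  ac <- Reduce(`+`, lapply(chains, acov)) / m
  var0 <- ac[1L] * n / (n - 1)
  if (var0 <= 0) return(m * n)
  rho <- ac / ac[1L]
  # pair consecutive lags; stop at first non-positive pair sum
  tau <- 1
  t <- 2L
  while (t + 1L <= n) {
    pair <- rho[t] + rho[t + 1L]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  max(m * n / tau, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
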