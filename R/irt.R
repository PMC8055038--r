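#' MCMC settings
#'
#' @param iterations total iterations per chain.
#' @param burn_in iterations discarded per chain (must be < iterations).
#' @param thin thinning interval (>= 1).
#' @param chains number of chains (>= 1).
#' @param seed master seed; every chain derives its own stream from it.
#' @return object of class `mcmc_control`.
#' @export
mcmc_control <- function(iterations = 5000L, burn_in = 2500L, thin = 1L,
                         chains = 4L, seed = 1L) {
  stopifnot(burn_in < iterations, thin >= 1, chains >= 1, iterations >= 2)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 chains = as.integer(chains), seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Prior settings for the item response model
#'
#' Identification comes from `theta ~ N(0, 1)` (location/scale) and from
#' the positivity constraint on every discrimination (removes the
#' reflection `(theta, beta) <-> (-theta, -beta)`, justified by the
#' deprivation-direction coding of the items). Pooled model: `alpha_j ~
#' N(0, alpha_sd^2)`, `beta_j ~ N+(0, beta_sd^2)`. Hierarchical model:
#' province-level parameters are drawn around per-item hypermeans with
#' per-item variances, `mu_j ~ N(0, hyper_mean_sd^2)` and `tau_j^2 ~
#' Inv-Gamma(tau_shape, tau_scale)` for conjugacy.
#'
#' @param alpha_sd,beta_sd pooled-prior standard deviations.
#' @param hyper_mean_sd standard deviation of the hypermean prior.
#' @param tau_shape,tau_scale inverse-gamma hyperprior on tau^2.
#' @return object of class `irt_prior`.
#' @export
irt_prior <- function(alpha_sd = 2, beta_sd = 2, hyper_mean_sd = 2,
                      tau_shape = 2, tau_scale = 1) {
  stopifnot(alpha_sd > 0, beta_sd > 0, hyper_mean_sd > 0,
            tau_shape > 0, tau_scale > 0)
  structure(list(alpha_sd = alpha_sd, beta_sd = beta_sd,
                 hyper_mean_sd = hyper_mean_sd,
                 tau_shape = tau_shape, tau_scale = tau_scale),
            class = "irt_prior")
}

# ---- Gibbs full conditionals (data augmentation, Albert-Chib style) ----

#' Draw latent utilities given parameters
#'
#' Each utility `x*_ij` is drawn from `N(alpha[j,k] + beta[j,k] *
#' theta[i], 1)` truncated to (0, Inf) when the observed response is 1 and
#' to (-Inf, 0] when it is 0.
#'
#' @param X N x J binary matrix (complete).
#' @param alpha,beta J x K parameter matrices.
#' @param theta length-N latent traits.
#' @param k_idx length-N province index (1..K).
#' @param seed optional; if given, seeds the RNG first (step functions are
#'   otherwise consumed inside a running chain's stream).
#' @return N x J matrix of utilities.
#' @export
step_latent_utilities <- function(X, alpha, beta, theta, k_idx = rep(1L, nrow(X)),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta <- t(alpha[, k_idx, drop = FALSE]) +
    t(beta[, k_idx, drop = FALSE]) * theta
  a <- -eta                      # standardized truncation bound at zero
  z <- numeric(length(eta))
  pos <- X == 1L
  u <- stats::runif(length(eta))
  z[pos] <- rtnorm_lower(a[pos], u[pos])
  z[!pos] <- rtnorm_upper(a[!pos], u[!pos])
  out <- eta + z
  dim(out) <- dim(eta)
  out
}

#' Draw latent traits given utilities and item parameters
#'
#' Conjugate update under the `theta_i ~ N(0, 1)` prior: the full
#' conditional is `N(V_k * sum_j beta[j,k] (x*_ij - alpha[j,k]), V_k)` with
#' `V_k = 1 / (1 + sum_j beta[j,k]^2)`.
#'
#' @inheritParams step_latent_utilities
#' @param x_star N x J utility matrix.
#' @return length-N vector of traits.
#' @export
step_theta <- function(x_star, alpha, beta, k_idx = rep(1L, nrow(x_star)),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond <- theta_conditional(x_star, alpha, beta, k_idx)
  stats::rnorm(length(cond$mean), cond$mean, sqrt(cond$var))
}

# Full-conditional moments of theta (exported draws go through this).
theta_conditional <- function(x_star, alpha, beta,
                              k_idx = rep(1L, nrow(x_star))) {
  V <- 1 / (1 + colSums(beta^2))           # per province
  ba <- colSums(beta * alpha)
  s <- rowSums(x_star * t(beta[, k_idx, drop = FALSE])) - ba[k_idx]
  list(mean = V[k_idx] * s, var = V[k_idx])
}

# Full conditional moments for one item-province cell, unit residual
# variance, independent normal priors on (alpha, beta).
#   alpha | beta: precision n + 1/va, mean ((sum y - beta sum th) + ma/va)/prec
#   beta  | alpha: precision sum th^2 + 1/vb,
#                  mean ((sum th*y - alpha sum th) + mb/vb)/prec, truncated > 0
cond_alpha <- function(n, sum_th, sum_y, beta, prior_mean, prior_var) {
  prec <- unname(n + 1 / prior_var)
  c(mean = unname(((sum_y - beta * sum_th) + prior_mean / prior_var) / prec),
    var = 1 / prec)
}

cond_beta <- function(sum_th, sum_th2, sum_ty, alpha, prior_mean, prior_var) {
  prec <- unname(sum_th2 + 1 / prior_var)
  c(mean = unname(((sum_ty - alpha * sum_th) + prior_mean / prior_var) / prec),
    var = 1 / prec)
}

# Joint (unconstrained) bivariate normal posterior of (alpha, beta) for one
# item-province cell: precision = X'X + prior precision, with X = (1, theta).
item_param_posterior <- function(n, sum_th, sum_th2, sum_y, sum_ty,
                                 mean_a, var_a, mean_b, var_b) {
  P11 <- n + 1 / var_a
  P22 <- sum_th2 + 1 / var_b
  P12 <- sum_th
  det <- P11 * P22 - P12^2
  C11 <- P22 / det; C22 <- P11 / det; C12 <- -P12 / det
  h1 <- unname(sum_y + mean_a / var_a)
  h2 <- unname(sum_ty + mean_b / var_b)
  list(mean = c(C11 * h1 + C12 * h2, C12 * h1 + C22 * h2),
       cov = matrix(c(C11, C12, C12, C22), 2, 2))
}

#' Draw item parameters given utilities and traits
#'
#' For each item j and province k, `(alpha, beta)` follow the posterior of
#' a linear regression of the utilities on `(1, theta)` with unit residual
#' variance and independent normal priors: a bivariate normal truncated to
#' the half-plane `beta > 0`. The update samples that distribution exactly
#' and independently of the current values: `beta` from the
#' positive-truncated marginal of the joint posterior, then `alpha` from
#' its Gaussian conditional given the drawn `beta`. (An independence draw
#' per cell; nothing mixes slowly even for rare items.)
#'
#' @param x_star N x J utilities.
#' @param theta length-N traits.
#' @param k_idx length-N province index.
#' @param alpha,beta current J x K values.
#' @param prior list of J x K matrices `mean_alpha`, `var_alpha`,
#'   `mean_beta`, `var_beta`.
#' @param seed optional seed.
#' @return list with new `alpha` and `beta` (J x K).
#' @export
step_item_params <- function(x_star, theta, k_idx, alpha, beta, prior,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- ncol(x_star); K <- ncol(alpha)
  grp <- if (is.factor(k_idx)) k_idx else factor(k_idx, levels = seq_len(K))
  n_k <- tabulate(as.integer(grp), K)
  if (any(n_k < 2L)) stopf("every province needs at least 2 individuals")
  # per-province sufficient statistics of the regression on (1, theta)
  S1 <- as.numeric(rowsum(theta, grp))
  S2 <- as.numeric(rowsum(theta * theta, grp))
  if (any(S2 - S1^2 / n_k < 1e-12))
    stopf("degenerate design: all traits equal within a province")
  Y0 <- t(rowsum(x_star, grp))                # J x K
  Y1 <- t(rowsum(x_star * theta, grp))
  new_a <- alpha; new_b <- beta
  for (k in seq_len(K)) for (j in seq_len(J)) {
    po <- item_param_posterior(n_k[k], S1[k], S2[k], Y0[j, k], Y1[j, k],
                               prior$mean_alpha[j, k], prior$var_alpha[j, k],
                               prior$mean_beta[j, k], prior$var_beta[j, k])
    b <- rtnorm_signed(po$mean[2], sqrt(po$cov[2, 2]), positive = TRUE)
    cond_m <- po$mean[1] + po$cov[1, 2] / po$cov[2, 2] * (b - po$mean[2])
    cond_v <- po$cov[1, 1] - po$cov[1, 2]^2 / po$cov[2, 2]
    new_a[j, k] <- stats::rnorm(1, cond_m, sqrt(cond_v))
    new_b[j, k] <- b
  }
  list(alpha = new_a, beta = new_b)
}

#' Draw per-item hypermeans and hypervariances (hierarchical model)
#'
#' For each item j, given the K province-level values `v_jk` and the
#' current `tau2_j`: the hypermean is drawn from its conjugate normal
#' conditional under a `N(mean0, sd0^2)` prior, then `tau2_j` from
#' `Inv-Gamma(shape + K/2, scale + SS/2)` with `SS = sum_k (v_jk - mu_j)^2`.
#'
#' @param values J x K matrix of province-level parameter values.
#' @param tau2 length-J current hypervariances.
#' @param mean0,sd0 hypermean prior.
#' @param shape,scale inverse-gamma hyperprior on tau^2.
#' @param seed optional seed.
#' @return list with `mu` (length J) and `tau2` (length J).
#' @export
step_hyper <- function(values, tau2, mean0 = 0, sd0 = 2, shape = 2, scale = 1,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hc <- hyper_mu_conditional(values, tau2, mean0, sd0)
  mu <- stats::rnorm(length(hc$mean), hc$mean, sqrt(hc$var))
  ht <- hyper_tau2_conditional(values, mu, shape, scale)
  tau2_new <- 1 / stats::rgamma(length(ht$scale), ht$shape, ht$scale)
  list(mu = mu, tau2 = tau2_new)
}

# Fixed per-cell proposal scales for the marginal item-parameter refresh:
# lower Cholesky factors of 2.38^2/2 times the inverse observed (Fisher +
# prior) information of the probit likelihood, evaluated at crude initial
# estimates. State-independent, so the random-walk proposal is symmetric.
refresh_proposals <- function(X, k_idx, alpha, beta, theta,
                              prior_var_alpha, prior_var_beta) {
  J <- ncol(X); K <- ncol(alpha)
  out <- matrix(NA_real_, J * K, 3)
  for (k in seq_len(K)) for (j in seq_len(J)) {
    rows <- k_idx == k
    th <- theta[rows]
    eta <- pmin(pmax(alpha[j, k] + beta[j, k] * th, -6), 6)
    w <- stats::dnorm(eta)^2 / (stats::pnorm(eta) * stats::pnorm(-eta))
    I11 <- sum(w) + 1 / prior_var_alpha[j, k]
    I12 <- sum(w * th)
    I22 <- sum(w * th^2) + 1 / prior_var_beta[j, k]
    det <- I11 * I22 - I12^2
    sc <- 2.38^2 / 2
    c11 <- sc * I22 / det; c12 <- -sc * I12 / det; c22 <- sc * I11 / det
    L11 <- sqrt(c11); L21 <- c12 / L11
    L22 <- sqrt(max(c22 - L21^2, 1e-12))
    out[(k - 1L) * J + j, ] <- c(L11, L21, L22)
  }
  out
}

# Marginal refresh of the item parameters: one symmetric random-walk
# Metropolis step per (item, province) cell targeting the cell posterior
# with the latent utilities integrated out (Bernoulli-probit likelihood).
# Valid as a partially collapsed update because x* is redrawn from its
# full conditional at the start of the next cycle before any reuse; it
# breaks the long x*-item-parameter autocorrelation of extreme-prevalence
# cells. Consumes 2 normals + 1 uniform per cell, always.
step_item_refresh <- function(X, theta, k_idx, alpha, beta, prior,
                              prop_chol, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- ncol(X); K <- ncol(alpha)
  for (k in seq_len(K)) {
    rows <- which(k_idx == k)
    th <- theta[rows]
    for (j in seq_len(J)) {
      x <- X[rows, j]
      z <- stats::rnorm(2)
      u <- stats::runif(1)
      L <- prop_chol[(k - 1L) * J + j, ]
      a1 <- alpha[j, k] + L[1] * z[1]
      b1 <- beta[j, k] + L[2] * z[1] + L[3] * z[2]
      if (b1 <= 0) next
      sgn <- ifelse(x == 1L, 1, -1)
      ll0 <- sum(stats::pnorm(sgn * (alpha[j, k] + beta[j, k] * th),
                              log.p = TRUE))
      ll1 <- sum(stats::pnorm(sgn * (a1 + b1 * th), log.p = TRUE))
      lp0 <- -0.5 * (alpha[j, k] - prior$mean_alpha[j, k])^2 /
        prior$var_alpha[j, k] -
        0.5 * (beta[j, k] - prior$mean_beta[j, k])^2 / prior$var_beta[j, k]
      lp1 <- -0.5 * (a1 - prior$mean_alpha[j, k])^2 /
        prior$var_alpha[j, k] -
        0.5 * (b1 - prior$mean_beta[j, k])^2 / prior$var_beta[j, k]
      if (log(u) < (ll1 + lp1) - (ll0 + lp0)) {
        alpha[j, k] <- a1
        beta[j, k] <- b1
      }
    }
  }
  list(alpha = alpha, beta = beta)
}

# Generalized Gibbs recentering move: sample a translation c along the
# group orbit theta -> theta - c, alpha -> alpha + beta * c (likelihood
# invariant) from the target density restricted to the orbit, which is
# Gaussian: precision N + sum(beta^2 / v_alpha), mean proportional to
# sum(theta) - sum(beta * (alpha - m_alpha) / v_alpha). Removes the slow
# common-location drift between the traits and the intercepts.
step_recenter <- function(theta, alpha, beta, mean_alpha, var_alpha,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- length(theta) + sum(beta^2 / var_alpha)
  mu <- (sum(theta) - sum(beta * (alpha - mean_alpha) / var_alpha)) / P
  c0 <- stats::rnorm(1, mu, sqrt(1 / P))
  list(theta = theta - c0, alpha = alpha + beta * c0, shift = c0)
}

# Companion scale move: Metropolis along the multiplicative orbit
# theta -> theta / s, beta -> s * beta (likelihood invariant), targeting
# the orbit density pi(T_s x) |Jacobian| with Haar measure ds/s; in
# t = log s the log-density is
#   -e^{-2t} sum(theta^2)/2 - sum((e^t beta - m)^2 / v)/2 + (JK - N) t.
# One symmetric random-walk proposal per call (fixed RNG consumption).
step_rescale <- function(theta, beta, mean_beta, var_beta, prop_sd = 0.1,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sum_th2 <- sum(theta^2)
  npar <- length(beta) - length(theta)
  logp <- function(t) {
    s <- exp(t)
    -0.5 * exp(-2 * t) * sum_th2 -
      0.5 * sum((s * beta - mean_beta)^2 / var_beta) + npar * t
  }
  t1 <- stats::rnorm(1, 0, prop_sd)
  u <- stats::runif(1)
  if (log(u) < logp(t1) - logp(0)) {
    s <- exp(t1)
    list(theta = theta / s, beta = beta * s, accepted = TRUE, scale = s)
  } else {
    list(theta = theta, beta = beta, accepted = FALSE, scale = 1)
  }
}

# Conjugate conditional of the per-item hypermean.
hyper_mu_conditional <- function(values, tau2, mean0 = 0, sd0 = 2) {
  K <- ncol(values)
  post_var <- 1 / (K / tau2 + 1 / sd0^2)
  list(mean = post_var * (K * rowMeans(values) / tau2 + mean0 / sd0^2),
       var = post_var)
}

# Inverse-gamma conditional of the per-item hypervariance.
hyper_tau2_conditional <- function(values, mu, shape = 2, scale = 1) {
  list(shape = shape + ncol(values) / 2,
       scale = scale + rowSums((values - mu)^2) / 2)
}

# ---- fitting front end ----

#' Fit the individual-level deprivation index model
#'
#' Fits a two-parameter probit item response model to binary
#' deprivation-direction items by a data-augmentation Gibbs sampler. Two
#' variants: `"pooled"` (item parameters common across provinces) and
#' `"hierarchical"` (item parameters vary by province around per-item
#' hypermeans, letting the data decide how much provinces differ). The
#' latent trait `theta_i` is the deprivation index.
#'
#' Each Gibbs cycle draws latent utilities, traits, item parameters and
#' (hierarchical variant) hyperparameters from their exact full
#' conditionals. Chains start from probit-transformed item prevalences
#' (`alpha`), unit discriminations and standardized row sums (`theta`),
#' jittered per chain, and are deterministic given `mcmc$seed`.
#'
#' @param data data.frame of complete-case items (0/1), plus optional
#'   `province` and `id` columns.
#' @param items item column names (default: `items` attribute of `data`).
#' @param variant `"hierarchical"` or `"pooled"`. Pooled ignores province
#'   labels.
#' @param prior an [irt_prior()].
#' @param mcmc an [mcmc_control()].
#' @param verbose print per-chain progress.
#' @return object of class `depriv_irt` with posterior draws, chain ids,
#'   data, and convergence diagnostics (split R-hat and effective sample
#'   size per item parameter).
#' @seealso [posterior_index()], [waic()], [icc_curve()],
#'   [discrimination_table()]
#' @export
irt_deprivation <- function(data, items = attr(data, "items"),
                            variant = c("hierarchical", "pooled"),
                            prior = irt_prior(), mcmc = mcmc_control(),
                            verbose = FALSE) {
  variant <- match.arg(variant)
  if (is.null(items)) items <- setdiff(names(data), c("id", "province", "outcome"))
  X <- as.matrix(data[, items, drop = FALSE])
  storage.mode(X) <- "integer"
  if (anyNA(X)) stopf("irt_deprivation requires complete cases; run complete_cases() first")
  if (!all(X %in% 0:1)) stopf("items must be coded 0/1")
  zero_var <- items[apply(X, 2, function(v) length(unique(v)) < 2)]
  if (length(zero_var))
    stopf("item(s) with zero variance: %s", paste(zero_var, collapse = ", "))
  N <- nrow(X); J <- ncol(X)
  if (variant == "pooled" || is.null(data$province)) {
    provinces <- "all"
    k_idx <- rep(1L, N)
  } else {
    provinces <- sort(unique(as.character(data$province)))
    k_idx <- match(as.character(data$province), provinces)
  }
  K <- length(provinces)
  kfac <- factor(k_idx, levels = seq_len(K))

  pr <- prior
  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  S <- n_keep * mcmc$chains
  draws <- list(
    alpha = array(NA_real_, c(S, J, K), dimnames = list(NULL, items, provinces)),
    beta = array(NA_real_, c(S, J, K), dimnames = list(NULL, items, provinces)),
    theta = matrix(NA_real_, S, N)
  )
  hierarchical <- variant == "hierarchical"
  if (hierarchical) {
    for (nm in c("mu_alpha", "tau2_alpha", "mu_beta", "tau2_beta"))
      draws[[nm]] <- matrix(NA_real_, S, J, dimnames = list(NULL, items))
  }
  chain_id <- rep(seq_len(mcmc$chains), each = n_keep)

  prev <- vapply(seq_len(K), function(k) {
    colMeans(X[k_idx == k, , drop = FALSE])
  }, numeric(J))
  dim(prev) <- c(J, K)
  prev <- pmin(pmax(prev, 0.02), 0.98)

  theta_crude <- as.numeric(scale(rowSums(X)))
  theta_crude[!is.finite(theta_crude)] <- 0
  prop_chol <- refresh_proposals(X, k_idx, stats::qnorm(prev) * sqrt(2),
                                 matrix(1, J, K), theta_crude,
                                 matrix(pr$alpha_sd^2, J, K),
                                 matrix(pr$beta_sd^2, J, K))

  for (ch in seq_len(mcmc$chains)) {
    set.seed(child_seed(mcmc$seed, paste0("irt-chain-", ch)))
    jit <- if (ch == 1L) 0 else 0.5
    alpha <- stats::qnorm(prev) * sqrt(2) + jit * stats::rnorm(J * K)
    beta <- matrix(pmax(1 + jit * stats::rnorm(J * K), 0.1), J, K)
    theta <- as.numeric(scale(rowSums(X))) + jit * stats::rnorm(N)
    theta[!is.finite(theta)] <- 0
    if (hierarchical) {
      mu_a <- rowMeans(alpha); tau2_a <- rep(1, J)
      mu_b <- rowMeans(beta); tau2_b <- rep(1, J)
    } else {
      mu_a <- mu_b <- tau2_a <- tau2_b <- numeric(J)
    }
    res <- .gibbs_chain(
      X, k_idx, K, alpha, beta, theta, hierarchical,
      matrix(0, J, K), matrix(pr$alpha_sd^2, J, K),
      matrix(0, J, K), matrix(pr$beta_sd^2, J, K),
      mu_a, tau2_a, mu_b, tau2_b,
      pr$hyper_mean_sd, pr$tau_shape, pr$tau_scale, prop_chol,
      mcmc$iterations, mcmc$burn_in, mcmc$thin)
    rows <- ((ch - 1L) * n_keep + 1L):(ch * n_keep)
    draws$alpha[rows, , ] <- res$alpha
    draws$beta[rows, , ] <- res$beta
    draws$theta[rows, ] <- res$theta
    if (hierarchical) {
      draws$mu_alpha[rows, ] <- res$mu_alpha
      draws$tau2_alpha[rows, ] <- res$tau2_alpha
      draws$mu_beta[rows, ] <- res$mu_beta
      draws$tau2_beta[rows, ] <- res$tau2_beta
    }
    if (verbose) message(sprintf("chain %d/%d done", ch, mcmc$chains))
  }

  fit <- structure(list(
    draws = draws, chain = chain_id, items = items, provinces = provinces,
    variant = variant, prior = prior, mcmc = mcmc,
    data = list(X = X, k_idx = k_idx, province = provinces[k_idx],
                id = data$id %||% seq_len(N)),
    call = match.call()
  ), class = "depriv_irt")
  fit$diagnostics <- irt_diagnostics(fit)
  fit
}

# Split R-hat and ESS for every item parameter (and hypermeans).
irt_diagnostics <- function(fit) {
  J <- length(fit$items); K <- length(fit$provinces)
  rows <- list()
  for (j in seq_len(J)) for (k in seq_len(K)) {
    for (par in c("alpha", "beta")) {
      v <- fit$draws[[par]][, j, k]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = sprintf("%s[%s,%s]", par, fit$items[j], fit$provinces[k]),
        rhat = split_rhat(v, fit$chain), ess = ess_basic(v, fit$chain),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(fit$draws$mu_alpha)) {
    for (j in seq_len(J)) for (par in c("mu_alpha", "mu_beta")) {
      v <- fit$draws[[par]][, j]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = sprintf("%s[%s]", par, fit$items[j]),
        rhat = split_rhat(v, fit$chain), ess = ess_basic(v, fit$chain),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.depriv_irt <- function(x, ...) {
  cat(sprintf("Deprivation index model (%s probit 2PL)\n", x$variant))
  cat(sprintf("  %d persons, %d items, %d province group(s)\n",
              nrow(x$data$X), length(x$items), length(x$provinces)))
  cat(sprintf("  %d retained draws from %d chain(s); max split R-hat %.3f\n",
              length(x$chain), x$mcmc$chains, max(x$diagnostics$rhat)))
  invisible(x)
}

#' @export
coef.depriv_irt <- function(object, ...) {
  list(alpha = apply(object$draws$alpha, c(2, 3), mean),
       beta = apply(object$draws$beta, c(2, 3), mean))
}

#' @export
summary.depriv_irt <- function(object, ...) {
  out <- list(variant = object$variant,
              items = discrimination_table(object),
              index = posterior_index(object),
              diagnostics = object$diagnostics)
  class(out) <- "summary.depriv_irt"
  out
}

#' @export
print.summary.depriv_irt <- function(x, ...) {
  cat(sprintf("Deprivation index model (%s)\n\n", x$variant))
  cat("Item parameters (ranked by posterior mean discrimination):\n")
  print(x$items, digits = 3, row.names = FALSE)
  cat(sprintf("\nIndex: %d persons, posterior-mean range [%.2f, %.2f]\n",
              nrow(x$index), min(x$index$theta_mean), max(x$index$theta_mean)))
  cat(sprintf("Max split R-hat: %.3f; min ESS: %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' Posterior summaries of the per-person deprivation index
#'
#' @param fit a `depriv_irt` object.
#' @return data.frame: `id`, `province`, `theta_mean`, `theta_sd`, `q2.5`,
#'   `q50`, `q97.5` (one row per person, suitable for boxplot export).
#' @export
posterior_index <- function(fit) {
  th <- fit$draws$theta
  qs <- apply(th, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  data.frame(id = fit$data$id, province = fit$data$province,
             theta_mean = colMeans(th), theta_sd = apply(th, 2, stats::sd),
             q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
             stringsAsFactors = FALSE)
}

#' Pointwise posterior log-likelihood of the item responses
#'
#' Entry (s, (i,j)) is the log-likelihood of response `x_ij` at draw s,
#' conditional on that draw's `theta_i`:
#' `log Phi(eta)` if x = 1, `log(1 - Phi(eta))` if x = 0, with
#' `eta = alpha[j,k] + beta[j,k] theta_i`, evaluated via the log-CDF so
#' saturated cells do not underflow.
#'
#' @param fit a `depriv_irt` object.
#' @param draw_idx optional subset of draw indices (rows).
#' @return S x (N*J) matrix; columns ordered person-major (all items of
#'   person 1, then person 2, ...).
#' @export
pointwise_loglik <- function(fit, draw_idx = NULL) {
  X <- fit$data$X; k_idx <- fit$data$k_idx
  N <- nrow(X); J <- ncol(X)
  idx <- draw_idx %||% seq_along(fit$chain)
  out <- matrix(NA_real_, length(idx), N * J)
  th <- fit$draws$theta[idx, , drop = FALSE]
  for (j in seq_len(J)) {
    # S x N linear predictor for item j, signed by the observed response
    a <- fit$draws$alpha[idx, j, ]; dim(a) <- c(length(idx), length(fit$provinces))
    b <- fit$draws$beta[idx, j, ]; dim(b) <- c(length(idx), length(fit$provinces))
    eta <- a[, k_idx, drop = FALSE] + b[, k_idx, drop = FALSE] * th
    sgn <- rep(ifelse(X[, j] == 1L, 1, -1), each = length(idx))
    out[, seq(j, N * J, by = J)] <- stats::pnorm(sgn * eta, log.p = TRUE)
  }
  out
}

#' Posterior draws in long format
#'
#' One row per retained draw and parameter (`chain`, `iter`, `parameter`,
#' `value`), covering the item parameters and, for hierarchical fits, the
#' per-item hypermeans and hypervariances. Trait draws are excluded by
#' default (one column per person makes the long format explode); set
#' `include_theta = TRUE` to add them.
#'
#' @param fit a `depriv_irt` object.
#' @param include_theta also emit the per-person trait draws.
#' @return data.frame suitable for CSV export.
#' @export
draws_long <- function(fit, include_theta = FALSE) {
  S <- length(fit$chain)
  iter <- stats::ave(seq_len(S), fit$chain, FUN = seq_along)
  blocks <- list()
  for (par in c("alpha", "beta")) {
    for (j in seq_along(fit$items)) for (k in seq_along(fit$provinces)) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        chain = fit$chain, iter = iter,
        parameter = sprintf("%s[%s,%s]", par, fit$items[j], fit$provinces[k]),
        value = fit$draws[[par]][, j, k], stringsAsFactors = FALSE)
    }
  }
  for (par in c("mu_alpha", "tau2_alpha", "mu_beta", "tau2_beta")) {
    if (is.null(fit$draws[[par]])) next
    for (j in seq_along(fit$items))
      blocks[[length(blocks) + 1L]] <- data.frame(
        chain = fit$chain, iter = iter,
        parameter = sprintf("%s[%s]", par, fit$items[j]),
        value = fit$draws[[par]][, j], stringsAsFactors = FALSE)
  }
  if (include_theta) {
    for (i in seq_len(ncol(fit$draws$theta)))
      blocks[[length(blocks) + 1L]] <- data.frame(
        chain = fit$chain, iter = iter,
        parameter = sprintf("theta[%s]", fit$data$id[i]),
        value = fit$draws$theta[, i], stringsAsFactors = FALSE)
  }
  do.call(rbind, blocks)
}

#' Simulate item responses from the posterior (posterior predictive)
#'
#' @param object a `depriv_irt` fit.
#' @param nsim number of replicated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` binary N x J matrices, each generated from one
#'   posterior draw.
#' @export
simulate.depriv_irt <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(object$chain)
  J <- length(object$items); K <- length(object$provinces)
  k_idx <- object$data$k_idx; N <- nrow(object$data$X)
  picks <- sample.int(S, nsim, replace = nsim > S)
  lapply(picks, function(s) {
    a <- object$draws$alpha[s, , ]; dim(a) <- c(J, K)
    b <- object$draws$beta[s, , ]; dim(b) <- c(J, K)
    eta <- t(a[, k_idx, drop = FALSE]) +
      t(b[, k_idx, drop = FALSE]) * object$draws$theta[s, ]
    m <- matrix(as.integer(stats::runif(N * J) < stats::pnorm(eta)), N, J)
    colnames(m) <- object$items
    m
  })
}

#' @export
plot.depriv_irt <- function(x, type = c("index", "icc"), item = NULL, ...) {
  type <- match.arg(type)
  if (type == "index") {
    idx <- posterior_index(x)
    graphics::boxplot(theta_mean ~ province, data = idx,
                      ylab = "posterior-mean deprivation index",
                      xlab = "province", ...)
  } else {
    item <- item %||% x$items[1]
    grid <- seq(-3, 3, length.out = 61)
    cols <- seq_along(x$provinces) + 1
    first <- TRUE
    for (k in seq_along(x$provinces)) {
      cv <- icc_curve(x, item, x$provinces[k], grid)
      if (first) {
        graphics::plot(grid, cv$prob_mean, type = "l", col = cols[k],
                       ylim = c(0, 1), xlab = "deprivation index",
                       ylab = sprintf("P(%s = 1)", item), ...)
        first <- FALSE
      } else graphics::lines(grid, cv$prob_mean, col = cols[k])
    }
    graphics::legend("bottomright", legend = x$provinces, col = cols, lty = 1)
  }
  invisible(x)
}
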