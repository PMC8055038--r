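#' Bayesian logistic regression for visit non-attendance
#'
#' Posterior for a logistic regression under independent `N(0, prior_sd^2)`
#' priors on intercept and coefficients, sampled by random-walk Metropolis
#' with a proposal covariance adapted during burn-in (sample covariance of
#' the chain so far, scaled by 2.38^2/d) and frozen afterwards. Chains
#' start at the maximum-likelihood solution; perfect separation triggers a
#' warning (the prior regularizes and sampling proceeds).
#'
#' Odds-ratio point estimates are the posterior mean of the exponentiated
#' draws (not the exponentiated posterior mean), with 2.5/97.5% quantile
#' credible intervals.
#'
#' @param y binary 0/1 outcome vector (both classes required).
#' @param x covariate matrix/data.frame (N x p) or vector.
#' @param prior_sd prior standard deviation (default 2.5, weakly
#'   informative for binary/unit-scale covariates).
#' @param mcmc an [mcmc_control()].
#' @return object of class `depriv_logit` with coefficient draws, chain
#'   ids, OR summary table, acceptance rate and data.
#' @export
bayes_logistic <- function(y, x, prior_sd = 2.5, mcmc = mcmc_control(chains = 2L)) {
  y <- as.integer(y)
  if (!all(y %in% 0:1)) stopf("y must be binary 0/1")
  if (length(unique(y)) < 2L) stopf("y has a single class; model unidentified")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!all(is.finite(x))) stopf("covariates must be finite")
  N <- nrow(x); p <- ncol(x)
  if (length(y) != N) stopf("y and x disagree on N")
  if (N <= p + 1L) stopf("need N > p")
  Xd <- cbind(`(Intercept)` = 1, x)
  d <- p + 1L

  sep_warn <- FALSE
  start <- tryCatch(
    withCallingHandlers(
      stats::glm.fit(Xd, y, family = stats::binomial())$coefficients,
      warning = function(w) {
        if (grepl("fitted probabilities", conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) rep(0, d))
  if (sep_warn)
    warning("possible perfect separation; the prior regularizes and sampling proceeds")
  start[!is.finite(start)] <- 0
  start <- pmin(pmax(start, -10), 10)

  log_post <- function(b) {
    eta <- drop(Xd %*% b)
    sum(stats::plogis(ifelse(y == 1L, eta, -eta), log.p = TRUE)) -
      0.5 * sum(b^2) / prior_sd^2
  }

  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  draws <- matrix(NA_real_, n_keep * mcmc$chains, d,
                  dimnames = list(NULL, colnames(Xd)))
  chain_id <- rep(seq_len(mcmc$chains), each = n_keep)
  acc_total <- 0L

  for (ch in seq_len(mcmc$chains)) {
    set.seed(child_seed(mcmc$seed, paste0("logit-chain-", ch)))
    b <- start + 0.1 * stats::rnorm(d) * (ch > 1L)
    lp <- log_post(b)
    prop_chol <- diag(0.1 / sqrt(d), d)
    hist_b <- matrix(NA_real_, mcmc$burn_in, d)
    s_out <- (ch - 1L) * n_keep
    for (it in seq_len(mcmc$iterations)) {
      cand <- b + drop(stats::rnorm(d) %*% prop_chol)
      lp_cand <- log_post(cand)
      if (log(stats::runif(1)) < lp_cand - lp) {
        b <- cand; lp <- lp_cand
        if (it > mcmc$burn_in) acc_total <- acc_total + 1L
      }
      if (it <= mcmc$burn_in) {
        hist_b[it, ] <- b
        if (it %% 100L == 0L && it >= 200L) {
          cv <- stats::cov(hist_b[seq_len(it), , drop = FALSE]) +
            diag(1e-8, d)
          prop_chol <- chol(2.38^2 / d * cv)
        }
      } else if ((it - mcmc$burn_in) %% mcmc$thin == 0L) {
        s_out <- s_out + 1L
        draws[s_out, ] <- b
      }
    }
  }

  or_draws <- exp(draws[, -1L, drop = FALSE])
  or <- data.frame(
    covariate = colnames(x),
    or_mean = colMeans(or_draws),
    ci_lo = apply(or_draws, 2, stats::quantile, 0.025, names = FALSE),
    ci_hi = apply(or_draws, 2, stats::quantile, 0.975, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(draws = draws, chain = chain_id, or = or,
                 y = y, x = x, prior_sd = prior_sd, mcmc = mcmc,
                 acceptance = acc_total / (mcmc$chains *
                   (mcmc$iterations - mcmc$burn_in)),
                 separation_warning = sep_warn),
            class = "depriv_logit")
}

#' @export
print.depriv_logit <- function(x, ...) {
  cat(sprintf("Bayesian logistic regression (N = %d, %d covariate(s); acceptance %.2f)\n",
              length(x$y), ncol(x$x), x$acceptance))
  cat("Odds ratios (posterior mean of exponentiated draws, 95% CrI):\n")
  print(x$or, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
coef.depriv_logit <- function(object, ...) colMeans(object$draws)

#' @export
summary.depriv_logit <- function(object, ...) {
  rh <- apply(object$draws, 2, split_rhat, chain = object$chain)
  list(or = object$or, coef_mean = colMeans(object$draws), rhat = rh,
       acceptance = object$acceptance)
}

#' @rdname waic
#' @export
waic.depriv_logit <- function(object, ...) {
  eta <- object$x %*% t(object$draws[, -1L, drop = FALSE])
  eta <- sweep(eta, 2, object$draws[, 1L], `+`)       # N x S
  sgn <- ifelse(object$y == 1L, 1, -1)
  ll <- t(stats::plogis(sgn * eta, log.p = TRUE))     # S x N
  waic.default(ll)
}

#' Univariable odds-ratio table
#'
#' Fits one single-covariate Bayesian logistic regression per column and
#' stacks the OR summaries (the layout of a univariable analysis table:
#' typically an index row plus one row per component). A covariate whose
#' fit fails is reported with NA estimates; the rest are unaffected.
#'
#' @param y binary outcome.
#' @param covariates data.frame/matrix of covariates.
#' @param prior_sd,mcmc passed to [bayes_logistic()].
#' @return data.frame: `covariate`, `or_mean`, `ci_lo`, `ci_hi`.
#' @export
univariable_table <- function(y, covariates, prior_sd = 2.5,
                              mcmc = mcmc_control(chains = 2L)) {
  covariates <- as.data.frame(covariates)
  rows <- lapply(names(covariates), function(nm) {
    fit <- tryCatch(
      bayes_logistic(y, stats::setNames(covariates[nm], nm),
                     prior_sd = prior_sd, mcmc = mcmc),
      error = function(e) NULL)
    if (is.null(fit))
      data.frame(covariate = nm, or_mean = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, stringsAsFactors = FALSE)
    else fit$or
  })
  do.call(rbind, rows)
}

#' Index-only versus all-components outcome models
#'
#' Fits the outcome on (a) the scalar deprivation index alone and (b) all
#' component indicators jointly, computes both WAICs on the same rows, and
#' applies the substantial-difference rule (threshold 5).
#'
#' @param y binary outcome.
#' @param index per-person scalar index (plug-in posterior mean of theta).
#' @param components N x J matrix of the binary component indicators.
#' @param prior_sd,mcmc passed to [bayes_logistic()].
#' @return object of class `index_comparison`: both fits, both
#'   `waic_result`s, and the `waic_comparison`.
#' @export
compare_index_vs_components <- function(y, index, components, prior_sd = 2.5,
                                        mcmc = mcmc_control(chains = 2L)) {
  components <- as.matrix(components)
  stopifnot(length(index) == length(y), nrow(components) == length(y))
  fit_index <- bayes_logistic(y, cbind(index = index), prior_sd, mcmc)
  fit_comp <- bayes_logistic(y, components, prior_sd, mcmc)
  w_index <- waic(fit_index)
  w_comp <- waic(fit_comp)
  structure(list(fit_index = fit_index, fit_components = fit_comp,
                 waic_index = w_index, waic_components = w_comp,
                 comparison = compare_waic(w_index, w_comp,
                                           labels = c("index", "components"))),
            class = "index_comparison")
}

#' @export
print.index_comparison <- function(x, ...) {
  print(x$comparison)
  invisible(x)
}
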