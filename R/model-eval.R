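#' Widely applicable information criterion
#'
#' `waic` is generic: the default method consumes an S x n matrix of
#' pointwise log-likelihoods (S posterior draws, n observations);
#' methods for fitted models build that matrix and delegate. Components:
#' `lppd = sum_i log(mean_s exp(ll_si))` (log-sum-exp, no underflow),
#' `p_waic = sum_i var_s(ll_si)` (sample variance, divisor S-1),
#' `waic = -2 (lppd - p_waic)`, and
#' `se = sqrt(n * var_i(waic_i))` over the pointwise contributions
#' `waic_i = -2 (lppd_i - p_i)`.
#'
#' @param object log-likelihood matrix or fitted model.
#' @param ... passed to methods.
#' @return object of class `waic_result`: `lppd`, `p_waic`, `waic`, `se`,
#'   `n_obs` and a `pointwise` data.frame.
#' @export
waic <- function(object, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.default <- function(object, ...) {
  ll <- as.matrix(object)
  S <- nrow(ll)
  if (S < 2L) stopf("waic needs at least 2 draws (variance undefined)")
  if (any(!is.finite(ll))) stopf("log-likelihood matrix must be finite")
  m <- apply(ll, 2, max)
  lppd_i <- m + log(colMeans(exp(sweep(ll, 2, m))))
  p_i <- apply(ll, 2, stats::var)
  new_waic(lppd_i, p_i)
}

new_waic <- function(lppd_i, p_i) {
  waic_i <- -2 * (lppd_i - p_i)
  n <- length(lppd_i)
  structure(list(
    lppd = sum(lppd_i), p_waic = sum(p_i), waic = sum(waic_i),
    se = sqrt(n * stats::var(waic_i)), n_obs = n,
    pointwise = data.frame(lppd = lppd_i, p_waic = p_i, waic = waic_i)
  ), class = "waic_result")
}

#' @rdname waic
#' @param chunk number of draws processed at a time (memory control).
#' @export
waic.depriv_irt <- function(object, chunk = 200L, ...) {
  S <- length(object$chain)
  n <- nrow(object$data$X) * ncol(object$data$X)
  # streaming accumulators: log-sum-exp state (m, s) and Chan-combined
  # mean/M2 for the pointwise variances
  acc_m <- rep(-Inf, n); acc_s <- rep(0, n)
  cnt <- 0; mean_a <- rep(0, n); M2_a <- rep(0, n)
  starts <- seq(1L, S, by = chunk)
  for (st in starts) {
    idx <- st:min(st + chunk - 1L, S)
    L <- pointwise_loglik(object, draw_idx = idx)
    cm <- do.call(pmax, c(asplit(L, 1), list(acc_m)))
    acc_s <- acc_s * exp(acc_m - cm) + colSums(exp(sweep(L, 2, cm)))
    acc_m <- cm
    nb <- nrow(L); mb <- colMeans(L)
    M2b <- colSums(sweep(L, 2, mb)^2)
    if (cnt == 0) {
      mean_a <- mb; M2_a <- M2b
    } else {
      d <- mb - mean_a
      M2_a <- M2_a + M2b + d^2 * cnt * nb / (cnt + nb)
      mean_a <- mean_a + d * nb / (cnt + nb)
    }
    cnt <- cnt + nb
  }
  lppd_i <- acc_m + log(acc_s) - log(cnt)
  p_i <- M2_a / (cnt - 1)
  new_waic(lppd_i, p_i)
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.1f (SE %.1f); lppd %.1f, p_waic %.1f, n = %d\n",
              x$waic, x$se, x$lppd, x$p_waic, x$n_obs))
  invisible(x)
}

#' Compare two models by WAIC with a substantial-difference rule
#'
#' Lower WAIC is preferred; an absolute difference of at least `threshold`
#' (default 5) is flagged substantial.
#'
#' @param a,b `waic_result` objects computed on the same observations.
#' @param labels length-2 model labels for the report.
#' @param threshold substantial-difference cutoff.
#' @return object of class `waic_comparison`: `difference` (a - b),
#'   `preferred`, `substantial`, and the two inputs.
#' @export
compare_waic <- function(a, b, labels = c("a", "b"), threshold = 5) {
  stopifnot(inherits(a, "waic_result"), inherits(b, "waic_result"))
  if (a$n_obs != b$n_obs)
    stopf("WAICs computed on different numbers of observations (%d vs %d)",
          a$n_obs, b$n_obs)
  diff <- a$waic - b$waic
  preferred <- if (diff == 0) NA_character_
               else labels[if (diff < 0) 1L else 2L]
  structure(list(difference = diff, preferred = preferred,
                 substantial = abs(diff) >= threshold,
                 threshold = threshold, labels = labels, a = a, b = b),
            class = "waic_comparison")
}

#' @export
print.waic_comparison <- function(x, ...) {
  cat(sprintf("WAIC comparison: %s = %.1f vs %s = %.1f\n",
              x$labels[1], x$a$waic, x$labels[2], x$b$waic))
  if (is.na(x$preferred)) cat("  no preference (equal WAIC)\n")
  else cat(sprintf("  preferred: %s (difference %.1f, %ssubstantial at threshold %g)\n",
                   x$preferred, x$difference,
                   if (x$substantial) "" else "not ", x$threshold))
  invisible(x)
}

#' Item characteristic curve with posterior uncertainty
#'
#' For one item and province, evaluates the endorsement probability
#' `Phi(alpha + beta * theta)` over a grid of index values for every
#' posterior draw and summarizes pointwise (mean, 2.5% and 97.5%
#' quantiles). The curve's inflection point sits at `theta = -alpha/beta`,
#' where the probability is exactly 0.5; `inflection_location` is the
#' posterior mean of `-alpha/beta`. Province `"overall"` uses the item's
#' hypermean draws (hierarchical fit) or the common parameters (pooled);
#' with `overall = "mean_curve"` it instead averages the province curves.
#'
#' @param fit a `depriv_irt` object.
#' @param item item name.
#' @param province province label or `"overall"`.
#' @param theta_grid increasing grid of index values.
#' @param overall how to form the overall curve: `"hypermean"` (default)
#'   or `"mean_curve"`.
#' @return object of class `icc_curve`: data.frame-like list with
#'   `theta_grid`, `prob_mean`, `prob_lo`, `prob_hi`,
#'   `inflection_location`, `item`, `province`.
#' @export
icc_curve <- function(fit, item, province = "overall",
                      theta_grid = seq(-3, 3, length.out = 61),
                      overall = c("hypermean", "mean_curve")) {
  overall <- match.arg(overall)
  if (is.unsorted(theta_grid)) stopf("theta_grid must be increasing")
  j <- match(item, fit$items)
  if (is.na(j)) stopf("unknown item '%s'", item)
  if (province == "overall" && overall == "mean_curve") {
    curves <- lapply(fit$provinces, function(p)
      icc_curve(fit, item, p, theta_grid))
    avg <- function(f) Reduce(`+`, lapply(curves, `[[`, f)) / length(curves)
    return(structure(list(item = item, province = "overall",
                          theta_grid = theta_grid,
                          prob_mean = avg("prob_mean"),
                          prob_lo = avg("prob_lo"), prob_hi = avg("prob_hi"),
                          inflection_location = avg("inflection_location")),
                     class = "icc_curve"))
  }
  if (province == "overall") {
    if (!is.null(fit$draws$mu_alpha)) {
      a <- fit$draws$mu_alpha[, j]; b <- fit$draws$mu_beta[, j]
    } else {
      a <- fit$draws$alpha[, j, 1]; b <- fit$draws$beta[, j, 1]
    }
  } else {
    k <- match(province, fit$provinces)
    if (is.na(k)) stopf("unknown province '%s'", province)
    a <- fit$draws$alpha[, j, k]; b <- fit$draws$beta[, j, k]
  }
  P <- stats::pnorm(outer(a, theta_grid, function(aa, th) aa) +
                    outer(b, theta_grid, `*`))
  qs <- apply(P, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(item = item, province = province, theta_grid = theta_grid,
                 prob_mean = colMeans(P), prob_lo = qs[1, ], prob_hi = qs[2, ],
                 inflection_location = mean(-a / b)),
            class = "icc_curve")
}

#' @export
print.icc_curve <- function(x, ...) {
  cat(sprintf("ICC for item '%s', province '%s': inflection at theta = %.3f\n",
              x$item, x$province, x$inflection_location))
  invisible(x)
}

#' @export
as.data.frame.icc_curve <- function(x, ...) {
  data.frame(item = x$item, province = x$province, theta = x$theta_grid,
             mean = x$prob_mean, lo = x$prob_lo, hi = x$prob_hi,
             stringsAsFactors = FALSE)
}

#' Posterior summaries of discriminations and inflection locations
#'
#' One row per (item, province): posterior mean, SD and 95% interval of
#' the discrimination `beta` and of the inflection location `-alpha/beta`,
#' ranked by mean discrimination (highest first).
#'
#' @param fit a `depriv_irt` object.
#' @return data.frame.
#' @export
discrimination_table <- function(fit) {
  J <- length(fit$items); K <- length(fit$provinces)
  rows <- vector("list", J * K)
  i <- 0L
  for (j in seq_len(J)) for (k in seq_len(K)) {
    b <- fit$draws$beta[, j, k]
    infl <- -fit$draws$alpha[, j, k] / b
    qb <- stats::quantile(b, c(0.025, 0.975), names = FALSE)
    qi <- stats::quantile(infl, c(0.025, 0.975), names = FALSE)
    i <- i + 1L
    rows[[i]] <- data.frame(
      item = fit$items[j], province = fit$provinces[k],
      beta_mean = mean(b), beta_sd = stats::sd(b),
      beta_lo = qb[1], beta_hi = qb[2],
      inflection_mean = mean(infl), inflection_sd = stats::sd(infl),
      inflection_lo = qi[1], inflection_hi = qi[2],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(-out$beta_mean), , drop = FALSE]
}
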