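#' Configuration for a synthetic coinfection-style cohort
#'
#' Bundles everything needed to simulate a cohort with known ground truth:
#' province labels and sizes, item labels, the true item intercepts
#' (`true_alpha`) and discriminations (`true_beta`) per item and province on
#' the probit latent scale, missing-completely-at-random masking rates, and
#' the logistic parameters of the binary second-visit outcome.
#'
#' The generative model is the latent-normal (probit) two-parameter IRT
#' model: each person carries a deprivation trait `theta ~ N(0, 1)`; the
#' latent utility for item j in province k is
#' `x* = alpha[j,k] + beta[j,k] * theta + e`, `e ~ N(0, 1)`, and the
#' recorded response is `1{x* > 0}`.
#'
#' @param province_labels character vector of K province labels.
#' @param province_sizes integer vector of K positive sizes.
#' @param item_labels character vector of J item names.
#' @param true_alpha J x K matrix of latent intercepts.
#' @param true_beta J x K matrix of positive discriminations.
#' @param missing_rates J x K matrix of masking probabilities in [0, 0.5].
#' @param outcome_intercept,outcome_slope log-odds scale parameters of the
#'   Bernoulli outcome `y ~ Bernoulli(plogis(intercept + slope * theta))`.
#' @param seed integer seed; mandatory so simulations are reproducible.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(province_labels, province_sizes, item_labels,
                          true_alpha, true_beta, missing_rates,
                          outcome_intercept = 0, outcome_slope = 0,
                          seed) {
  K <- length(province_labels)
  J <- length(item_labels)
  true_alpha <- as.matrix(true_alpha)
  true_beta <- as.matrix(true_beta)
  missing_rates <- as.matrix(missing_rates)
  if (length(province_sizes) != K)
    stopf("province_sizes must have length %d", K)
  if (any(province_sizes < 1)) stopf("all province_sizes must be >= 1")
  for (nm in c("true_alpha", "true_beta", "missing_rates")) {
    m <- get(nm)
    if (!all(dim(m) == c(J, K)))
      stopf("%s must be a %d x %d matrix", nm, J, K)
  }
  if (any(true_beta <= 0)) stopf("all true_beta must be > 0")
  if (any(missing_rates < 0 | missing_rates > 0.5))
    stopf("missing_rates must lie in [0, 0.5]")
  if (missing(seed)) stopf("seed is mandatory")
  dimnames(true_alpha) <- dimnames(true_beta) <- dimnames(missing_rates) <-
    list(item_labels, province_labels)
  structure(list(
    province_labels = province_labels,
    province_sizes = as.integer(province_sizes),
    item_labels = item_labels,
    true_alpha = true_alpha, true_beta = true_beta,
    missing_rates = missing_rates,
    outcome_intercept = outcome_intercept, outcome_slope = outcome_slope,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  provinces: %s (n = %s)\n",
              paste(x$province_labels, collapse = ", "),
              paste(x$province_sizes, collapse = "/")))
  cat(sprintf("  items: %d; outcome slope (log-OR per unit trait): %.4f\n",
              length(x$item_labels), x$outcome_slope))
  invisible(x)
}

#' Latent intercept matching a target marginal prevalence
#'
#' Under `theta ~ N(0, 1)` the marginal probability of a positive response
#' is `Phi(alpha / sqrt(1 + beta^2))`, so the intercept reproducing a target
#' prevalence p is `alpha = qnorm(p) * sqrt(1 + beta^2)`.
#'
#' @param prevalence target marginal prevalence in (0, 1).
#' @param beta positive discrimination.
#' @return the latent intercept alpha.
#' @export
calibrate_alpha <- function(prevalence, beta) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stopf("prevalence must lie strictly in (0, 1)")
  if (any(beta <= 0)) stopf("beta must be > 0")
  stats::qnorm(prevalence) * sqrt(1 + beta^2)
}

#' Outcome intercept matching a target marginal event rate
#'
#' Finds, by 1-D root finding, the logistic intercept c such that
#' `E[plogis(c + slope * theta)] = target` with `theta ~ N(0, 1)`
#' (expectation by Gauss-Hermite quadrature).
#'
#' @param slope log-odds per unit latent trait.
#' @param target target marginal event probability in (0, 1).
#' @return the intercept on the log-odds scale.
#' @export
calibrate_outcome_intercept <- function(slope, target) {
  gh <- gauss_hermite_normal(61L)
  marg <- function(c0) sum(gh$w * stats::plogis(c0 + slope * gh$x)) - target
  stats::uniroot(marg, c(-20, 20), tol = 1e-10)$root
}

# Gauss-Hermite nodes/weights re-expressed for N(0,1) expectations,
# built from the symmetric tridiagonal Golub-Welsch recurrence.
gauss_hermite_normal <- function(n) {
  i <- seq_len(n - 1)
  a <- sqrt(i / 2)
  T <- diag(0, n)
  T[cbind(i, i + 1)] <- a
  T[cbind(i + 1, i)] <- a
  e <- eigen(T, symmetric = TRUE)
  x <- e$values * sqrt(2)           # physicists' -> probabilists' scale
  w <- e$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

#' Simulate item responses with known ground truth
#'
#' Draws `theta_i ~ N(0, 1)` per person and binary responses from the
#' probit latent-utility model of the configuration. Deterministic given
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `data` (data.frame: id, province, one 0/1 column per
#'   item) and `truth` (list: theta, alpha, beta).
#' @export
simulate_items <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(config$seed, "items"))
  N <- sum(config$province_sizes)
  J <- length(config$item_labels)
  province <- rep(config$province_labels, config$province_sizes)
  k_idx <- rep(seq_along(config$province_labels), config$province_sizes)
  theta <- stats::rnorm(N)
  eta <- config$true_alpha[, k_idx, drop = FALSE] +
    config$true_beta[, k_idx, drop = FALSE] * rep(theta, each = J)
  xstar <- eta + stats::rnorm(N * J)
  X <- t(matrix(as.integer(xstar > 0), nrow = J))
  colnames(X) <- config$item_labels
  dat <- data.frame(id = seq_len(N), province = province,
                    X, check.names = FALSE, stringsAsFactors = FALSE)
  attr(dat, "items") <- config$item_labels
  list(data = dat,
       truth = list(theta = theta, alpha = config$true_alpha,
                    beta = config$true_beta))
}

#' Mask item responses completely at random
#'
#' Each cell of item j for a person in province k is independently set to
#' `NA` with probability `rates[j, k]`. Deterministic given `seed`.
#'
#' @param data data.frame from [simulate_items()] (columns id, province,
#'   items).
#' @param rates J x K matrix of masking probabilities in [0, 1), rows named
#'   by item and columns by province.
#' @param seed integer seed.
#' @return the data.frame with masked cells set to `NA`.
#' @export
apply_missingness <- function(data, rates, seed) {
  rates <- as.matrix(rates)
  if (any(rates < 0 | rates >= 1)) stopf("rates must lie in [0, 1)")
  items <- rownames(rates)
  if (is.null(items)) stopf("rates must have item rownames")
  if (!all(items %in% names(data))) stopf("rates rows must match item columns")
  set.seed(child_seed(seed, "missingness"))
  k_idx <- match(data$province, colnames(rates))
  for (j in items) {
    p <- rates[j, k_idx]
    mask <- stats::runif(nrow(data)) < p
    data[[j]][mask] <- NA_integer_
  }
  data
}

#' Simulate the binary second-visit non-attendance outcome
#'
#' `y_i ~ Bernoulli(plogis(intercept + slope * theta_i))`, deterministic
#' given `seed`.
#'
#' @param theta numeric vector of latent traits.
#' @param intercept,slope logistic parameters (log-odds scale).
#' @param seed integer seed.
#' @return integer 0/1 vector.
#' @export
simulate_outcome <- function(theta, intercept, slope, seed) {
  stopifnot(all(is.finite(theta)), is.finite(intercept), is.finite(slope))
  set.seed(child_seed(seed, "outcome"))
  p <- stats::plogis(intercept + slope * theta)
  as.integer(stats::runif(length(theta)) < p)
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_items()], [apply_missingness()] and [simulate_outcome()]
#' under the configuration's seed streams and returns the assembled cohort
#' table together with the truth record.
#'
#' @param config a [cohort_config()].
#' @return list with `data` (id, province, items with NAs, outcome) and
#'   `truth` (theta, alpha, beta, outcome_prob).
#' @export
simulate_cohort <- function(config) {
  sim <- simulate_items(config)
  dat <- apply_missingness(sim$data, config$missing_rates, config$seed)
  theta <- sim$truth$theta
  dat$outcome <- simulate_outcome(theta, config$outcome_intercept,
                                  config$outcome_slope, config$seed)
  attr(dat, "items") <- config$item_labels
  sim$truth$outcome_prob <- stats::plogis(config$outcome_intercept +
                                          config$outcome_slope * theta)
  list(data = dat, truth = sim$truth)
}

#' Calibrated cohort configuration shipped with the package
#'
#' Returns the frozen synthetic-cohort configuration calibrated to the
#' four-province coinfection-cohort structure: province sizes 613, 409, 563
#' and 197; per-item, per-province marginal prevalences and missing rates
#' taken from the published baseline characteristics table; discriminations
#' drawn once from LogNormal(0, 0.3^2) and frozen in
#' `inst/extdata/ccc_truth.csv`; intercepts solved from the prevalences via
#' [calibrate_alpha()]. The outcome is calibrated so that a one-unit
#' increase in the trait carries a 1.17 odds ratio and the marginal
#' non-attendance rate is 30%.
#'
#' @param items `"core9"` (the nine indicators retained by the published
#'   screening) or `"all19"` (all candidate indicators).
#' @param province_sizes optionally override the four province sizes (e.g.
#'   scaled-down runs).
#' @param seed integer seed stored in the config.
#' @return a [cohort_config()].
#' @export
ccc_config <- function(items = c("core9", "all19"), province_sizes = NULL,
                       seed = 20210419) {
  items <- match.arg(items)
  truth <- ccc_truth_table()
  keep <- if (items == "core9") unique(truth$item[truth$starred == 1])
          else unique(truth$item)
  truth <- truth[truth$item %in% keep, ]
  provs <- c("QC", "ON", "BC", "SK")
  J <- length(keep)
  shape <- function(col) {
    m <- matrix(NA_real_, J, 4, dimnames = list(keep, provs))
    m[cbind(match(truth$item, keep), match(truth$province, provs))] <- truth[[col]]
    m
  }
  sizes <- if (is.null(province_sizes)) c(613L, 409L, 563L, 197L)
           else as.integer(province_sizes)
  slope <- log(1.17)
  cohort_config(
    province_labels = provs, province_sizes = sizes, item_labels = keep,
    true_alpha = shape("alpha"), true_beta = shape("beta"),
    missing_rates = shape("missing_rate"),
    outcome_intercept = calibrate_outcome_intercept(slope, 0.30),
    outcome_slope = slope, seed = seed
  )
}

# Frozen truth table (item, province, prevalence, missing_rate, beta,
# alpha, starred) shipped as plain text.
ccc_truth_table <- function() {
  path <- system.file("extdata", "ccc_truth.csv", package = "deprivindex")
  if (path == "") path <- file.path("inst", "extdata", "ccc_truth.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Names of the nine retained deprivation indicators
#' @return character vector of item names in deprivation direction.
#' @export
core9_items <- function() {
  c("education", "low_income", "unemployed", "non_gbmsm", "indigenous",
    "incarceration", "idu_ever", "idu_6mo", "psych_hosp")
}
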