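# Gibbs full conditionals: closed forms, truncation sides, grid oracles,
# and a successive-conditional (Geweke-style) joint-preservation check.

test_that("latent utilities respect truncation sides and moments", {
  X1 <- matrix(1L, 1e5, 1)
  a <- matrix(0, 1, 1); b <- matrix(1e-12, 1, 1)
  xs <- step_latent_utilities(X1, a, b, theta = rep(0, 1e5), seed = 1)
  expect_true(all(xs > 0))
  # half-normal mean sqrt(2/pi)
  se <- sd(xs) / sqrt(length(xs))
  expect_lt(abs(mean(xs) - sqrt(2 / pi)), 3 * se)
  X0 <- matrix(0L, 1e4, 1)
  xs0 <- step_latent_utilities(X0, a, b, theta = rep(0, 1e4), seed = 2)
  expect_true(all(xs0 <= 0))
  # shifted mean: truncated-normal closed form at eta = 5 and at eta = -5
  a5 <- matrix(5, 1, 1)
  xs5 <- step_latent_utilities(X1, a5, b, theta = rep(0, 1e5), seed = 3)
  m5 <- 5 + dnorm(-5) / (1 - pnorm(-5))
  expect_lt(abs(mean(xs5) - m5), 3 * sd(xs5) / sqrt(length(xs5)))
  # deep tail: x = 1 despite eta = -8 still yields finite positive draws
  am8 <- matrix(-8, 1, 1)
  xs8 <- step_latent_utilities(matrix(1L, 100, 1), am8, b,
                               theta = rep(0, 100), seed = 4)
  expect_true(all(is.finite(xs8)) && all(xs8 > 0))
})

test_that("theta full conditional matches its conjugate closed form", {
  cond <- deprivindex:::theta_conditional(
    matrix(1.5, 1, 1), matrix(0, 1, 1), matrix(1, 1, 1))
  expect_equal(cond$mean, 0.75, tolerance = 1e-12)
  expect_equal(cond$var, 0.5, tolerance = 1e-12)
  # no information: prior N(0,1)
  cond0 <- deprivindex:::theta_conditional(
    matrix(2, 1, 2), matrix(0, 2, 1), matrix(0, 2, 1))
  expect_equal(cond0$mean, 0, tolerance = 1e-12)
  expect_equal(cond0$var, 1, tolerance = 1e-12)
  # J = 2, beta = (1,2), alpha = 0, x* = (1,1) -> N(3/6, 1/6)
  cond2 <- deprivindex:::theta_conditional(
    matrix(c(1, 1), 1, 2), matrix(0, 2, 1), matrix(c(1, 2), 2, 1))
  expect_equal(cond2$mean, 0.5, tolerance = 1e-12)
  expect_equal(cond2$var, 1 / 6, tolerance = 1e-12)
})

test_that("item-parameter conditionals reduce to least squares and the prior", {
  th <- c(-1, 0, 1); xs <- c(-1, 0, 1)
  # flat prior: posterior centred on the least-squares line (0, 1)
  ca <- deprivindex:::cond_alpha(3, sum(th), sum(xs), beta = 1,
                                 prior_mean = 0, prior_var = 1e12)
  cb <- deprivindex:::cond_beta(sum(th), sum(th^2), sum(th * xs), alpha = 0,
                                prior_mean = 0, prior_var = 1e12)
  expect_equal(unname(ca["mean"]), 0, tolerance = 1e-10)
  expect_equal(unname(cb["mean"]), 1, tolerance = 1e-10)
  # vanishing prior variance: posterior concentrates at the prior mean
  ca0 <- deprivindex:::cond_alpha(3, sum(th), sum(xs), beta = 1,
                                  prior_mean = 0.7, prior_var = 1e-10)
  expect_equal(unname(ca0["mean"]), 0.7, tolerance = 1e-6)
  expect_lt(ca0["var"], 1e-9)
})

test_that("item-parameter update samples the 2-D grid posterior exactly", {
  set.seed(21)
  n <- 8
  th <- rnorm(n)
  xs <- 0.4 + 1.3 * th + rnorm(n)
  pm <- c(0.3, 0.5); pv <- c(1.5, 0.8)
  # dense-grid oracle over (alpha, beta > 0), quadratic log-likelihood
  ag <- seq(-3, 4, length.out = 401)
  bg <- seq(1e-4, 5, length.out = 401)
  S0 <- n; S1 <- sum(th); S2 <- sum(th^2)
  Y0 <- sum(xs); Y1 <- sum(th * xs); YY <- sum(xs^2)
  lp <- -0.5 * (YY - 2 * outer(ag, rep(1, 401)) * Y0 -
                  2 * outer(rep(1, 401), bg) * Y1 +
                  2 * outer(ag, bg) * S1 +
                  outer(ag^2, rep(1, 401)) * S0 +
                  outer(rep(1, 401), bg^2) * S2) -
    0.5 * outer((ag - pm[1])^2 / pv[1], rep(1, 401)) -
    0.5 * outer(rep(1, 401), (bg - pm[2])^2 / pv[2])
  w <- exp(lp - max(lp))
  grid_a <- sum(outer(ag, rep(1, 401)) * w) / sum(w)
  grid_b <- sum(outer(rep(1, 401), bg) * w) / sum(w)
  # the update draws the cell posterior independently each call
  prior <- list(mean_alpha = matrix(pm[1], 1, 1),
                var_alpha = matrix(pv[1], 1, 1),
                mean_beta = matrix(pm[2], 1, 1),
                var_beta = matrix(pv[2], 1, 1))
  set.seed(22)
  M <- 20000L
  out <- matrix(NA_real_, M, 2)
  for (m in seq_len(M)) {
    d <- step_item_params(matrix(xs, n, 1), th, rep(1L, n),
                          matrix(0, 1, 1), matrix(1, 1, 1), prior)
    out[m, ] <- c(d$alpha, d$beta)
  }
  for (d in 1:2) {
    mcse <- sd(out[, d]) / sqrt(M)   # independence draws
    expect_lt(abs(mean(out[, d]) - c(grid_a, grid_b)[d]), 4 * mcse + 0.01)
  }
  # joint-posterior moments match the closed form of the normal regression
  po <- deprivindex:::item_param_posterior(S0, S1, S2, Y0, Y1,
                                           pm[1], pv[1], pm[2], pv[2])
  P <- matrix(c(S0 + 1 / pv[1], S1, S1, S2 + 1 / pv[2]), 2, 2)
  expect_equal(po$cov, solve(P), tolerance = 1e-12)
  expect_equal(po$mean,
               drop(solve(P, c(Y0 + pm[1] / pv[1], Y1 + pm[2] / pv[2]))),
               tolerance = 1e-12)
})

test_that("hyper-parameter conditionals follow the conjugate bookkeeping", {
  vals <- matrix(2.5, 1, 4)            # all provinces equal
  hc <- deprivindex:::hyper_mu_conditional(vals, tau2 = 1e-6, mean0 = 0,
                                           sd0 = 100)
  expect_equal(unname(hc$mean), 2.5, tolerance = 1e-6)
  # zero residual SS, K = 4, IG(2,1) prior -> IG(2 + 2, 1)
  ht <- deprivindex:::hyper_tau2_conditional(vals, mu = 2.5, shape = 2,
                                             scale = 1)
  expect_equal(unname(ht$shape), 4)
  expect_equal(unname(ht$scale), 1, tolerance = 1e-12)
  # random values against a 1-D grid oracle for mu
  set.seed(30)
  v <- matrix(rnorm(4, 1, 0.8), 1, 4)
  tau2 <- 0.6
  hm <- deprivindex:::hyper_mu_conditional(v, tau2, mean0 = 0, sd0 = 2)
  mg <- seq(-4, 5, length.out = 20001)
  lp <- -0.5 * colSums(outer(as.numeric(v), mg, `-`)^2) / tau2 -
    0.5 * mg^2 / 4
  wg <- exp(lp - max(lp))
  expect_equal(unname(hm$mean), sum(mg * wg) / sum(wg), tolerance = 1e-5)
  expect_equal(unname(hm$var),
               sum((mg - sum(mg * wg) / sum(wg))^2 * wg) / sum(wg),
               tolerance = 1e-4)
})

test_that("Gibbs scan preserves the joint law (successive-conditional check)", {
  J <- 2L; N <- 15L
  prior <- list(mean_alpha = matrix(0, J, 1), var_alpha = matrix(4, J, 1),
                mean_beta = matrix(0, J, 1), var_beta = matrix(4, J, 1))
  draw_params <- function() list(
    alpha = matrix(rnorm(J, 0, 2), J, 1),
    beta = matrix(deprivindex:::rtnorm_signed(rep(0, J), 2, TRUE), J, 1))
  draw_data <- function(p) {
    theta <- rnorm(N)
    eta <- t(p$alpha[, rep(1, N), drop = FALSE]) +
      t(p$beta[, rep(1, N), drop = FALSE]) * theta
    list(theta = theta,
         X = matrix(as.integer(runif(N * J) < pnorm(eta)), N, J))
  }
  prop_fixed <- matrix(rep(c(0.4, 0.1, 0.35), each = J), J, 3)
  M <- 4000L
  set.seed(41)
  marg <- t(replicate(M, {
    p <- draw_params(); d <- draw_data(p)
    c(mean(p$alpha), mean(p$beta), mean(d$X))
  }))
  set.seed(42)
  p <- draw_params()
  succ <- matrix(NA_real_, M, 3)
  for (m in seq_len(M)) {
    d <- draw_data(p)                      # data | params
    xs <- step_latent_utilities(d$X, p$alpha, p$beta, d$theta)
    th <- step_theta(xs, p$alpha, p$beta)
    p <- step_item_params(xs, th, rep(1L, N), p$alpha, p$beta, prior)
    p <- deprivindex:::step_item_refresh(d$X, th, rep(1L, N), p$alpha,
                                         p$beta, prior, prop_fixed)
    rc <- deprivindex:::step_recenter(th, p$alpha, p$beta,
                                      prior$mean_alpha, prior$var_alpha)
    p$alpha <- rc$alpha
    rs <- deprivindex:::step_rescale(rc$theta, p$beta,
                                     prior$mean_beta, prior$var_beta)
    p$beta <- rs$beta
    succ[m, ] <- c(mean(p$alpha), mean(p$beta), mean(d$X))
  }
  for (d in 1:3) {
    se_m <- sd(marg[, d]) / sqrt(M)
    se_s <- sd(succ[, d]) /
      sqrt(deprivindex:::ess_basic(succ[, d], rep(1L, M)))
    expect_lt(abs(mean(marg[, d]) - mean(succ[, d])),
              4 * sqrt(se_m^2 + se_s^2) + 0.01)
  }
})

test_that("recentering move leaves every linear predictor invariant", {
  set.seed(71)
  J <- 3; K <- 2; N <- 30
  alpha <- matrix(rnorm(J * K), J, K)
  beta <- matrix(rlnorm(J * K, 0, 0.3), J, K)
  theta <- rnorm(N)
  k_idx <- rep(1:2, c(18, 12))
  rc <- deprivindex:::step_recenter(theta, alpha, beta,
                                    matrix(0, J, K), matrix(4, J, K))
  eta_before <- t(alpha[, k_idx]) + t(beta[, k_idx]) * theta
  eta_after <- t(rc$alpha[, k_idx]) + t(beta[, k_idx]) * rc$theta
  expect_equal(eta_after, eta_before, tolerance = 1e-12)
  # the drawn shift follows its Gaussian orbit conditional
  P <- N + sum(beta^2 / 4)
  mu <- (sum(theta) - sum(beta * alpha / 4)) / P
  set.seed(72)
  shifts <- replicate(5000, deprivindex:::step_recenter(
    theta, alpha, beta, matrix(0, J, K), matrix(4, J, K))$shift)
  expect_lt(abs(mean(shifts) - mu), 4 / sqrt(P * 5000))
  expect_lt(abs(sd(shifts) - sqrt(1 / P)), 0.01)
})

test_that("truncated-normal sampler matches closed-form tail moments", {
  set.seed(5)
  z <- deprivindex:::rtnorm_lower(rep(2, 2e4))
  m_true <- dnorm(2) / (1 - pnorm(2))
  expect_lt(abs(mean(z) - m_true), 3 * sd(z) / sqrt(2e4))
  expect_true(all(z >= 2))
  z2 <- deprivindex:::rtnorm_upper(rep(-7, 1000))
  expect_true(all(is.finite(z2)) && all(z2 <= -7))
})
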