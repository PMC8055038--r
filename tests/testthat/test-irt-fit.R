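# The assembled sampler: determinism, recovery, orientation, diagnostics,
# pointwise log-likelihood and index summaries.

test_that("fits are deterministic given the seed and reject bad input", {
  cfg <- toy_config(J = 2, N = 60, seed = 3)
  sim <- simulate_items(cfg)
  mc <- quick_mcmc(iterations = 120, burn_in = 60, chains = 2)
  f1 <- irt_deprivation(sim$data, variant = "pooled", mcmc = mc)
  f2 <- irt_deprivation(sim$data, variant = "pooled", mcmc = mc)
  expect_identical(f1$draws, f2$draws)
  # missing cells and constant items are fatal
  bad <- sim$data; bad$it1[1] <- NA
  expect_error(irt_deprivation(bad, variant = "pooled", mcmc = mc),
               "complete cases")
  const <- sim$data; const$it2 <- 1L
  expect_error(irt_deprivation(const, variant = "pooled", mcmc = mc), "it2")
})

test_that("compiled chain reproduces the R reference steps bit for bit", {
  set.seed(1)
  N <- 40L; J <- 3L; K <- 2L
  k_idx <- rep(1:2, c(25, 15)); theta0 <- rnorm(N)
  X <- matrix(rbinom(N * J, 1, 0.5), N, J)
  a0 <- matrix(0.2, J, K); b0 <- matrix(1, J, K)
  flat <- matrix(0, J, K); four <- matrix(4, J, K)
  prop <- matrix(rep(c(0.3, 0.05, 0.25), each = J * K), J * K, 3)
  ref_chain <- function(iters, hier) {
    alpha <- a0; beta <- b0; theta <- theta0
    mu_a <- rowMeans(alpha); tau2_a <- rep(1, J)
    mu_b <- rowMeans(beta); tau2_b <- rep(1, J)
    out <- vector("list", iters)
    for (it in seq_len(iters)) {
      xs <- step_latent_utilities(X, alpha, beta, theta, k_idx)
      theta <- step_theta(xs, alpha, beta, k_idx)
      pr <- if (hier)
        list(mean_alpha = matrix(mu_a, J, K), var_alpha = matrix(tau2_a, J, K),
             mean_beta = matrix(mu_b, J, K), var_beta = matrix(tau2_b, J, K))
      else list(mean_alpha = flat, var_alpha = four,
                mean_beta = flat, var_beta = four)
      ab <- step_item_params(xs, theta, k_idx, alpha, beta, pr)
      alpha <- ab$alpha; beta <- ab$beta
      rf <- deprivindex:::step_item_refresh(X, theta, k_idx, alpha, beta,
                                            pr, prop)
      alpha <- rf$alpha; beta <- rf$beta
      if (hier) {
        ha <- step_hyper(alpha, tau2_a, 0, 2, 2, 1)
        mu_a <- ha$mu; tau2_a <- ha$tau2
        hb <- step_hyper(beta, tau2_b, 0, 2, 2, 1)
        mu_b <- hb$mu; tau2_b <- hb$tau2
      }
      rc <- deprivindex:::step_recenter(
        theta, alpha, beta,
        if (hier) matrix(mu_a, J, K) else flat,
        if (hier) matrix(tau2_a, J, K) else four)
      theta <- rc$theta; alpha <- rc$alpha
      rs <- deprivindex:::step_rescale(
        theta, beta,
        if (hier) matrix(mu_b, J, K) else flat,
        if (hier) matrix(tau2_b, J, K) else four)
      theta <- rs$theta; beta <- rs$beta
      out[[it]] <- list(alpha = alpha, beta = beta, theta = theta)
    }
    out
  }
  for (hier in c(FALSE, TRUE)) {
    set.seed(99); ref <- ref_chain(20, hier)
    set.seed(99)
    cpp <- deprivindex:::.gibbs_chain(
      X, k_idx, K, a0, b0, theta0, hier, flat, four, flat, four,
      rowMeans(a0), rep(1, J), rowMeans(b0), rep(1, J),
      2, 2, 1, prop, 20L, 0L, 1L)
    for (it in c(1L, 10L, 20L)) {
      expect_identical(as.numeric(cpp$alpha[it, , ]),
                       as.numeric(ref[[it]]$alpha))
      expect_identical(as.numeric(cpp$beta[it, , ]),
                       as.numeric(ref[[it]]$beta))
      expect_identical(as.numeric(cpp$theta[it, ]),
                       as.numeric(ref[[it]]$theta))
    }
  }
})

test_that("pooled fit recovers simulated item parameters", {
  cfg <- cached("rec_cfg", {
    truth <- deprivindex:::ccc_truth_table()
    truth <- truth[truth$starred == 1 & truth$province == "QC", ]
    cohort_config("A", 400L, truth$item,
                  true_alpha = matrix(truth$alpha, 9, 1),
                  true_beta = matrix(truth$beta, 9, 1),
                  missing_rates = matrix(0, 9, 1), seed = 19)
  })
  sim <- cached("rec_sim", simulate_items(cfg))
  fit <- cached("rec_fit", irt_deprivation(
    sim$data, variant = "pooled",
    mcmc = mcmc_control(iterations = 1500, burn_in = 750, chains = 2,
                        seed = 23)))
  ok_a <- ok_b <- logical(9)
  for (j in 1:9) {
    da <- fit$draws$alpha[, j, 1]; db <- fit$draws$beta[, j, 1]
    ok_a[j] <- abs(mean(da) - cfg$true_alpha[j, 1]) < 3 * sd(da)
    ok_b[j] <- abs(mean(db) - cfg$true_beta[j, 1]) < 3 * sd(db)
  }
  expect_gte(sum(ok_a), 8)
  expect_gte(sum(ok_b), 8)
  # index recovers the trait ordering
  r <- cor(colMeans(fit$draws$theta), sim$truth$theta)
  expect_gt(r, 0.6)
  # aggregate shrinkage toward the N(0,1) prior
  expect_lt(abs(mean(colMeans(fit$draws$theta))), 0.1)
  expect_lte(mean(apply(fit$draws$theta, 2, sd)), 1.05)
})

test_that("chains converge at default settings on the calibrated cohort", {
  cfg <- ccc_config("core9")
  sim <- simulate_cohort(cfg)
  cc <- complete_cases(sim$data)
  fit <- irt_deprivation(cc$data, variant = "hierarchical",
                         mcmc = mcmc_control(seed = 102))
  expect_lt(max(fit$diagnostics$rhat), 1.05)
  expect_true(all(fit$diagnostics$rhat >= 1 - 1e-6))
})

test_that("index orientation follows the response pattern", {
  sf <- small_fit()
  idx <- posterior_index(sf$fit)
  rows1 <- rowSums(sf$data[, sf$fit$items]) == length(sf$fit$items)
  rows0 <- rowSums(sf$data[, sf$fit$items]) == 0
  if (any(rows1) && any(rows0))
    expect_gt(min(idx$theta_mean[rows1]), max(idx$theta_mean[rows0]))
  expect_true(all(sf$fit$draws$beta > 0))
})

test_that("hierarchical path with one province matches the pooled path", {
  cfg <- toy_config(J = 3, N = 300, beta = c(0.8, 1.2, 1.6),
                    alpha = c(-0.4, 0.2, 0.8), seed = 55)
  sim <- simulate_items(cfg)
  mc <- mcmc_control(iterations = 1200, burn_in = 600, chains = 2, seed = 9)
  fp <- irt_deprivation(sim$data, variant = "pooled", mcmc = mc)
  fh <- irt_deprivation(sim$data, variant = "hierarchical",
                        mcmc = mcmc_control(iterations = 1200, burn_in = 600,
                                            chains = 2, seed = 10))
  thin <- seq(1, 1200, by = 10)   # near-independent draws for the KS test
  for (j in 1:3) {
    ks <- suppressWarnings(
      ks.test(fp$draws$alpha[thin, j, 1], fh$draws$alpha[thin, j, 1]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("pointwise log-likelihood matches direct evaluation", {
  sf <- small_fit()
  ll <- pointwise_loglik(sf$fit, draw_idx = 1:5)
  X <- sf$fit$data$X
  N <- nrow(X); J <- ncol(X)
  for (s in 1:5) {
    direct <- matrix(NA_real_, N, J)
    for (i in 1:N) for (j in 1:J) {
      eta <- sf$fit$draws$alpha[s, j, 1] +
        sf$fit$draws$beta[s, j, 1] * sf$fit$draws$theta[s, i]
      p <- pnorm(eta)
      direct[i, j] <- if (X[i, j] == 1L) log(p) else log1p(-p)
    }
    expect_equal(ll[s, ], as.vector(t(direct)), tolerance = 1e-10)
  }
})

test_that("pointwise log-likelihood handles flat and saturated items", {
  X <- matrix(c(1L, 0L), 2, 1)
  fit <- fake_fit(array(0, c(2, 1, 1)), array(1e-300, c(2, 1, 1)),
                  matrix(0, 2, 2), X)
  ll <- pointwise_loglik(fit)
  expect_equal(as.vector(ll), rep(log(0.5), 4), tolerance = 1e-12)
  # saturation: eta = 10 with x = 1 is near 0 but not underflowed
  fit2 <- fake_fit(array(10, c(2, 1, 1)), array(1e-300, c(2, 1, 1)),
                   matrix(0, 2, 2), matrix(1L, 2, 1))
  ll2 <- pointwise_loglik(fit2)
  expect_true(all(ll2 < 0) && all(ll2 > -1e-20))
  # and eta = -10 with x = 1 is a huge negative number, not -Inf
  fit3 <- fake_fit(array(-10, c(2, 1, 1)), array(1e-300, c(2, 1, 1)),
                   matrix(0, 2, 2), matrix(1L, 2, 1))
  expect_true(all(is.finite(pointwise_loglik(fit3))))
})

test_that("posterior index summaries match their definitions", {
  th <- matrix(2, 50, 3)
  fit <- fake_fit(array(0, c(50, 1, 1)), array(1, c(50, 1, 1)), th,
                  matrix(0L, 3, 1))
  idx <- posterior_index(fit)
  expect_equal(idx$theta_mean, rep(2, 3))
  expect_equal(idx$q50, rep(2, 3))
  expect_equal(idx$theta_sd, rep(0, 3))
  set.seed(61)
  thn <- matrix(rnorm(20000), 20000, 1)
  fitn <- fake_fit(array(0, c(20000, 1, 1)), array(1, c(20000, 1, 1)), thn,
                   matrix(0L, 1, 1))
  idxn <- posterior_index(fitn)
  expect_lt(abs(idxn$q2.5 - qnorm(0.025)), 0.06)
  expect_lt(abs(idxn$q97.5 - qnorm(0.975)), 0.06)
})

test_that("long-format draw export is complete and consistent", {
  sf <- small_fit()
  dl <- draws_long(sf$fit)
  S <- length(sf$fit$chain)
  expect_equal(nrow(dl), S * 2 * 4)   # alpha and beta for 4 items
  expect_setequal(unique(dl$chain), 1:2)
  one <- dl[dl$parameter == "alpha[it1,all]", ]
  expect_identical(one$value, sf$fit$draws$alpha[, 1, 1])
  expect_equal(max(one$iter), S / 2)
})

test_that("methods print, summarize and simulate coherently", {
  sf <- small_fit()
  expect_output(print(sf$fit), "pooled")
  cf <- coef(sf$fit)
  expect_equal(dim(cf$alpha), c(4, 1))
  sm <- summary(sf$fit)
  expect_s3_class(sm, "summary.depriv_irt")
  expect_output(print(sm), "discrimination")
  reps <- simulate(sf$fit, nsim = 2, seed = 3)
  expect_length(reps, 2)
  expect_equal(dim(reps[[1]]), dim(sf$fit$data$X))
  # posterior predictive keeps marginal prevalences in the right range
  expect_lt(max(abs(colMeans(reps[[1]]) - colMeans(sf$fit$data$X))), 0.2)
})
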