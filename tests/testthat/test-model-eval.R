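# WAIC, model comparison rule, and item characteristic curves.

waic_naive <- function(ll) {
  # independent double-loop reference
  S <- nrow(ll); n <- ncol(ll)
  lppd_i <- p_i <- numeric(n)
  for (i in seq_len(n)) {
    lppd_i[i] <- log(mean(exp(ll[, i])))
    p_i[i] <- var(ll[, i])
  }
  waic_i <- -2 * (lppd_i - p_i)
  list(lppd = sum(lppd_i), p_waic = sum(p_i), waic = sum(waic_i),
       se = sqrt(n * var(waic_i)))
}

test_that("waic matches hand evaluation on the two-draw example", {
  ll <- matrix(log(c(0.5, 0.25)), 2, 1)
  w <- waic(ll)
  expect_equal(w$lppd, log(0.375), tolerance = 1e-12)
  expect_equal(w$p_waic, log(2)^2 / 2, tolerance = 1e-12)
  expect_equal(w$waic, -2 * (log(0.375) - log(2)^2 / 2), tolerance = 1e-12)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic), tolerance = 1e-10)
})

test_that("waic on identical draws has zero penalty and the stated SE", {
  L <- log(seq(0.1, 0.9, length.out = 6))
  ll <- matrix(L, 3, 6, byrow = TRUE)
  w <- waic(ll)
  expect_equal(w$p_waic, 0, tolerance = 1e-12)
  expect_equal(w$waic, -2 * sum(L), tolerance = 1e-10)
  expect_equal(w$se, sqrt(6 * var(-2 * L)), tolerance = 1e-10)
})

test_that("waic equals the brute-force reference on random matrices", {
  set.seed(7)
  for (rep in 1:3) {
    ll <- matrix(rnorm(100 * 50, -1, 0.5), 100, 50)
    w <- waic(ll)
    ref <- waic_naive(ll)
    expect_equal(w$lppd, ref$lppd, tolerance = 1e-10)
    expect_equal(w$p_waic, ref$p_waic, tolerance = 1e-10)
    expect_equal(w$waic, ref$waic, tolerance = 1e-10)
    expect_equal(w$se, ref$se, tolerance = 1e-10)
  }
  expect_error(waic(matrix(0, 1, 3)), "2 draws")
})

test_that("waic is column-permutation invariant and additive over observations", {
  set.seed(8)
  ll <- matrix(rnorm(40 * 30, -1), 40, 30)
  w <- waic(ll)
  wp <- waic(ll[, sample(30)])
  expect_equal(w$waic, wp$waic, tolerance = 1e-10)
  a <- ll[, 1:12]; b <- ll[, 13:30]
  expect_equal(waic(a)$lppd + waic(b)$lppd, w$lppd, tolerance = 1e-10)
  expect_equal(waic(a)$p_waic + waic(b)$p_waic, w$p_waic, tolerance = 1e-10)
  expect_equal(waic(a)$waic + waic(b)$waic, w$waic, tolerance = 1e-10)
})

test_that("streaming model-method waic equals the in-memory computation", {
  sf <- small_fit()
  w_model <- waic(sf$fit, chunk = 37L)
  w_full <- waic(pointwise_loglik(sf$fit))
  expect_equal(w_model$waic, w_full$waic, tolerance = 1e-8)
  expect_equal(w_model$p_waic, w_full$p_waic, tolerance = 1e-8)
  expect_equal(w_model$se, w_full$se, tolerance = 1e-8)
})

test_that("comparison rule prefers the lower WAIC with the threshold flag", {
  fake_waic <- function(w, n) structure(list(waic = w, n_obs = n),
                                        class = "waic_result")
  cmp <- compare_waic(fake_waic(12413.7, 100), fake_waic(11960.6, 100),
                      labels = c("pooled", "hierarchical"))
  expect_equal(cmp$preferred, "hierarchical")
  expect_equal(cmp$difference, 453.1, tolerance = 1e-9)
  expect_true(cmp$substantial)
  eq <- compare_waic(fake_waic(10, 5), fake_waic(10, 5))
  expect_true(is.na(eq$preferred))
  expect_false(eq$substantial)
  near <- compare_waic(fake_waic(104.9, 5), fake_waic(100, 5))
  expect_equal(near$preferred, "b")
  expect_false(near$substantial)
  expect_error(compare_waic(fake_waic(1, 5), fake_waic(1, 6)), "different")
})

test_that("ICC identities: half-probability at the inflection, monotone curves", {
  S <- 4
  fit <- fake_fit(array(0, c(S, 1, 1)), array(1, c(S, 1, 1)),
                  matrix(0, S, 2), matrix(0L, 2, 1), items = "it1")
  cv <- icc_curve(fit, "it1", "all", theta_grid = seq(-3, 3, by = 0.5))
  expect_equal(cv$prob_mean, pnorm(seq(-3, 3, by = 0.5)), tolerance = 1e-12)
  expect_equal(cv$prob_mean[cv$theta_grid == 0], 0.5, tolerance = 1e-12)
  expect_equal(cv$inflection_location, 0, tolerance = 1e-12)
  # fixed (alpha, beta) = (1, 2): P(0) = Phi(1), inflection at -1/2
  fit2 <- fake_fit(array(1, c(S, 1, 1)), array(2, c(S, 1, 1)),
                   matrix(0, S, 2), matrix(0L, 2, 1), items = "it1")
  cv2 <- icc_curve(fit2, "it1", "all", theta_grid = c(-0.5, 0))
  expect_equal(cv2$prob_mean[2], pnorm(1), tolerance = 1e-12)
  expect_equal(cv2$prob_mean[1], 0.5, tolerance = 1e-12)
  expect_equal(cv2$inflection_location, -0.5, tolerance = 1e-12)
  # posterior-mean curves are monotone whenever all beta draws are positive
  sf <- small_fit()
  for (it in sf$fit$items) {
    cm <- icc_curve(sf$fit, it, "all")
    expect_true(all(diff(cm$prob_mean) >= 0))
    expect_true(all(cm$prob_lo <= cm$prob_mean + 1e-12) &&
                  all(cm$prob_mean <= cm$prob_hi + 1e-12))
  }
  expect_error(icc_curve(sf$fit, "nope", "all"), "unknown item")
})

test_that("discrimination table ranks items and matches quantile oracle", {
  S <- 1000
  set.seed(13)
  a <- array(rnorm(S * 2), c(S, 2, 1))
  b <- array(c(rep(2, S), rep(1, S)), c(S, 2, 1))
  fit <- fake_fit(a, b, matrix(0, S, 2), matrix(0L, 2, 2),
                  items = c("hi", "lo"))
  tab <- discrimination_table(fit)
  expect_equal(tab$item, c("hi", "lo"))
  expect_equal(tab$beta_mean, c(2, 1))
  infl <- -a[, 1, 1] / 2
  expect_equal(tab$inflection_mean[tab$item == "hi"], mean(infl),
               tolerance = 1e-12)
  expect_equal(tab$inflection_lo[tab$item == "hi"],
               sort(infl)[ceiling(0.025 * S)], tolerance = 0.02)
})
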