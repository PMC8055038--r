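# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Small single-province config with hand-picked truth.
toy_config <- function(J = 3, N = 500, beta = rep(1, J), alpha = rep(0, J),
                       miss = 0, seed = 42) {
  cohort_config(
    province_labels = "A", province_sizes = N,
    item_labels = paste0("it", seq_len(J)),
    true_alpha = matrix(alpha, J, 1), true_beta = matrix(beta, J, 1),
    missing_rates = matrix(miss, J, 1), seed = seed)
}

quick_mcmc <- function(iterations = 600, burn_in = 300, chains = 2, seed = 7)
  mcmc_control(iterations = iterations, burn_in = burn_in, thin = 1,
               chains = chains, seed = seed)

# A modest pooled fit reused by several summary-level tests.
small_fit <- function() cached("small_fit", {
  cfg <- toy_config(J = 4, N = 300, beta = c(0.8, 1.2, 1, 1.5),
                    alpha = c(-0.5, 0, 0.5, 1), seed = 11)
  sim <- simulate_items(cfg)
  fit <- irt_deprivation(sim$data, variant = "pooled", mcmc = quick_mcmc())
  list(fit = fit, truth = sim$truth, data = sim$data)
})

# Hand-built fit object with fully controlled draws, for exact identities.
fake_fit <- function(alpha_draws, beta_draws, theta_draws, X, k_idx = NULL,
                     provinces = "all", items = NULL, mu_alpha = NULL,
                     mu_beta = NULL) {
  S <- dim(alpha_draws)[1]
  items <- items %||% paste0("it", seq_len(dim(alpha_draws)[2]))
  dimnames(alpha_draws) <- dimnames(beta_draws) <-
    list(NULL, items, provinces)
  structure(list(
    draws = c(list(alpha = alpha_draws, beta = beta_draws,
                   theta = theta_draws),
              if (!is.null(mu_alpha)) list(mu_alpha = mu_alpha,
                                           mu_beta = mu_beta)),
    chain = rep(1L, S), items = items, provinces = provinces,
    variant = "pooled",
    data = list(X = X, k_idx = k_idx %||% rep(1L, nrow(X)),
                province = rep(provinces[1], nrow(X)),
                id = seq_len(nrow(X)))
  ), class = "depriv_irt")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
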