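# Fits here are deliberately small; deeper recovery experiments live in
# test-acceptance.R.

fitted_frame <- function(n = 200, seed = 71, family = "poisson",
                         precision_spatial = 1e12, precision_iid = 1e12,
                         coefs = c(0.2, 0.1, -0.3, 0.5, -1, -0.5, 0.4), ...) {
  cfg <- synth_config(n_villages = n, n_stores = 10,
                      region_size = 1000 * sqrt(n), n_days = 1, seed = seed,
                      family = family, true_coefficients = coefs,
                      precision_spatial = precision_spatial,
                      precision_iid = precision_iid, ...)
  vf <- generate_villages(cfg)
  adj <- build_adjacency(vf)
  sim <- simulate_counts(vf, cfg, adj)
  sim$villages$data$modeled <- TRUE
  list(villages = sim$villages, adj = adj, truth = sim$truth, cfg = cfg)
}

test_that("count log-likelihoods: closed form, NB limit, NB variance", {
  expect_equal(loglik_count(0, 1, 1, "poisson"), -1)
  expect_equal(loglik_count(c(2, 5), c(1, 2), c(3, 1), "poisson"),
               dpois(c(2, 5), c(3, 2), log = TRUE))
  # Poisson is the size -> Inf limit of the negative binomial
  Y <- c(0, 3, 17, 120); E <- c(1, 2, 10, 100); rho <- c(0.5, 1, 2, 1.1)
  expect_equal(loglik_count(Y, E, rho, "negbin", size = 1e8),
               loglik_count(Y, E, rho, "poisson"), tolerance = 1e-4)
  # parameterization: mean lambda, variance lambda + lambda^2 / size
  k <- 0:5000
  p <- exp(loglik_count(k, 1, 10, "negbin", size = 1.6))
  expect_equal(sum(p * k), 10, tolerance = 1e-8)
  expect_equal(sum(p * k^2) - sum(p * k)^2, 10 + 100 / 1.6, tolerance = 1e-6)
  expect_error(loglik_count(-1, 1, 1, "poisson"), "non-negative")
  expect_error(loglik_count(1.5, 1, 1, "poisson"), "non-negative integers")
})

test_that("identity-RR data gives an intercept near zero", {
  f <- fitted_frame(n = 200, seed = 72,
                    coefs = c(0, 0.001, 0, 0.001, 0.001, 0, 0))
  f$villages$data$Y <- round(f$villages$data$E)
  fit <- suppressWarnings(fit_bhm(f$villages, f$adj,
         model_spec("poisson", spatial = FALSE, chains = 2,
                    iter = 1500, burnin = 500, seed = 5)))
  b0 <- fit$summary$mean[fit$summary$parameter == "intercept"]
  expect_lt(abs(b0), 0.05)
})

test_that("aspatial Poisson posterior agrees with the GLM oracle", {
  f <- fitted_frame(n = 400, seed = 73)
  fit <- suppressWarnings(fit_bhm(f$villages, f$adj,
         model_spec("poisson", spatial = FALSE, chains = 2,
                    iter = 3000, burnin = 1000, seed = 6)))
  X <- maskgap:::village_design(f$villages)
  g <- stats::glm.fit(X, f$villages$data$Y, family = stats::poisson(),
                      offset = log(f$villages$data$E))
  se <- sqrt(diag(chol2inv(chol(crossprod(X * sqrt(g$weights))))))
  expect_true(all(abs(fit$summary$mean[1:7] - g$coefficients) < 3.5 * se))
  expect_true(all(fit$summary$sd[1:7] < 2 * se) && all(fit$summary$sd[1:7] > se / 2))
})

test_that("aspatial negative binomial recovers the size parameter", {
  f <- fitted_frame(n = 600, seed = 74, family = "negbin",
                    size_parameter = 1.6)
  fit <- suppressWarnings(fit_bhm(f$villages, f$adj,
         model_spec("negbin", spatial = FALSE, chains = 2,
                    iter = 3000, burnin = 1000, seed = 7)))
  th <- fit$summary[fit$summary$parameter == "theta", ]
  expect_gt(th$mean, 1.6 - 3 * th$sd)
  expect_lt(th$mean, 1.6 + 3 * th$sd)
  expect_lt(abs(th$mean - 1.6), 0.6)
})

test_that("spatial fit recovers strong fixed effects and flags convergence", {
  f <- fitted_frame(n = 300, seed = 75, precision_spatial = 0.5,
                    precision_iid = 6.4)
  fit <- suppressWarnings(fit_bhm(f$villages, f$adj,
         model_spec("poisson", spatial = TRUE, chains = 2,
                    iter = 3000, burnin = 1500, seed = 8)))
  s <- fit$summary
  # residential (index 5) is the strongest effect; its CI should cover truth
  expect_gt(-1, s$q025[5]); expect_lt(-1, s$q975[5])
  expect_true(is.finite(fit$accept_beta))
  expect_s3_class(fit, "bhm_fit")
  expect_true(all(c("tau_u", "tau_v") %in% s$parameter))
  # lambda = E * rho pointwise per draw
  expect_equal(dim(fit$draws$rho), c(300L, 2L * 1500L))
  expect_true(all(fit$draws$rho > 0))
})

test_that("exceedance probabilities behave and match the lognormal oracle", {
  rho <- matrix(c(0.2, 0.5, 0.9, 1.5, 2, 3), nrow = 2, byrow = TRUE)
  expect_equal(exceedance(rho, 1), c(1, 0))
  set.seed(91)
  draws <- matrix(rlnorm(4e4), nrow = 4)
  pr <- exceedance(draws, 1)
  expect_equal(pr, rep(pnorm(0), 4), tolerance = 0.02)
  # monotone non-increasing as the threshold drops
  thr <- c(2, 1.5, 1, 0.7, 0.4)
  prs <- sapply(thr, function(t) exceedance(draws, t))
  expect_true(all(apply(prs, 1, diff) <= 0))
})

test_that("sum-to-zero recentring keeps the spatial field identified", {
  f <- fitted_frame(n = 150, seed = 76, precision_spatial = 1,
                    precision_iid = 10)
  fit <- suppressWarnings(fit_bhm(f$villages, f$adj,
         model_spec("poisson", spatial = TRUE, chains = 2,
                    iter = 1500, burnin = 500, seed = 9)))
  expect_lt(max(abs(rowMeans(fit$draws$u))), 1e-8)
})
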