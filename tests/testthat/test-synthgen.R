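test_that("village tessellation tiles the region and is reproducible", {
  cfg <- synth_config(n_villages = 4, n_stores = 2, region_size = 1000,
                      n_days = 1, seed = 1)
  vf <- generate_villages(cfg)
  areas <- vapply(vf$polygons, maskgap:::poly_area, numeric(1))
  expect_equal(sum(areas), 1000^2, tolerance = 1e-9)

  vf2 <- generate_villages(cfg)
  expect_identical(vf$data, vf2$data)
  expect_identical(vf$polygons, vf2$polygons)
})

test_that("generated covariates respect their ranges and the graph is connected", {
  cfg <- synth_config(n_villages = 50, n_stores = 10, region_size = 10000,
                      n_days = 1, seed = 7)
  vf <- generate_villages(cfg)
  d <- vf$data
  expect_true(all(d$pop > 0))
  expect_true(all(d$income > 0))
  shares <- as.matrix(d[, c("business", "residential", "mixed", "school")])
  expect_true(all(shares >= 0 & shares <= 1))
  expect_true(all(rowSums(shares) <= 1))
  expect_true(all(d$store_n >= 0 & d$store_n == round(d$store_n)))
  adj <- build_adjacency(vf)
  expect_equal(max(adj$components), 1)
})

test_that("too few villages is an error", {
  expect_error(synth_config(n_villages = 1), "n_villages")
})

test_that("inventory traces conserve stock exactly and honour zero sales", {
  cfg <- synth_config(n_villages = 5, n_stores = 3, region_size = 2000,
                      n_days = 4, seed = 3, restock_prob_per_day = 0.8)
  stores <- generate_stores(cfg)
  inv <- generate_inventory(cfg, stores)
  for (sid in stores$store_id) {
    tr <- inv$inventory[inv$inventory$store_id == sid, ]
    sold <- sum(inv$ledger$sales[inv$ledger$store_id == sid])
    restocked <- sum(inv$restocks$amount[inv$restocks$store_id == sid])
    initial <- inv$initial_stock$initial[inv$initial_stock$store_id == sid]
    expect_identical(tr$stock[nrow(tr)], initial + restocked - sold)
    expect_true(all(tr$stock >= 0))
  }

  cfg0 <- synth_config(n_villages = 5, n_stores = 1, region_size = 2000,
                       n_days = 4, seed = 3, restock_prob_per_day = 0)
  flat <- generate_inventory(cfg0, stores[1, , drop = FALSE], daily_sales = 0)
  expect_equal(length(unique(flat$inventory$stock)), 1L)
  expect_true(all(flat$ledger$sales == 0))
})

test_that("one-day no-restock trace loses exactly the realized sales", {
  cfg <- synth_config(n_villages = 5, n_stores = 1, region_size = 2000,
                      n_days = 1, seed = 11, restock_prob_per_day = 0)
  stores <- generate_stores(cfg)
  inv <- generate_inventory(cfg, stores, daily_sales = 90)
  tr <- inv$inventory
  expect_equal(tr$stock[1] - tr$stock[nrow(tr)], sum(inv$ledger$sales))
})

test_that("ICAR draws are sum-to-zero and simulate_counts is deterministic", {
  cfg <- synth_config(n_villages = 40, n_stores = 5, region_size = 8000,
                      n_days = 1, seed = 5)
  vf <- generate_villages(cfg)
  adj <- build_adjacency(vf)
  set.seed(9)
  u <- sample_icar(adj, 2)
  expect_lt(abs(sum(u)), 1e-8)

  sim1 <- simulate_counts(vf, cfg, adj)
  sim2 <- simulate_counts(vf, cfg, adj)
  expect_identical(sim1$villages$data$Y, sim2$villages$data$Y)
  expect_identical(sim1$truth$u, sim2$truth$u)
})

test_that("with null effects the relative risk is one and counts match E", {
  cfg <- synth_config(n_villages = 60, n_stores = 5, region_size = 8000,
                      n_days = 1, seed = 6,
                      true_coefficients = rep(0, 7),
                      precision_spatial = 1e12, precision_iid = 1e12)
  vf <- generate_villages(cfg)
  sim <- simulate_counts(vf, cfg)
  expect_equal(sim$truth$rho, rep(1, 60), tolerance = 1e-4)
  # Poisson draws around E: standardized residuals behave
  z <- (sim$villages$data$Y - sim$truth$E) / sqrt(sim$truth$E)
  expect_lt(abs(mean(z)), 0.5)
})

test_that("negative binomial with huge size collapses to Poisson dispersion", {
  # fixed rho = 1 and equal E everywhere: counts are iid draws, so the
  # pooled sample variance/mean ratio estimates the NB dispersion; 10^4
  # draws collected over 20 seeds of a 500-village frame
  vf <- grid_frame(25, 20)
  vf$data$pop <- 3000 # E = 0.033 * 3000 = 99, identical everywhere
  vf$data$store_n <- 0L; vf$data$income <- 1
  vf$data$business <- vf$data$residential <- vf$data$mixed <- vf$data$school <- 0
  adj <- build_adjacency(vf)
  Y <- unlist(lapply(1:20, function(s) {
    cfg <- synth_config(n_villages = 500, n_stores = 5, region_size = 25,
                        n_days = 1, seed = s, family = "negbin",
                        size_parameter = 1e6,
                        true_coefficients = rep(0, 7),
                        precision_spatial = 1e12, precision_iid = 1e12)
    simulate_counts(vf, cfg, adj)$villages$data$Y
  }))
  expect_length(Y, 10000)
  expect_equal(var(Y) / mean(Y), 1, tolerance = 0.05)

  # same construction at the study's overdispersion: ratio ~ 1 + lambda/size
  Y2 <- unlist(lapply(1:5, function(s) {
    cfg <- synth_config(n_villages = 500, n_stores = 5, region_size = 25,
                        n_days = 1, seed = s, family = "negbin",
                        size_parameter = 1.6,
                        true_coefficients = rep(0, 7),
                        precision_spatial = 1e12, precision_iid = 1e12)
    simulate_counts(vf, cfg, adj)$villages$data$Y
  }))
  expect_equal(var(Y2) / mean(Y2), 1 + 99 / 1.6, tolerance = 0.15)
})

test_that("study-scale coefficients give finite positive risks", {
  cfg <- synth_config(n_villages = 200, n_stores = 20, region_size = 15000,
                      n_days = 1, seed = 10)
  vf <- generate_villages(cfg)
  sim <- simulate_counts(vf, cfg)
  expect_true(all(is.finite(sim$truth$rho)))
  expect_true(all(sim$truth$rho > 0))
})

test_that("negbin family requires a positive size parameter", {
  expect_error(synth_config(family = "negbin", size_parameter = 0),
               "size_parameter")
})
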