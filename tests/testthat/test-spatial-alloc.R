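region_unit <- c(0, 1, 0, 1)

supply_df <- function(x, y, counts) {
  data.frame(store_id = sprintf("S%03d", seq_along(x)), x = x, y = y,
             avg_daily_customers = counts)
}

test_that("degenerate tessellations: one store, two symmetric stores", {
  s1 <- build_voronoi(supply_df(0.4, 0.6, 10), region_unit)
  expect_length(s1$cells, 1)
  expect_equal(maskgap:::poly_area(s1$cells[[1]]), 1)

  s2 <- build_voronoi(supply_df(c(0.25, 0.75), c(0.5, 0.5), c(3, 5)), region_unit)
  areas <- vapply(s2$cells, maskgap:::poly_area, numeric(1))
  expect_equal(areas, c(0.5, 0.5))
})

test_that("stores outside the region or an empty set are errors", {
  expect_error(build_voronoi(supply_df(numeric(0), numeric(0), numeric(0)),
                             region_unit), "no stores")
  expect_error(build_voronoi(supply_df(2, 0.5, 1), region_unit), "outside")
})

test_that("duplicate store locations are collapsed with counts summed", {
  s <- build_voronoi(supply_df(c(0.3, 0.3, 0.8), c(0.4, 0.4, 0.9), c(1, 2, 7)),
                     region_unit)
  expect_length(s$cells, 2)
  expect_equal(sum(s$counts), 10)
  expect_true(7 %in% s$counts && 3 %in% s$counts)
})

test_that("voronoi cells agree with brute-force nearest-neighbour assignment", {
  set.seed(41)
  n_s <- 20
  sup <- supply_df(runif(n_s), runif(n_s), rpois(n_s, 50))
  surf <- build_voronoi(sup, region_unit)
  px <- runif(1000); py <- runif(1000)
  nearest <- apply((outer(px, sup$x, "-"))^2 + (outer(py, sup$y, "-"))^2,
                   1, which.min)
  in_cell <- vapply(seq_along(px), function(k) {
    hits <- which(vapply(surf$cells, function(cl)
      maskgap:::point_in_poly(px[k], py[k], cl), logical(1)))
    hits[1]
  }, integer(1))
  expect_equal(mean(in_cell == nearest), 1)
})

test_that("areal interpolation: identity overlay and proportional split", {
  # village identical to the single cell
  vf <- frame_from_polys(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))), region_unit)
  surf <- build_voronoi(supply_df(0.5, 0.5, 105), region_unit)
  out <- areal_interpolate(surf, vf)
  expect_equal(out$data$Y_raw, 105)
  expect_equal(out$data$Y, 105)

  # village covering exactly half of a count-100 cell
  half <- frame_from_polys(list(cbind(c(0, 0.5, 0.5, 0), c(0, 0, 1, 1))),
                           region_unit)
  out2 <- areal_interpolate(build_voronoi(supply_df(0.5, 0.5, 100), region_unit),
                            half)
  expect_equal(out2$data$Y_raw, 50)
})

test_that("interpolation conserves mass and is linear in counts", {
  cfg <- small_cfg(seed = 31)
  vf <- generate_villages(cfg)
  set.seed(32)
  sup <- supply_df(runif(12, 0, 5000), runif(12, 0, 5000), rgamma(12, 50))
  surf <- build_voronoi(sup, vf$region)
  out <- areal_interpolate(surf, vf)
  expect_equal(sum(out$data$Y_raw), sum(surf$counts), tolerance = 1e-9)

  sup2 <- sup; sup2$avg_daily_customers <- 2 * sup$avg_daily_customers
  out2 <- areal_interpolate(build_voronoi(sup2, vf$region), vf)
  expect_equal(out2$data$Y_raw, 2 * out$data$Y_raw, tolerance = 1e-12)
})

test_that("interpolated shares match a Monte Carlo overlay oracle", {
  # random 4-cell / 6-village fixture; the oracle rasterizes the overlay
  # with uniform sample points
  set.seed(33)
  sup <- supply_df(runif(4), runif(4), c(100, 40, 250, 10))
  surf <- build_voronoi(sup, region_unit)
  cfg6 <- synth_config(n_villages = 6, n_stores = 2, region_size = 1,
                       n_days = 1, seed = 34)
  vf <- generate_villages(cfg6)
  out <- areal_interpolate(surf, vf)

  m <- 1e6
  px <- runif(m); py <- runif(m)
  cell_of <- max.col(-((outer(px, sup$x, "-"))^2 + (outer(py, sup$y, "-"))^2),
                     ties.method = "first")
  vil_of <- integer(m)
  for (v in seq_along(vf$polygons)) {
    p <- vf$polygons[[v]]
    inside <- maskgap:::point_in_poly(px, py, p)
    vil_of[inside & vil_of == 0L] <- v
  }
  cell_pts <- tabulate(cell_of, 4)
  y_mc <- vapply(seq_along(vf$polygons), function(v) {
    sum(surf$counts * tabulate(cell_of[vil_of == v], 4) / cell_pts)
  }, numeric(1))
  expect_equal(out$data$Y_raw, y_mc, tolerance = 0.005)
})

test_that("a zero-area cell donates its count to the village holding its generator", {
  cells <- list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                cbind(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))) # degenerate
  surf <- surface_from_cells(cells, counts = c(10, 7),
                             generators = rbind(c(0.5, 0.5), c(0.2, 0.2)),
                             region = region_unit)
  vf <- frame_from_polys(list(cbind(c(0, 0.5, 0.5, 0), c(0, 0, 1, 1)),
                              cbind(c(0.5, 1, 1, 0.5), c(0, 0, 1, 1))),
                         region_unit)
  out <- areal_interpolate(surf, vf)
  expect_equal(out$data$Y_raw, c(5 + 7, 5))
})

test_that("store counting partitions stores over villages deterministically", {
  cfg <- small_cfg(seed = 35)
  vf <- generate_villages(cfg)
  expect_equal(count_stores_in_village(data.frame(store_id = character(),
                                                  x = numeric(), y = numeric()),
                                       vf),
               rep(0L, 30))
  set.seed(36)
  stores <- data.frame(store_id = sprintf("S%03d", 1:100),
                       x = runif(100, 0, 5000), y = runif(100, 0, 5000))
  cnt <- count_stores_in_village(stores, vf)
  expect_equal(sum(cnt), 100)

  # a store exactly on a shared boundary is counted exactly once
  gvf <- grid_frame(2, 1)
  onb <- data.frame(store_id = "S001", x = 1, y = 0.5)
  expect_equal(sum(count_stores_in_village(onb, gvf)), 1)
  expect_equal(count_stores_in_village(onb, gvf), c(1L, 0L))
})
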