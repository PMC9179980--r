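# Fixture builders shared across tests. Everything is generated in code;
# no data files.

# A village_frame of nx x ny unit squares (row-major ids), for tests that
# need known topology rather than a random tessellation.
grid_frame <- function(nx, ny, cell = 1) {
  polys <- list()
  ids <- character(0)
  k <- 0
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1
      x0 <- (i - 1) * cell; y0 <- (j - 1) * cell
      polys[[k]] <- cbind(c(x0, x0 + cell, x0 + cell, x0),
                          c(y0, y0, y0 + cell, y0 + cell))
      ids[k] <- sprintf("V%04d", k)
    }
  }
  names(polys) <- ids
  n <- nx * ny
  dat <- data.frame(village_id = ids, pop = rep(1000, n), store_n = 0L,
                    income = 439, business = 0.02, residential = 0.2,
                    mixed = 0.1, school = 0.01, stringsAsFactors = FALSE)
  structure(list(data = dat, polygons = polys,
                 region = c(0, nx * cell, 0, ny * cell)),
            class = "village_frame")
}

# A frame with externally supplied polygons and default covariates.
frame_from_polys <- function(polys, region, pop = 1000) {
  n <- length(polys)
  ids <- sprintf("V%04d", seq_len(n))
  names(polys) <- ids
  dat <- data.frame(village_id = ids, pop = rep_len(pop, n), store_n = 0L,
                    income = 439, business = 0.02, residential = 0.2,
                    mixed = 0.1, school = 0.01, stringsAsFactors = FALSE)
  structure(list(data = dat, polygons = polys, region = region),
            class = "village_frame")
}

# A ready voronoi_surface from raw pieces (bypassing build_voronoi).
surface_from_cells <- function(cells, counts, generators, region) {
  structure(list(cells = cells, counts = counts, generators = generators,
                 store_id = sprintf("S%03d", seq_along(cells)),
                 region = region),
            class = "voronoi_surface")
}

# Inventory series on an hourly grid from given stock levels (one store).
series_from_hourly <- function(stocks, start = "2020-04-09 08:00:00") {
  data.frame(store_id = "S001",
             timestamp = as.POSIXct(start, tz = "UTC") + 3600 * (seq_along(stocks) - 1),
             stock = stocks, stringsAsFactors = FALSE)
}

# Quick small config for pipeline-scale tests.
small_cfg <- function(seed = 1, ...) {
  synth_config(n_villages = 30, n_stores = 15, region_size = 5000,
               n_days = 3, seed = seed, ...)
}
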