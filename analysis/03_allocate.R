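#!/usr/bin/env Rscript
# Stage 3 — change of support: stores -> villages.
#
# Tessellates the region into Voronoi service areas (one convex cell per
# pharmacy), then splits each cell's average daily customers over the
# villages it intersects in proportion to intersection area (homogeneous
# density within a cell). Also counts pharmacies per village: the first
# model covariate. Total customer mass must be conserved exactly.

library(maskgap)

res_dir <- "results/run"
supply <- read.csv(file.path(res_dir, "supply.csv"))
stores <- read.csv(file.path(res_dir, "stores.csv"))
villages <- read_villages_geojson(file.path(res_dir, "villages.geojson"))

surface <- build_voronoi(supply, villages$region)
write_surface_geojson(surface, file.path(res_dir, "surface.geojson"))

villages <- areal_interpolate(surface, villages)
villages$data$store_n <- count_stores_in_village(stores, villages)
write_villages_geojson(villages, file.path(res_dir, "villages_y.geojson"))

rel_err <- abs(sum(villages$data$Y_raw) - sum(surface$counts)) / sum(surface$counts)
cat(sprintf("Voronoi surface: %d cells. Interpolated %0.f customers onto %d villages.\n",
            length(surface$cells), sum(villages$data$Y_raw), nrow(villages$data)))
cat(sprintf("Mass conservation relative error: %.2e (tolerance 1e-9).\n", rel_err))
stopifnot(rel_err < 1e-9)
cat(sprintf("Supply count per village: median %d, max %d; pharmacies per village: 0-%d.\n",
            median(villages$data$Y), max(villages$data$Y), max(villages$data$store_n)))
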