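#!/usr/bin/env Rscript
# Stage 6 — choropleth export.
#
# Renders the raw relative-risk surface, each model's posterior-mean RR on
# a diverging scale anchored at RR = 1 (blue = undersupply, red =
# oversupply), and the undersupply probability Pr(RR < 1) for each spatial
# model — the map a health authority would use to rank villages for
# priority allocation.

library(maskgap)

res_dir <- "results/run"
villages <- read_villages_geojson(file.path(res_dir, "villages_model.geojson"))
fits <- list()
for (nm in c("poisson", "negbin", "poisson_spatial", "negbin_spatial")) {
  fits[[nm]] <- readRDS(file.path(res_dir, paste0("fit_", nm, ".rds")))
}

files <- export_maps(villages, fits, res_dir, threshold = 1)
cat("Wrote", length(files), "maps:\n")
cat(paste(" -", basename(files)), sep = "\n")

psp <- fits$poisson_spatial
flagged <- sum(exceedance(psp) > 0.8)
cat(sprintf("\n%d of %d villages have Pr(RR < 1) > 0.8 under the Poisson spatial model.\n",
            flagged, length(psp$Y)))
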