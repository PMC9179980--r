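#!/usr/bin/env Rscript
# Stage 1 — synthesize the study region.
#
# Builds a synthetic metropolitan study area in the image of the system the
# package models: a square region tiled by village polygons with adult
# populations, income and land-use covariates; pharmacies with expected
# daily sales; and 10-minute inventory traces over a two-week rationing
# window, with the realized per-day sales kept as a ground-truth ledger.
# The full-scale defaults (1488 villages, 1774 stores, 49 days) make sense
# on a workstation; here the analysis runs a 400-village / 300-store /
# 14-day region so the whole workflow completes in a few minutes.

library(maskgap)

res_dir <- "results/run"
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(
  n_villages = 400, n_stores = 300, region_size = 25000,
  n_days = 14, seed = 20200409, restock_prob_per_day = 0.3
)
jsonlite::write_json(unclass(cfg), file.path(res_dir, "config.json"),
                     auto_unbox = TRUE, digits = NA) # stage handoff

villages <- generate_villages(cfg)
stores <- generate_stores(cfg)
inventory <- generate_inventory(cfg, stores)

write_villages_geojson(villages, file.path(res_dir, "villages.geojson"))
write.csv(stores, file.path(res_dir, "stores.csv"), row.names = FALSE)
write_inventory_csv(inventory$inventory, file.path(res_dir, "inventory.csv"))
write.csv(inventory$ledger, file.path(res_dir, "sales_ledger_truth.csv"),
          row.names = FALSE)

cat(sprintf(
  "Simulated %d villages (median adult pop %d) and %d pharmacies over a %.0f km square.\n",
  nrow(villages$data), round(median(villages$data$pop)), nrow(stores),
  cfg$region_size / 1000))
cat(sprintf(
  "Inventory: %d ten-minute observations across %d days; %d restock events; %s masks sold in truth.\n",
  nrow(inventory$inventory), cfg$n_days, nrow(inventory$restocks),
  format(sum(inventory$ledger$sales), big.mark = ",")))
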