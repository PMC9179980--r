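# End-to-end orchestration: simulate -> preprocess -> allocate -> demand ->
# fit -> evaluate -> maps. Stages communicate through files in the run
# directory so each is independently inspectable and resumable; a manifest
# records seeds, configuration and per-stage timing.

#' Run the full supply-demand pipeline on a synthetic region
#'
#' Generates a study region, builds inventory traces, preprocesses them to
#' store supply, allocates customers to villages through the Voronoi
#' surface, computes expected counts, fits the requested hierarchical
#' models, scores them, and exports tables and choropleth maps. Every
#' artefact lands under `out_dir`.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory (created if missing).
#' @param models named list of [model_spec()] objects to fit; defaults to
#'   the four models of the framework (Poisson and negative binomial, each
#'   with and without the spatial terms) at `sampler` settings.
#' @param sampler list of shared sampler settings passed to [model_spec()]
#'   (`chains`, `iter`, `burnin`, `thin`, `seed`).
#' @param threshold exceedance threshold for `Pr(rho < threshold)`.
#' @param maps logical; render choropleth PNGs.
#' @return Invisibly, a list with the fitted objects, score table, village
#'   frame and manifest.
#' @export
run_pipeline <- function(cfg, out_dir, models = NULL,
                         sampler = list(chains = 2, iter = 2000, burnin = 1000,
                                        thin = 1, seed = cfg$seed),
                         threshold = 1, maps = TRUE) {
  stopifnot(inherits(cfg, "synth_config"), threshold > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, config = unclass(cfg),
                   sampler = sampler, threshold = threshold,
                   r_version = as.character(getRversion()),
                   stages = list(), warnings = list())
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    manifest$stages[[stage]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  # 1. simulate region
  villages <- tick("simulate_villages", generate_villages(cfg))
  stores <- tick("simulate_stores", generate_stores(cfg))
  inv <- tick("simulate_inventory", generate_inventory(cfg, stores))
  write_villages_geojson(villages, file.path(out_dir, "villages.geojson"))
  utils::write.csv(stores, file.path(out_dir, "stores.csv"), row.names = FALSE)
  write_inventory_csv(inv$inventory, file.path(out_dir, "inventory.csv"))
  utils::write.csv(inv$ledger, file.path(out_dir, "sales_ledger_truth.csv"),
                   row.names = FALSE)

  # 2. preprocess inventory -> store supply
  supply <- tick("preprocess", supply_from_inventory(inv$inventory, stores, cfg$quota))
  utils::write.csv(supply, file.path(out_dir, "supply.csv"), row.names = FALSE)

  # 3. allocate to villages
  region <- villages$region
  surface <- tick("voronoi", build_voronoi(supply, region))
  write_surface_geojson(surface, file.path(out_dir, "surface.geojson"))
  villages <- tick("interpolate", areal_interpolate(surface, villages))
  villages$data$store_n <- count_stores_in_village(stores, villages)

  # 4. demand side
  dem <- tick("demand", expected_counts(villages))
  villages <- dem$villages
  write_villages_geojson(villages, file.path(out_dir, "villages_y.geojson"))

  # 5. fit models
  if (is.null(models)) {
    mk <- function(family, spatial) do.call(model_spec, c(list(family = family, spatial = spatial), sampler))
    models <- list(
      poisson = mk("poisson", FALSE),
      negbin = mk("negbin", FALSE),
      poisson_spatial = mk("poisson", TRUE),
      negbin_spatial = mk("negbin", TRUE)
    )
  }
  adj <- tick("adjacency", build_adjacency(villages))
  utils::write.csv(adjacency_edges(adj), file.path(out_dir, "adjacency.csv"),
                   row.names = FALSE)
  fits <- list()
  for (nm in names(models)) {
    fits[[nm]] <- tick(paste0("fit_", nm), withCallingHandlers(
      fit_bhm(villages, adj, models[[nm]]),
      warning = function(w) {
        manifest$warnings[[length(manifest$warnings) + 1L]] <<-
          paste0(nm, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
    utils::write.csv(fits[[nm]]$summary,
                     file.path(out_dir, paste0("posterior_", nm, ".csv")),
                     row.names = FALSE)
    rs <- fits[[nm]]$rho_summary
    rs$pr_under <- exceedance(fits[[nm]], threshold)
    utils::write.csv(rs, file.path(out_dir, paste0("villages_", nm, ".csv")),
                     row.names = FALSE)
  }

  # 6. evaluate
  scores <- tick("evaluate", compare_models(fits))
  utils::write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  vif <- vif_report(villages)
  utils::write.csv(data.frame(covariate = names(vif), vif = as.numeric(vif)),
                   file.path(out_dir, "vif.csv"), row.names = FALSE)

  # 7. maps
  if (maps) tick("maps", export_maps(villages, fits, out_dir, threshold))

  manifest$n_villages_modeled <- sum(villages$data$modeled)
  manifest$service_rate <- dem$r
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(villages = villages, supply = supply, surface = surface,
                 adjacency = adj, fits = fits, scores = scores, vif = vif,
                 manifest = manifest))
}

adjacency_edges <- function(adj) {
  idx <- which(adj$a != 0 & upper.tri(adj$a), arr.ind = TRUE)
  ids <- if (!is.null(adj$ids)) adj$ids else seq_along(adj$N)
  data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]])
}

#' Export choropleth maps of relative risks and exceedance probabilities
#'
#' Renders the raw relative risk, each model's posterior-mean relative risk
#' (all on a diverging scale anchored at RR = 1), and each spatial model's
#' undersupply probability `Pr(rho < threshold)`.
#'
#' @param villages a `village_frame` with `rho_raw`.
#' @param fits named list of `bhm_fit` objects (may be empty: raw map only).
#' @param out_dir directory for the PNG files.
#' @param threshold exceedance threshold.
#' @return invisible character vector of files written.
#' @export
export_maps <- function(villages, fits = list(), out_dir = ".", threshold = 1) {
  stopifnot(inherits(villages, "village_frame"))
  df <- polygons_df(villages)
  files <- character(0)
  save_map <- function(values, title, file, diverging = TRUE) {
    dfx <- df
    dfx$value <- values[match(df$village_id, villages$data$village_id)]
    v <- dfx$value
    g <- ggplot2::ggplot(dfx, ggplot2::aes(x = x, y = y,
                                           group = village_id,
                                           fill = value)) +
      ggplot2::geom_polygon(color = "grey30", linewidth = 0.05) +
      ggplot2::coord_equal() +
      ggplot2::labs(title = title, fill = NULL) +
      ggplot2::theme_void()
    g <- if (diverging) {
      g + ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#F7F7F7",
                                        high = "#B2182B", midpoint = 0,
                                        limits = range(c(v, 0), na.rm = TRUE))
    } else {
      g + ggplot2::scale_fill_gradient(low = "#FFFFCC", high = "#800026",
                                       limits = c(0, 1))
    }
    path <- file.path(out_dir, file)
    ggplot2::ggsave(path, g, width = 6, height = 5.5, dpi = 120)
    files <<- c(files, path)
  }
  # log2(RR) so the diverging midpoint 0 is exactly RR = 1
  if (!is.null(villages$data$rho_raw)) {
    save_map(log2(pmax(villages$data$rho_raw, 1 / 64)), "raw RR (log2, 0 = parity)",
             "map_rr_raw.png")
  }
  for (nm in names(fits)) {
    f <- fits[[nm]]
    rho <- rep(NA_real_, nrow(villages$data))
    rho[f$modeled_index] <- rowMeans(f$draws$rho)
    save_map(log2(rho), paste0(nm, " posterior RR (log2, 0 = parity)"),
             paste0("map_rr_", nm, ".png"))
    pr <- rep(NA_real_, nrow(villages$data))
    pr[f$modeled_index] <- exceedance(f, threshold)
    save_map(pr, paste0(nm, " Pr(RR < ", threshold, ")"),
             paste0("map_pr_under_", nm, ".png"), diverging = FALSE)
  }
  invisible(files)
}

polygons_df <- function(villages) {
  d <- villages$data
  do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    p <- villages$polygons[[i]]
    data.frame(village_id = d$village_id[i], x = p[, 1], y = p[, 2])
  }))
}
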