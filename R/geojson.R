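# GeoJSON input/output for the village frames and Voronoi surfaces.
# Coordinates are planar metres (the study CRS), carried verbatim in the
# coordinate arrays; attributes travel in each feature's properties.

#' Write a village frame to GeoJSON
#'
#' One Polygon feature per village; all data columns become feature
#' properties. The region bounding box is stored under the top-level `bbox`.
#'
#' @param villages a `village_frame`.
#' @param path output file.
#' @export
write_villages_geojson <- function(villages, path) {
  stopifnot(inherits(villages, "village_frame"))
  d <- villages$data
  features <- lapply(seq_len(nrow(d)), function(i) {
    poly <- villages$polygons[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE]) # close the ring
    list(
      type = "Feature",
      properties = as.list(d[i, , drop = FALSE]),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(split_coords(ring))))
    )
  })
  fc <- list(type = "FeatureCollection",
             bbox = villages$region[c(1, 3, 2, 4)],
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}

split_coords <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))

#' Read a village frame from GeoJSON
#'
#' Inverse of [write_villages_geojson()].
#'
#' @param path GeoJSON file written by this package.
#' @return a `village_frame`.
#' @export
read_villages_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  features <- fc$features
  polys <- lapply(features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(xy) c(xy[[1]], xy[[2]])))
    ring[-nrow(ring), , drop = FALSE] # reopen the ring
  })
  props <- lapply(features, function(f) {
    as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  })
  dat <- do.call(rbind, props)
  bbox <- unlist(fc$bbox)
  region <- c(bbox[1], bbox[3], bbox[2], bbox[4])
  names(polys) <- dat$village_id
  structure(list(data = dat, polygons = polys, region = region),
            class = "village_frame")
}

#' Write a Voronoi surface to GeoJSON
#'
#' @param surface a [build_voronoi()] result.
#' @param path output file.
#' @export
write_surface_geojson <- function(surface, path) {
  stopifnot(inherits(surface, "voronoi_surface"))
  features <- lapply(seq_along(surface$cells), function(i) {
    poly <- surface$cells[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(store_id = surface$store_id[i],
                        avg_daily_customers = surface$counts[i],
                        gen_x = surface$generators[i, 1],
                        gen_y = surface$generators[i, 2]),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(split_coords(ring))))
    )
  })
  fc <- list(type = "FeatureCollection",
             bbox = surface$region[c(1, 3, 2, 4)],
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}
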