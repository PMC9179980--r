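# Change-of-support step: store points -> Voronoi service areas -> village
# polygons, redistributing customer counts by intersection area under the
# homogeneous-density assumption.

#' Build the Voronoi service-area surface of the stores
#'
#' Partitions the study region into one convex cell per store; every interior
#' point of a cell is nearer (Euclidean) to its generating store than to any
#' other. Stores at duplicate locations are collapsed and their customer
#' counts summed before tessellation. Cells are clipped to the rectangular
#' study region.
#'
#' @param supply data.frame with `store_id`, `x`, `y`, `avg_daily_customers`.
#' @param region `c(xmin, xmax, ymin, ymax)` of the study region, metres.
#' @return A `voronoi_surface`: list with `cells` (vertex matrices),
#'   `counts`, `generators` (matrix of points) and `region`.
#' @export
build_voronoi <- function(supply, region) {
  if (nrow(supply) == 0) stop("no stores")
  inside <- supply$x >= region[1] & supply$x <= region[2] &
            supply$y >= region[3] & supply$y <= region[4]
  if (!all(inside)) stop("stores outside the study region: ",
                         paste(supply$store_id[!inside], collapse = ", "))
  key <- paste(supply$x, supply$y)
  if (anyDuplicated(key)) {
    counts <- tapply(supply$avg_daily_customers, key, sum)
    first <- !duplicated(key)
    supply <- supply[first, , drop = FALSE]
    supply$avg_daily_customers <- as.numeric(counts[paste(supply$x, supply$y)])
  }
  pts <- cbind(supply$x, supply$y)
  cells <- if (nrow(pts) == 1) {
    list(matrix(c(region[1], region[3], region[2], region[3],
                  region[2], region[4], region[1], region[4]),
                ncol = 2, byrow = TRUE))
  } else {
    voronoi_polygons(pts, region)
  }
  structure(list(cells = cells, counts = supply$avg_daily_customers,
                 generators = pts, store_id = supply$store_id,
                 region = region),
            class = "voronoi_surface")
}

#' @export
print.voronoi_surface <- function(x, ...) {
  cat("voronoi_surface:", length(x$cells), "cells, total count",
      format(sum(x$counts)), "\n")
  invisible(x)
}

#' Areally interpolate cell counts onto village polygons
#'
#' Each cell's count is split over the villages it intersects in proportion
#' to intersection area (homogeneous density within a cell):
#' `Y_i = sum_cells count_c * area(cell_c intersect village_i) / area(cell_c)`.
#' When the villages tile the region the full mass is conserved. A
#' degenerate zero-area cell contributes its whole count to the village
#' containing its generator point.
#'
#' @param surface a [build_voronoi()] result.
#' @param villages a `village_frame`.
#' @return The `village_frame` with columns `Y_raw` (fractional interpolated
#'   count) and `Y` (rounded half-to-even to an integer for the count
#'   likelihoods) added.
#' @export
areal_interpolate <- function(surface, villages) {
  stopifnot(inherits(surface, "voronoi_surface"),
            inherits(villages, "village_frame"))
  vp <- villages$polygons
  n_v <- length(vp)
  vb <- lapply(vp, poly_bbox)
  y <- numeric(n_v)
  area_tol <- 1e-9
  for (c_i in seq_along(surface$cells)) {
    cell <- surface$cells[[c_i]]
    a_cell <- poly_area(cell)
    cnt <- surface$counts[c_i]
    if (cnt == 0) next
    if (a_cell <= area_tol) {
      g <- surface$generators[c_i, ]
      hit <- which(vapply(vp, function(p) point_in_poly(g[1], g[2], p), logical(1)))
      if (length(hit)) y[hit[1]] <- y[hit[1]] + cnt
      next
    }
    cb <- poly_bbox(cell)
    for (v_i in seq_len(n_v)) {
      if (!bbox_overlap(cb, vb[[v_i]])) next
      a_int <- intersection_area(vp[[v_i]], cell)
      if (a_int > area_tol) y[v_i] <- y[v_i] + cnt * a_int / a_cell
    }
  }
  villages$data$Y_raw <- y
  villages$data$Y <- round(y)
  villages
}

#' Count stores falling in each village
#'
#' Point-in-polygon store counts, the first model covariate. A store on a
#' shared boundary is assigned to the single village whose id sorts first,
#' so every store is counted exactly once.
#'
#' @param stores data.frame with `store_id`, `x`, `y`.
#' @param villages a `village_frame`.
#' @return integer vector of counts in village order; also written to
#'   `villages$data$store_n` by [pipeline_allocate()].
#' @export
count_stores_in_village <- function(stores, villages) {
  stopifnot(inherits(villages, "village_frame"))
  vp <- villages$polygons
  ord <- order(villages$data$village_id)
  counts <- integer(length(vp))
  assigned <- rep(FALSE, nrow(stores))
  for (v_i in ord) {
    p <- vp[[v_i]]
    todo <- which(!assigned)
    if (!length(todo)) break
    inside <- point_in_poly(stores$x[todo], stores$y[todo], p)
    hit <- todo[inside]
    counts[v_i] <- length(hit)
    assigned[hit] <- TRUE
  }
  counts
}
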