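# Queen contiguity between village polygons: a single shared boundary point
# suffices. Built geometrically (bounding-box prune + minimum boundary
# distance under tolerance) because the tessellations here store no shared
# topology.

#' Build the queen-contiguity adjacency of a village tessellation
#'
#' Two villages are neighbours when their polygon boundaries come within a
#' small tolerance of each other (shared edge or shared vertex). Returns the
#' binary weight matrix of the ICAR prior, neighbour lists, neighbour counts
#' and connected-component labels; villages with no neighbour are islands.
#'
#' @param villages a `village_frame`.
#' @param tol contact tolerance in map units; defaults to 1e-6 of the region
#'   diagonal.
#' @return An `adjacency`: list with `a` (symmetric 0/1 matrix, zero
#'   diagonal), `nb` (list of neighbour index vectors), `N` (neighbour
#'   counts) and `components` (integer labels).
#' @export
build_adjacency <- function(villages, tol = NULL) {
  stopifnot(inherits(villages, "village_frame"))
  polys <- villages$polygons
  n <- length(polys)
  if (is.null(tol)) {
    dx <- villages$region[2] - villages$region[1]
    dy <- villages$region[4] - villages$region[3]
    tol <- 1e-6 * sqrt(dx^2 + dy^2)
  }
  bb <- t(vapply(polys, poly_bbox, numeric(4)))
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    j_cand <- which(bb[, 1] <= bb[i, 2] + tol & bb[, 2] >= bb[i, 1] - tol &
                    bb[, 3] <= bb[i, 4] + tol & bb[, 4] >= bb[i, 3] - tol)
    j_cand <- j_cand[j_cand > i]
    for (j in j_cand) {
      if (poly_min_distance(polys[[i]], polys[[j]]) <= tol) {
        a[i, j] <- a[j, i] <- 1L
      }
    }
  }
  adjacency_from_matrix(a, villages$data$village_id)
}

# Assemble the adjacency object from a 0/1 matrix (also used directly by
# tests with hand-built lattices).
adjacency_from_matrix <- function(a, ids = NULL) {
  stopifnot(isSymmetric(unname(a)), all(diag(a) == 0))
  n <- nrow(a)
  nb <- lapply(seq_len(n), function(i) which(a[i, ] != 0))
  N <- vapply(nb, length, integer(1))
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  structure(list(a = a, nb = nb, N = N, components = comp, ids = ids),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat("adjacency:", length(x$N), "areas,", sum(x$N) / 2, "edges,",
      max(x$components), "component(s),", sum(x$N == 0), "island(s)\n")
  invisible(x)
}

# Flattened neighbour structure for the C++ sampler: 0-based concatenated
# neighbour indices plus row offsets (CRS layout).
adjacency_crs <- function(adj) {
  idx <- unlist(adj$nb, use.names = FALSE) - 1L
  ptr <- c(0L, cumsum(vapply(adj$nb, length, integer(1))))
  list(idx = as.integer(idx), ptr = as.integer(ptr))
}
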