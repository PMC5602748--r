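#' Geodesic distances from a source vertex
#'
#' Edge-graph shortest paths (Dijkstra) from one source vertex to every other
#' vertex, the discrete stand-in for geodesic distance on the tessellated
#' surface. Equal-length paths are resolved deterministically by preferring
#' the predecessor with the smallest vertex id. Unreachable vertices carry an
#' `Inf` distance and an `NA` predecessor.
#'
#' @param mesh an [sd_mesh()]
#' @param source 1-based vertex id
#' @return a `geodesic_map`: list(source, dist, pred)
#' @export
geodesic_from <- function(mesh, source) {
  n <- nrow(mesh$vertices)
  if (source < 1L || source > n) stop(sprintf("source %d out of range 1..%d", source, n))
  csr <- mesh_csr(mesh)
  res <- dijkstra_csr(csr$ptr, csr$idx, csr$w, as.integer(source - 1L))
  pred <- res$pred[, 1] + 1L
  pred[pred == 0L] <- NA_integer_
  structure(list(source = as.integer(source), dist = res$dist[, 1], pred = pred),
            class = "geodesic_map")
}

# distances (and predecessors) from several sources at once; returns matrices
geodesic_multi <- function(mesh, sources) {
  csr <- mesh_csr(mesh)
  res <- dijkstra_csr(csr$ptr, csr$idx, csr$w, as.integer(sources - 1L))
  pred <- res$pred + 1L
  pred[pred == 0L] <- NA_integer_
  list(dist = res$dist, pred = pred, sources = as.integer(sources))
}

#' @export
print.geodesic_map <- function(x, ...) {
  cat(sprintf("<geodesic_map> source %d, %d vertices (%d unreachable)\n",
              x$source, length(x$dist), sum(is.infinite(x$dist))))
  invisible(x)
}

#' Extract the shortest path to a target vertex
#'
#' Follows the predecessor chain of a [geodesic_from()] map. The cumulative
#' edge length along the returned path equals the stored distance.
#'
#' @param gmap a `geodesic_map`
#' @param target 1-based vertex id
#' @return ordered integer vector of vertex ids from source to target
#' @export
shortest_path <- function(gmap, target) {
  if (target < 1L || target > length(gmap$dist))
    stop(sprintf("target %d out of range", target))
  if (is.infinite(gmap$dist[target]))
    stop(sprintf("target %d unreachable from source %d", target, gmap$source))
  path <- integer(0)
  v <- as.integer(target)
  while (!is.na(v)) {
    path <- c(v, path)
    if (v == gmap$source) break
    v <- gmap$pred[v]
  }
  if (path[1] != gmap$source) stop("broken predecessor chain")
  path
}
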