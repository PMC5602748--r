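#' Triangle surface mesh
#'
#' The geometric substrate for all trajectory computations: a discretized
#' (tessellated) cortical surface patch, stored as world-millimetre vertex
#' coordinates and 1-based triangle vertex indices.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm
#' @param faces integer matrix (m x 3), 1-based vertex indices
#' @param scalar optional per-vertex numeric channel (e.g. a heatmap)
#' @param validate check the mesh invariants (default TRUE)
#' @return an object of class `sd_mesh`
#' @export
sd_mesh <- function(vertices, faces, scalar = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  m <- structure(list(vertices = vertices, faces = faces, scalar = scalar),
                 class = "sd_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.sd_mesh <- function(x, ...) {
  cat(sprintf("<sd_mesh> %d vertices, %d faces, mean edge %.3f mm\n",
              nrow(x$vertices), nrow(x$faces),
              if (nrow(x$faces)) mean(mesh_edge_lengths(x)) else NA_real_))
  invisible(x)
}

#' Check mesh invariants
#'
#' Verifies index ranges, absence of zero-length edges, edge-manifoldness
#' (each edge shared by at most two faces) and consistent face orientation
#' (a shared edge is traversed in opposite directions by its two faces).
#'
#' @param mesh an `sd_mesh`
#' @return invisibly TRUE; stops with a structured message otherwise
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(v) == 0L) stop("empty mesh")
  if (nrow(f) > 0L) {
    bad <- which(f < 1L | f > nrow(v), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("face %d references vertex %d, out of range 1..%d",
                   bad[1, 1], f[bad[1, 1], bad[1, 2]], nrow(v)))
    }
    e <- mesh_edges(mesh)
    len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
    if (any(len == 0)) stop(sprintf("zero-length edge between vertices %d and %d",
                                    e[which(len == 0)[1], 1], e[which(len == 0)[1], 2]))
    # directed half-edges: manifold + orientation check
    he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key_u <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
    cnt <- table(key_u)
    if (any(cnt > 2)) {
      k <- names(cnt)[cnt > 2][1]
      stop(sprintf("non-manifold edge (%s) shared by %d faces", k, max(cnt)))
    }
    key_d <- paste(he[, 1], he[, 2])
    if (anyDuplicated(key_d)) {
      k <- key_d[duplicated(key_d)][1]
      stop(sprintf("inconsistent face orientation at edge (%s)", k))
    }
  }
  invisible(TRUE)
}

#' Unique undirected edges of a mesh
#' @param mesh an `sd_mesh`
#' @return integer matrix (e x 2), each row sorted ascending, rows unique
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Edge lengths (mm) in the order of [mesh_edges()]
#' @param mesh an `sd_mesh`
#' @param edges optionally precomputed edges
#' @export
mesh_edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  v <- mesh$vertices
  sqrt(rowSums((v[edges[, 1], , drop = FALSE] - v[edges[, 2], , drop = FALSE])^2))
}

#' Triangle areas (mm^2)
#' @param mesh an `sd_mesh`
#' @export
mesh_face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Boundary vertices (incident to an edge with a single adjacent face)
#' @param mesh an `sd_mesh`
#' @return integer vector of vertex ids
#' @export
mesh_boundary_vertices <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  bkeys <- names(cnt)[cnt == 1]
  if (!length(bkeys)) return(integer(0))
  ij <- do.call(rbind, strsplit(bkeys, " "))
  sort(unique(as.integer(ij)))
}

# CSR adjacency of the vertex-edge graph with Euclidean edge weights
mesh_csr <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- mesh_edge_lengths(mesh, e)
  n <- nrow(mesh$vertices)
  from <- c(e[, 1], e[, 2]); to <- c(e[, 2], e[, 1]); ww <- c(w, w)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; ww <- ww[o]
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  list(ptr = as.integer(ptr), idx = as.integer(to - 1L), w = ww, n = n)
}

# vertex -> neighbour list (1-based), used by subdivision and smoothing
mesh_vertex_neighbors <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  nb <- vector("list", n)
  sp1 <- split(e[, 2], e[, 1])
  sp2 <- split(e[, 1], e[, 2])
  for (k in names(sp1)) nb[[as.integer(k)]] <- c(nb[[as.integer(k)]], sp1[[k]])
  for (k in names(sp2)) nb[[as.integer(k)]] <- c(nb[[as.integer(k)]], sp2[[k]])
  lapply(nb, function(x) sort(unique(x)))
}
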