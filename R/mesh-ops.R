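#' Interpolating 4-split mesh up-sampling
#'
#' Each triangle is split into four by inserting one new vertex per edge.
#' Original vertices are never moved (the scheme is interpolating). New edge
#' vertices are placed by the butterfly spline stencil (1/2, 1/2 on the edge
#' endpoints, 1/8 on the two opposite vertices, -1/16 on the four wing
#' vertices); boundary edges, and optionally all edges, fall back to the flat
#' midpoint. Counts obey V' = V + E and F' = 4F.
#'
#' @param mesh an [sd_mesh()]
#' @param iterations number of 4-split passes (>= 1)
#' @param scheme `"butterfly"` (default) or `"midpoint"`
#' @return the up-sampled `sd_mesh`
#' @export
upsample_4split <- function(mesh, iterations = 1L, scheme = c("butterfly", "midpoint")) {
  scheme <- match.arg(scheme)
  stopifnot(iterations >= 1L)
  validate_mesh(mesh)
  for (it in seq_len(iterations)) mesh <- upsample_once(mesh, scheme)
  mesh
}

upsample_once <- function(mesh, scheme) {
  v <- mesh$vertices; f <- mesh$faces
  nV <- nrow(v)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  # edge -> opposite vertices (one per adjacent face)
  keys <- c(ekey(f[, 1], f[, 2]), ekey(f[, 2], f[, 3]), ekey(f[, 3], f[, 1]))
  opps <- c(f[, 3], f[, 1], f[, 2])
  opp_by_edge <- split(opps, keys)
  edges <- do.call(rbind, lapply(strsplit(names(opp_by_edge), " "), as.integer))
  ne <- nrow(edges)
  mid_id <- setNames(nV + seq_len(ne), names(opp_by_edge))

  a <- edges[, 1]; b <- edges[, 2]
  newv <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
  if (scheme == "butterfly") {
    nopp <- lengths(opp_by_edge)
    opp1 <- vapply(opp_by_edge, `[`, integer(1), 1L)
    opp2 <- vapply(opp_by_edge, function(o) if (length(o) > 1L) o[2] else NA_integer_,
                   integer(1))
    # wings: opposite vertices of the faces across (a,c),(b,c),(a,d),(b,d);
    # a missing wing (boundary) is substituted by the stencil's inner vertex
    wing <- function(x, y, inner) {
      j <- match(ekey(x, y), names(opp_by_edge))
      w <- ifelse(opp1[j] != inner, opp1[j], opp2[j])
      ifelse(is.na(w), inner, w)
    }
    int <- which(nopp >= 2L)
    if (length(int)) {
      ai <- a[int]; bi <- b[int]
      cc <- opp1[int]; dd <- opp2[int]
      w1 <- wing(ai, cc, bi); w2 <- wing(bi, cc, ai)
      w3 <- wing(ai, dd, bi); w4 <- wing(bi, dd, ai)
      newv[int, ] <- newv[int, , drop = FALSE] +
        (v[cc, , drop = FALSE] + v[dd, , drop = FALSE]) / 8 -
        (v[w1, , drop = FALSE] + v[w2, , drop = FALSE] +
         v[w3, , drop = FALSE] + v[w4, , drop = FALSE]) / 16
    }
  }
  m12 <- mid_id[ekey(f[, 1], f[, 2])]
  m23 <- mid_id[ekey(f[, 2], f[, 3])]
  m31 <- mid_id[ekey(f[, 3], f[, 1])]
  nf <- rbind(cbind(f[, 1], m12, m31),
              cbind(m12, f[, 2], m23),
              cbind(m31, m23, f[, 3]),
              cbind(m12, m23, m31))
  sd_mesh(rbind(v, newv), nf, validate = FALSE)
}

#' Edge-length-preserving Laplacian smoothing
#'
#' Applies the umbrella Laplace operator to relax curvature while projecting
#' edge lengths back toward their original values after every step (so the
#' tessellation's metric, and with it geodesic distances, is retained within
#' a 1% tolerance). The restoration always targets the input lengths, so the
#' residual distortion does not accumulate over iterations. Boundary
#' vertices are kept fixed. Aborts if any edge length drifts more than 10%
#' from its input length. The defaults balance the two competing goals:
#' tighter restoration tolerances progressively cancel the curvature
#' relaxation (exact edge preservation would freeze the intrinsic metric
#' entirely).
#'
#' @param mesh an [sd_mesh()]
#' @param iterations smoothing passes
#' @param step Laplacian step size in (0, 1]
#' @param restore_tol target mean absolute relative edge-length error of the
#'   restoration projection after each pass
#' @param restore_rounds maximum restoration sweeps per pass
#' @param monitor when TRUE, attach the per-iteration mean-curvature variance
#'   (initial value first) as attribute `"curvature_variance"`
#' @return the smoothed `sd_mesh`
#' @export
smooth_laplacian_edge_preserving <- function(mesh, iterations = 10L, step = 0.05,
                                             restore_tol = 8e-3,
                                             restore_rounds = 500L,
                                             monitor = FALSE) {
  if (step <= 0) stop("step must be positive")
  if (step > 1) stop("step must be at most 1")
  validate_mesh(mesh)
  v <- mesh$vertices
  e <- mesh_edges(mesh)
  l0 <- mesh_edge_lengths(mesh, e)
  nb <- mesh_vertex_neighbors(mesh)
  free <- rep(TRUE, nrow(v))
  free[mesh_boundary_vertices(mesh)] <- FALSE
  deg <- lengths(nb)
  e1 <- e[, 1]; e2 <- e[, 2]
  idx_all <- c(e1, e2)
  out <- mesh
  cv <- if (monitor) stats::var(mesh_vertex_curvature(mesh), na.rm = TRUE)

  for (it in seq_len(iterations)) {
    # umbrella displacement toward the neighbour mean
    nbr_sum <- rowsum(rbind(v[e2, , drop = FALSE], v[e1, , drop = FALSE]),
                      idx_all, reorder = TRUE)
    mean_nbr <- nbr_sum / deg[sort(unique(idx_all))]
    disp <- mean_nbr - v
    v[free, ] <- v[free, ] + step * disp[free, , drop = FALSE]
    # Jacobi-style projection back onto the original edge lengths, iterated
    # until the residual metric distortion is below restore_tol
    for (r in seq_len(restore_rounds)) {
      d <- v[e2, , drop = FALSE] - v[e1, , drop = FALSE]
      l <- sqrt(rowSums(d^2))
      if (mean(abs(l - l0) / l0) < restore_tol) break
      corr <- 0.5 * (l - l0) / l
      delta <- d * corr
      acc <- rowsum(rbind(delta, -delta), idx_all, reorder = TRUE)
      adj <- acc / deg[sort(unique(idx_all))]
      v[free, ] <- v[free, ] + adj[free, , drop = FALSE]
    }
    l <- sqrt(rowSums((v[e2, , drop = FALSE] - v[e1, , drop = FALSE])^2))
    drift <- abs(l - l0) / l0
    if (any(drift > 0.10)) {
      stop(sprintf("smoothing diverged at iteration %d: edge length change %.1f%% (> 10%%)",
                   it, 100 * max(drift)))
    }
    if (monitor) {
      out$vertices <- v
      cv <- c(cv, stats::var(mesh_vertex_curvature(out), na.rm = TRUE))
    }
  }
  out$vertices <- v
  if (monitor) attr(out, "curvature_variance") <- cv
  out
}

#' Discrete mean curvature per vertex
#'
#' Magnitude of the cotangent-weighted mean-curvature normal,
#' H_i = |sum_j (cot a_ij + cot b_ij) (v_j - v_i)| / (4 A_i), with A_i the
#' barycentric vertex area (one third of the incident face areas). This is
#' an extrinsic quantity — unlike the angle deficit it is not fixed by the
#' edge lengths alone — so it is the right monitor for an edge-length
#' preserving smoother. Boundary vertices, where the stencil is truncated,
#' are returned as NA.
#'
#' @param mesh an [sd_mesh()]
#' @return numeric vector, one value per vertex (1/mm); NA on the boundary
#' @export
mesh_vertex_curvature <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nV <- nrow(v)
  lap <- matrix(0, nV, 3)
  area <- numeric(nV)
  # cotangent at vertex k of each face, applied to the opposite edge (i, j)
  cot_at <- function(i, j, k) {
    a <- v[i, , drop = FALSE] - v[k, , drop = FALSE]
    b <- v[j, , drop = FALSE] - v[k, , drop = FALSE]
    dot <- rowSums(a * b)
    crs <- sqrt(pmax(0, rowSums(a^2) * rowSums(b^2) - dot^2))
    dot / pmax(crs, .Machine$double.eps)
  }
  acc_edge <- function(i, j, w) {
    d <- (v[j, , drop = FALSE] - v[i, , drop = FALSE]) * w
    add <- rowsum(rbind(d, -d), c(i, j), reorder = TRUE)
    ids <- as.integer(rownames(add))
    lap[ids, ] <<- lap[ids, ] + add
  }
  acc_edge(f[, 1], f[, 2], cot_at(f[, 1], f[, 2], f[, 3]))
  acc_edge(f[, 2], f[, 3], cot_at(f[, 2], f[, 3], f[, 1]))
  acc_edge(f[, 3], f[, 1], cot_at(f[, 3], f[, 1], f[, 2]))
  fa <- mesh_face_areas(mesh)
  aa <- rowsum(rep(fa, 3) / 3, c(f[, 1], f[, 2], f[, 3]), reorder = TRUE)
  area[as.integer(rownames(aa))] <- aa[, 1]
  h <- sqrt(rowSums(lap^2)) / (4 * area)
  h[mesh_boundary_vertices(mesh)] <- NA_real_
  h
}

#' Extract the surface patch around an electrode strip
#'
#' The patch is the union of geodesic disks of the given radius around each
#' electrode vertex: all faces with at least one vertex within the radius are
#' kept, so every patch boundary vertex lies strictly beyond the radius from
#' every electrode. Errors if an electrode is within the radius of the parent
#' mesh's own boundary (the patch would be clipped).
#'
#' @param mesh parent `sd_mesh`
#' @param electrode_vertices 1-based vertex ids (optionally named by labels)
#' @param radius patch radius in mm (default 30)
#' @return an `sd_patch`: list(mesh, parent_vertex, electrode_vertices,
#'   boundary_vertices, radius)
#' @export
extract_patch <- function(mesh, electrode_vertices, radius = 30) {
  validate_mesh(mesh)
  ev <- as.integer(electrode_vertices)
  if (any(ev < 1L | ev > nrow(mesh$vertices))) stop("electrode vertex out of range")
  gm <- geodesic_multi(mesh, ev)
  dmin <- do.call(pmin, as.data.frame(gm$dist))
  pb <- mesh_boundary_vertices(mesh)
  if (length(pb) && any(dmin[pb] < radius)) {
    stop(sprintf("insufficient margin: electrode within %.1f mm of the parent mesh boundary (need >= %.1f mm)",
                 min(dmin[pb]), radius))
  }
  f <- mesh$faces
  keep_f <- dmin[f[, 1]] <= radius | dmin[f[, 2]] <= radius | dmin[f[, 3]] <= radius
  fk <- f[keep_f, , drop = FALSE]
  vids <- sort(unique(as.integer(fk)))
  remap <- integer(nrow(mesh$vertices))
  remap[vids] <- seq_along(vids)
  pmesh <- sd_mesh(mesh$vertices[vids, , drop = FALSE],
                   matrix(remap[fk], ncol = 3), validate = FALSE)
  pev <- remap[ev]
  names(pev) <- names(electrode_vertices)
  bnd <- mesh_boundary_vertices(pmesh)
  if (any(pev %in% bnd)) stop("electrode vertex on patch boundary")
  structure(list(mesh = pmesh, parent_vertex = vids,
                 electrode_vertices = pev, boundary_vertices = bnd,
                 radius = radius),
            class = "sd_patch")
}

#' @export
print.sd_patch <- function(x, ...) {
  cat(sprintf("<sd_patch> %d vertices, %d faces, %d electrodes, radius %.0f mm\n",
              nrow(x$mesh$vertices), nrow(x$mesh$faces),
              length(x$electrode_vertices), x$radius))
  invisible(x)
}

#' Patch preparation pipeline (extract, smooth, up-sample)
#'
#' Convenience wrapper running patch extraction, edge-length-preserving
#' smoothing and 4-split up-sampling in a configurable order. Electrode
#' vertex ids remain valid throughout because smoothing does not renumber
#' vertices and up-sampling preserves original vertex ids.
#'
#' @param mesh parent `sd_mesh`
#' @param electrode_vertices 1-based vertex ids on the parent mesh
#' @param radius patch radius (mm)
#' @param smooth_iterations Laplacian passes (0 to skip)
#' @param upsample_iterations 4-split passes (0 to skip)
#' @param smooth_first smooth before up-sampling (default TRUE)
#' @return an `sd_patch`
#' @export
prep_patch <- function(mesh, electrode_vertices, radius = 30,
                       smooth_iterations = 0L, upsample_iterations = 0L,
                       smooth_first = TRUE) {
  patch <- extract_patch(mesh, electrode_vertices, radius)
  do_smooth <- function(p) {
    p$mesh <- smooth_laplacian_edge_preserving(p$mesh, iterations = smooth_iterations)
    p
  }
  do_up <- function(p) {
    nold <- nrow(p$mesh$vertices)
    p$mesh <- upsample_4split(p$mesh, iterations = upsample_iterations)
    p$parent_vertex <- c(p$parent_vertex,
                         rep(NA_integer_, nrow(p$mesh$vertices) - nold))
    p$boundary_vertices <- mesh_boundary_vertices(p$mesh)
    p
  }
  if (smooth_first) {
    if (smooth_iterations > 0) patch <- do_smooth(patch)
    if (upsample_iterations > 0) patch <- do_up(patch)
  } else {
    if (upsample_iterations > 0) patch <- do_up(patch)
    if (smooth_iterations > 0) patch <- do_smooth(patch)
  }
  patch
}
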