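#' Generate a synthetic surface mesh
#'
#' Three mesh families emulating a reconstructed cortical patch: a flat
#' triangulated plane (with diagonal edges), an icosphere (subdivided
#' icosahedron projected to a sphere), and a "gyral" surface — the plane
#' displaced by a sinusoid along x, the simplest surface on which geodesic
#' and Euclidean distances diverge the way they do across folded cortex.
#'
#' @param kind `"plane"`, `"icosphere"` or `"gyral"`
#' @param width,height plane extent in mm
#' @param spacing grid spacing in mm
#' @param radius icosphere radius in mm
#' @param subdivisions icosphere subdivision level (vertices = 10*4^n + 2)
#' @param amplitude fold amplitude in mm (gyral)
#' @param wavelength fold wavelength in mm (gyral)
#' @return an [sd_mesh()]
#' @export
make_mesh <- function(kind = c("plane", "icosphere", "gyral"),
                      width = 120, height = 80, spacing = 1,
                      radius = 50, subdivisions = 3,
                      amplitude = 5, wavelength = 30) {
  kind <- match.arg(kind)
  if (kind == "icosphere") return(make_icosphere(radius, subdivisions))
  if (width <= 0 || height <= 0 || spacing <= 0) stop("degenerate dimensions")
  xs <- seq(0, width, by = spacing)
  ys <- seq(0, height, by = spacing)
  nx <- length(xs); ny <- length(ys)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  if (kind == "gyral" && amplitude != 0) {
    v[, 3] <- amplitude * sin(2 * pi * v[, 1] / wavelength)
  }
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- id(i, j); v10 <- id(i + 1L, j); v01 <- id(i, j + 1L); v11 <- id(i + 1L, j + 1L)
  # alternate the cell diagonal in a checkerboard so both diagonal
  # directions have straight edge paths (a single fixed diagonal would make
  # the graph metric anisotropic, with stretch sqrt(2) across the missing
  # diagonal)
  a <- (i + j) %% 2L == 0L
  f <- rbind(cbind(v00[a], v10[a], v11[a]), cbind(v00[a], v11[a], v01[a]),
             cbind(v00[!a], v10[!a], v01[!a]), cbind(v10[!a], v11[!a], v01[!a]))
  sd_mesh(v, f, validate = FALSE)
}

make_icosphere <- function(radius = 50, subdivisions = 3) {
  if (radius <= 0) stop("degenerate dimensions")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  project <- function(vv) vv * radius / sqrt(rowSums(vv^2))
  v <- project(v)
  mesh <- sd_mesh(v, f, validate = FALSE)
  for (s in seq_len(subdivisions)) {
    mesh <- upsample_once(mesh, scheme = "midpoint")
    mesh$vertices <- project(mesh$vertices)
  }
  mesh
}

#' Place a collinear electrode strip on a mesh
#'
#' Walks along the surface from an origin vertex in a given world direction,
#' placing `n` electrodes at successive geodesic arc lengths of ~`spacing`
#' (the subdural strip geometry: six electrodes, 10 mm center spacing). Each
#' next electrode is the vertex whose geodesic distance from the previous one
#' is within 5% of the spacing and whose direction best continues the walk.
#'
#' @param mesh an [sd_mesh()]
#' @param origin 1-based vertex id of the first electrode
#' @param direction 3-vector, world direction of the strip
#' @param n number of electrodes (default 6)
#' @param spacing nominal center spacing in mm (default 10)
#' @return an `sd_electrodes`
#' @export
place_strip <- function(mesh, origin, direction, n = 6L, spacing = 10) {
  direction <- direction / sqrt(sum(direction^2))
  verts <- integer(n)
  verts[1] <- if (length(origin) == 3L) nearest_vertex(mesh, origin)
              else as.integer(origin)
  dir_cur <- direction
  for (k in seq_len(n - 1L)) {
    gm <- geodesic_from(mesh, verts[k])
    cand <- which(gm$dist >= 0.95 * spacing & gm$dist <= 1.05 * spacing)
    cand <- setdiff(cand, verts[seq_len(k)])
    if (!length(cand)) stop("insufficient room: strip runs off the mesh")
    delta <- mesh$vertices[cand, , drop = FALSE] -
      matrix(mesh$vertices[verts[k], ], length(cand), 3, byrow = TRUE)
    delta <- delta / sqrt(rowSums(delta^2))
    score <- delta %*% dir_cur
    if (max(score) < 0.5) stop("insufficient room: strip runs off the mesh")
    best <- cand[which.max(score)]
    dir_cur <- mesh$vertices[best, ] - mesh$vertices[verts[k], ]
    dir_cur <- dir_cur / sqrt(sum(dir_cur^2))
    verts[k + 1L] <- best
  }
  labels <- paste0("E", seq_len(n))
  structure(list(labels = labels, centroids = mesh$vertices[verts, , drop = FALSE],
                 vertex = setNames(verts, labels),
                 snap_distance = setNames(rep(0, n), labels), spacing = spacing),
            class = "sd_electrodes")
}

#' Specification of a simulated SD wave
#'
#' The forward model of the trajectory-search assumptions: the wave front is
#' a circular arc of (fairly) constant radius whose center moves at constant
#' velocity along the surface — either along an explicit center path
#' (`moving_center`) or expanding concentrically from a source vertex
#' (`concentric`).
#'
#' @param mode `"moving_center"` or `"concentric"`
#' @param path vertex ids of the center path (moving_center)
#' @param source source vertex id (concentric)
#' @param velocity center (or front) velocity in mm/min, > 0
#' @param radius front curvature radius in mm (moving_center)
#' @param start start time in min
#' @return a `wave_spec`
#' @export
wave_spec <- function(mode = c("moving_center", "concentric"), path = NULL,
                      source = NULL, velocity = 3.6, radius = 2, start = 0) {
  mode <- match.arg(mode)
  stopifnot(velocity > 0, radius >= 0)
  if (mode == "moving_center" && is.null(path)) stop("moving_center needs a path")
  if (mode == "concentric" && is.null(source)) stop("concentric needs a source")
  structure(list(mode = mode, path = path, source = source, velocity = velocity,
                 radius = radius, start = start),
            class = "wave_spec")
}

#' Build a wave center path along an electrode strip
#'
#' Chains the canonical geodesic paths through the strip's electrode
#' vertices, optionally extending the path before the first and after the
#' last electrode so the front crosses every electrode mid-run.
#'
#' @param mesh an [sd_mesh()]
#' @param electrodes an `sd_electrodes` on this mesh
#' @param extend_before,extend_after extension lengths in mm
#' @param lateral_offset displace the whole path laterally by this many mm
#'   (perpendicular to the strip, within the surface's xy plane); the path is
#'   re-snapped to nearest vertices
#' @return integer vector of vertex ids
#' @export
strip_wave_path <- function(mesh, electrodes, extend_before = 10, extend_after = 5,
                            lateral_offset = 0) {
  ev <- as.integer(electrodes$vertex)
  pos <- mesh$vertices
  dir <- pos[ev[length(ev)], ] - pos[ev[1], ]
  dir <- dir / sqrt(sum(dir^2))
  ends <- ev
  if (extend_before > 0) {
    start <- nearest_vertex(mesh, pos[ev[1], ] - extend_before * dir)
    ends <- c(start, ends)
  }
  if (extend_after > 0) {
    stop_v <- nearest_vertex(mesh, pos[ev[length(ev)], ] + extend_after * dir)
    ends <- c(ends, stop_v)
  }
  if (lateral_offset != 0) {
    lat <- c(-dir[2], dir[1], 0)
    lat <- lat / sqrt(sum(lat^2))
    ends <- vapply(ends, function(v)
      nearest_vertex(mesh, pos[v, ] + lateral_offset * lat), integer(1))
  }
  path <- ends[1]
  for (k in seq_len(length(ends) - 1L)) {
    gm <- geodesic_from(mesh, ends[k])
    seg <- shortest_path(gm, ends[k + 1L])
    path <- c(path, seg[-1])
  }
  path
}

#' Nearest mesh vertex to a point
#'
#' @param mesh an [sd_mesh()]
#' @param point length-3 world coordinate (mm)
#' @return the index of the Euclidean-nearest vertex
#' @export
nearest_vertex <- function(mesh, point) {
  d2 <- rowSums(sweep(mesh$vertices, 2, point)^2)
  which.min(d2)
}

#' Simulate SD arrival times at a strip
#'
#' Forward-simulates a wave given by a [wave_spec()] and records the onset
#' time at each electrode: for a moving center, the first time the geodesic
#' distance between the center and the electrode drops to the front radius
#' (linearly interpolated along the center path); for a concentric wave,
#' source-to-electrode geodesic distance over velocity. Electrodes never
#' reached are recorded absent.
#'
#' @param mesh an [sd_mesh()]
#' @param spec a [wave_spec()]
#' @param electrodes an `sd_electrodes`
#' @param event_id id for the generated event
#' @param onset_jitter_sd Gaussian jitter (min) added to onsets (default 0:
#'   exact, noiseless observation)
#' @param seed seed for the jitter
#' @param day recording day index
#' @return list(event = `sd_event`, truth = ground-truth description)
#' @export
simulate_wave <- function(mesh, spec, electrodes, event_id = "sim1",
                          onset_jitter_sd = 0, seed = 1L, day = 1L) {
  labs <- electrodes$labels
  onsets <- setNames(rep(NA_real_, length(labs)), labs)
  if (spec$mode == "concentric") {
    gm <- geodesic_from(mesh, spec$source)
    d <- gm$dist[electrodes$vertex]
    onsets[] <- ifelse(is.finite(d), spec$start + d / spec$velocity, NA_real_)
  } else {
    pv <- spec$path
    xyz <- mesh$vertices[pv, , drop = FALSE]
    s <- c(0, cumsum(sqrt(rowSums((xyz[-1, , drop = FALSE] -
                                   xyz[-nrow(xyz), , drop = FALSE])^2))))
    tt <- spec$start + s / spec$velocity
    for (ei in seq_along(labs)) {
      dE <- geodesic_from(mesh, electrodes$vertex[ei])$dist[pv]
      g <- dE - spec$radius
      hit <- which(g <= 0)
      if (!length(hit)) next
      m <- hit[1]
      onsets[ei] <- if (m == 1L) tt[1] else {
        tt[m - 1L] + (tt[m] - tt[m - 1L]) * g[m - 1L] / (g[m - 1L] - g[m])
      }
    }
  }
  if (onset_jitter_sd > 0) {
    set.seed(seed)
    onsets <- onsets + stats::rnorm(length(onsets), 0, onset_jitter_sd)
  }
  keep <- !is.na(onsets)
  event <- sd_event(event_id, onsets[keep], day = day)
  list(event = event,
       truth = list(spec = spec, velocity = spec$velocity, radius = spec$radius,
                    onsets = onsets))
}

#' Generate a CT-like volume with metal-bright electrode spheres
#'
#' A 3-D volume whose background intensities lie in the brain-tissue
#' Hounsfield range and whose electrodes are spheres far above the metal
#' threshold, centered on the electrode centroids. Same seed, bit-identical
#' volume.
#'
#' @param electrodes an `sd_electrodes`
#' @param voxel isotropic voxel size in mm
#' @param sphere_radius electrode sphere radius in mm
#' @param metal_hu electrode intensity (default 3500 HU)
#' @param background HU range of the tissue background (default 20-120)
#' @param margin padding around the strip in mm
#' @param seed RNG seed for the background
#' @return an `sd_volume`
#' @export
make_ct_volume <- function(electrodes, voxel = 0.5, sphere_radius = 2,
                           metal_hu = 3500, background = c(20, 120),
                           margin = 10, seed = 1L) {
  if (voxel <= 0) stop("voxel size must be positive")
  cen <- electrodes$centroids
  if (nrow(cen) > 1L) {
    dmin <- min(stats::dist(cen))
    if (dmin < 2 * sphere_radius)
      warning(sprintf("electrode spheres overlap: spacing %.1f mm < %.1f mm", dmin,
                      2 * sphere_radius))
  }
  lo <- apply(cen, 2, min) - margin
  hi <- apply(cen, 2, max) + margin
  dm <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  affine <- diag(c(voxel, voxel, voxel, 1))
  affine[1:3, 4] <- lo
  set.seed(seed)
  data <- array(sample(background[1]:background[2], prod(dm), replace = TRUE), dim = dm)
  # world coordinates of voxel centers, axis-aligned affine
  gx <- lo[1] + voxel * (seq_len(dm[1]) - 1L)
  gy <- lo[2] + voxel * (seq_len(dm[2]) - 1L)
  gz <- lo[3] + voxel * (seq_len(dm[3]) - 1L)
  for (i in seq_len(nrow(cen))) {
    ix <- which(abs(gx - cen[i, 1]) <= sphere_radius)
    iy <- which(abs(gy - cen[i, 2]) <= sphere_radius)
    iz <- which(abs(gz - cen[i, 3]) <= sphere_radius)
    for (z in iz) for (y in iy) {
      d2 <- (gx[ix] - cen[i, 1])^2 + (gy[y] - cen[i, 2])^2 + (gz[z] - cen[i, 3])^2
      data[ix[d2 <= sphere_radius^2], y, z] <- metal_hu
    }
  }
  sd_volume(data, affine)
}

#' Generate a complete synthetic SD dataset
#'
#' Builds a mesh, places a six-electrode strip with 10 mm spacing, and
#' simulates a cohort of SD events with known ground truth: plain
#' longitudinal waves (moving center along the strip), branching events
#' (concentric waves from a source displaced ~1 mm from an interior
#' electrode, so the wave spreads in both strip directions), and optionally
#' "complex" events with non-longitudinal hit orders that defeat branch
#' reduction.
#'
#' @param seed master seed
#' @param n_events number of events
#' @param mesh_kind `"plane"` or `"gyral"`
#' @param spacing mesh grid spacing (mm)
#' @param velocity_range wave velocities drawn uniformly from this range (mm/min)
#' @param wave_radius front curvature radius (mm)
#' @param p_branching,p_complex proportions of branching / complex events
#' @param width,height mesh extent (mm)
#' @param amplitude,wavelength gyral fold parameters
#' @return list(mesh, electrodes, events, truth)
#' @export
make_synthetic_dataset <- function(seed = 1L, n_events = 12L,
                                   mesh_kind = c("plane", "gyral"),
                                   spacing = 1, velocity_range = c(2, 9),
                                   wave_radius = 2,
                                   p_branching = 0.25, p_complex = 0,
                                   width = 120, height = 80,
                                   amplitude = 5, wavelength = 30) {
  mesh_kind <- match.arg(mesh_kind)
  mesh <- make_mesh(mesh_kind, width = width, height = height, spacing = spacing,
                    amplitude = amplitude, wavelength = wavelength)
  origin <- nearest_vertex(mesh, c((width - 50) / 2, height / 2, 0))
  electrodes <- place_strip(mesh, origin, c(1, 0, 0), n = 6L, spacing = 10)
  set.seed(seed)
  vels <- stats::runif(n_events, velocity_range[1], velocity_range[2])
  kinds <- sample(c("longitudinal", "branching", "complex"), n_events, replace = TRUE,
                  prob = c(1 - p_branching - p_complex, p_branching, p_complex))
  path <- strip_wave_path(mesh, electrodes, extend_before = 10, extend_after = 5)
  events <- vector("list", n_events)
  truth <- vector("list", n_events)
  pos <- mesh$vertices
  for (i in seq_len(n_events)) {
    id <- sprintf("SD%02d", i)
    day <- 1L + (i - 1L) %/% 4L
    if (kinds[i] == "longitudinal") {
      sim <- simulate_wave(mesh, wave_spec("moving_center", path = path,
                                           velocity = vels[i], radius = wave_radius),
                           electrodes, event_id = id, day = day)
    } else if (kinds[i] == "branching") {
      # concentric source displaced 1 mm from an interior electrode toward E1
      ei <- sample(2:3, 1)
      src <- nearest_vertex(mesh, pos[electrodes$vertex[ei], ] + c(-1, 0, 0))
      sim <- simulate_wave(mesh, wave_spec("concentric", source = src,
                                           velocity = vels[i]),
                           electrodes, event_id = id, day = day)
    } else {
      # non-longitudinal order: swap two onsets of a branching-type event
      ei <- 3L
      src <- nearest_vertex(mesh, pos[electrodes$vertex[ei], ] + c(-1, 0, 0))
      sim <- simulate_wave(mesh, wave_spec("concentric", source = src,
                                           velocity = vels[i]),
                           electrodes, event_id = id, day = day)
      on <- sim$event$onsets
      o <- order(on)
      if (length(on) >= 4L) {
        # swap the 2nd and 4th hits: the down-run is no longer monotone
        tmp <- on[o[2]]; on[o[2]] <- on[o[4]]; on[o[4]] <- tmp
        sim$event <- sd_event(id, on, day = day)
      }
    }
    events[[i]] <- sim$event
    truth[[i]] <- c(sim$truth, list(kind = kinds[i]))
  }
  list(mesh = mesh, electrodes = electrodes, events = events, truth = truth,
       seed = seed)
}

#' Write a synthetic event cohort as CSV
#' @param events list of `sd_event`
#' @param path output CSV path
#' @export
write_events_csv <- function(events, path) {
  rows <- lapply(events, function(e) {
    data.frame(event_id = e$id, electrode = names(e$onsets),
               onset_min = as.numeric(e$onsets),
               day = e$day)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
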