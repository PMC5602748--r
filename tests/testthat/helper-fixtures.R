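# Shared fixtures and independent oracles for the test suite. Heavyweight
# fixtures are memoized per session so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a 120 x 80 mm plane at 1 mm spacing with a 6-electrode strip and its
# 30 mm patch — the standard full-size scenario
fix_plane_strip <- function() memo("plane_strip", function() {
  mesh <- make_mesh("plane", width = 120, height = 80, spacing = 1)
  el <- place_strip(mesh, origin = c(35, 40, 0), direction = c(1, 0, 0),
                    n = 6L, spacing = 10)
  patch <- prep_patch(mesh, el$vertex, radius = 30)
  list(mesh = mesh, el = el, patch = patch)
})

# a small 3-electrode scenario with an enumerable solution set
fix_small_patch <- function() memo("small_patch", function() {
  mesh <- make_mesh("plane", width = 60, height = 40, spacing = 2)
  el <- place_strip(mesh, origin = c(14, 20, 0), direction = c(1, 0, 0),
                    n = 3L, spacing = 10)
  patch <- prep_patch(mesh, el$vertex, radius = 12)
  sim <- simulate_wave(mesh, wave_spec("moving_center",
                                       path = strip_wave_path(mesh, el),
                                       velocity = 4, radius = 2), el)
  sq <- build_hit_sequence(sim$event)
  list(mesh = mesh, el = el, patch = patch, sq = sq)
})

# on-path moving-center wave on the full-size plane scenario
fix_plane_wave <- function(velocity = 5, radius = 2) {
  fx <- fix_plane_strip()
  key <- sprintf("plane_wave_%g_%g", velocity, radius)
  memo(key, function() {
    sim <- simulate_wave(fx$mesh,
                         wave_spec("moving_center",
                                   path = strip_wave_path(fx$mesh, fx$el),
                                   velocity = velocity, radius = radius),
                         fx$el)
    build_hit_sequence(sim$event)
  })
}

# independent exhaustive oracle: per-subrange trajectory counts of a
# 3-electrode search by a triple loop over the candidate disks
brute_force_counts <- function(patch, sq, p) {
  stopifnot(length(sq$electrodes) == 3L)
  pm <- patch$mesh
  ev <- patch$electrode_vertices[sq$electrodes]
  gmE <- lapply(ev, function(v) geodesic_from(pm, v)$dist)
  disks <- lapply(gmE, function(d) which(d <= p$r_max))
  gA <- lapply(disks[[1]], function(a) geodesic_from(pm, a)$dist)
  gB <- lapply(disks[[2]], function(b) geodesic_from(pm, b)$dist)
  vapply(p$centers, function(c0) {
    lo <- max(p$v_min, c0 - p$v_diff)
    hi <- min(p$v_max, c0 + p$v_diff)
    cnt <- 0
    for (ia in seq_along(disks[[1]])) {
      a <- disks[[1]][ia]
      for (ib in seq_along(disks[[2]])) {
        b <- disks[[2]][ib]
        v1 <- gA[[ia]][b] / sq$toads[1]
        if (v1 < lo || v1 > hi) next
        if (abs(gmE[[1]][a] - gmE[[2]][b]) > p$r_diff) next
        for (cc in disks[[3]]) {
          v2 <- gB[[ib]][cc] / sq$toads[2]
          if (v2 < lo || v2 > hi) next
          if (abs(gmE[[2]][b] - gmE[[3]][cc]) > p$r_diff) next
          cnt <- cnt + 1
        }
      }
    }
    cnt
  }, numeric(1))
}

# independent shortest-path oracle built on igraph
igraph_distance <- function(mesh, from, to) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::distances(g, v = from, to = to,
                    weights = mesh_edge_lengths(mesh, e))
}

# great-circle distance between two vertices of a sphere centered at the
# origin
great_circle <- function(mesh, a, b, radius) {
  va <- mesh$vertices[a, ]; vb <- mesh$vertices[b, ]
  va <- va / sqrt(sum(va^2)); vb <- vb / sqrt(sum(vb^2))
  radius * acos(min(1, max(-1, sum(va * vb))))
}

# noisy icosphere used by the smoothing contracts
fix_noisy_icosphere <- function(seed = 42, sigma = 0.5) memo(
  sprintf("noisy_ico_%d_%g", seed, sigma), function() {
    ic <- make_mesh("icosphere", radius = 50, subdivisions = 3)
    set.seed(seed)
    r <- sqrt(rowSums(ic$vertices^2))
    ic$vertices <- ic$vertices * (r + rnorm(nrow(ic$vertices), 0, sigma)) / r
    ic
  })
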