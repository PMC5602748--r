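test_that("generated meshes have the advertised geometry", {
  p <- make_mesh("plane", width = 20, height = 10, spacing = 2)
  expect_equal(range(p$vertices[, 1]), c(0, 20))
  expect_equal(range(p$vertices[, 2]), c(0, 10))
  expect_identical(max(abs(p$vertices[, 3])), 0)

  ic <- make_mesh("icosphere", radius = 50, subdivisions = 3)
  expect_identical(nrow(ic$vertices), 642L)
  expect_equal(sqrt(rowSums(ic$vertices^2)), rep(50, nrow(ic$vertices)),
               tolerance = 1e-9)

  g <- make_mesh("gyral", width = 30, height = 20, spacing = 2,
                 amplitude = 5, wavelength = 30)
  expect_gt(diff(range(g$vertices[, 3])), 5)  # folds actually present
  expect_silent(validate_mesh(g))
})

test_that("strips are placed with near-uniform geodesic spacing", {
  m <- make_mesh("plane", width = 120, height = 80, spacing = 1)
  el <- place_strip(m, origin = c(30, 40, 0), direction = c(1, 0, 0),
                    n = 6, spacing = 10)
  expect_length(el$vertex, 6)
  for (k in 1:5) {
    d <- geodesic_from(m, el$vertex[k])$dist[el$vertex[k + 1]]
    expect_lt(abs(d - 10), 0.5 + 1e-9)
  }
})

test_that("a strip that would run off the mesh is refused", {
  m <- make_mesh("plane", width = 30, height = 20, spacing = 1)
  expect_error(place_strip(m, origin = c(25, 10, 0), direction = c(1, 0, 0),
                           n = 6, spacing = 10), "insufficient room")
})

test_that("concentric wave onsets equal geodesic distance over velocity", {
  fx <- fix_small_patch()
  src <- fx$el$vertex[[2]]
  sim <- simulate_wave(fx$mesh, wave_spec("concentric", source = src,
                                          velocity = 4, start = 1), fx$el)
  d <- geodesic_from(fx$mesh, src)$dist[fx$el$vertex]
  expect_equal(unname(sim$truth$onsets), unname(1 + d / 4), tolerance = 1e-9)
})

test_that("moving-center waves hit electrodes in strip order with TOADs
           spacing/velocity", {
  fx <- fix_plane_strip()
  sim <- simulate_wave(fx$mesh,
                       wave_spec("moving_center",
                                 path = strip_wave_path(fx$mesh, fx$el),
                                 velocity = 5, radius = 2), fx$el)
  sq <- build_hit_sequence(sim$event)
  expect_identical(sq$electrodes, paste0("E", 1:6))
  expect_equal(sq$toads, rep(10 / 5, 5), tolerance = 0.05)
})

test_that("electrodes beyond the wave's travel are recorded absent", {
  fx <- fix_plane_strip()
  # path stops after the third electrode
  short_path <- strip_wave_path(fx$mesh, fx$el, extend_after = 0)
  p3 <- short_path[seq_len(which(short_path == fx$el$vertex[[3]]))]
  sim <- simulate_wave(fx$mesh, wave_spec("moving_center", path = p3,
                                          velocity = 5, radius = 2), fx$el)
  expect_true(all(c("E1", "E2", "E3") %in% names(sim$event$onsets)))
  expect_false(any(c("E5", "E6") %in% names(sim$event$onsets)))
})

test_that("identical seeds give bit-identical synthetic volumes", {
  fx <- fix_small_patch()
  v1 <- make_ct_volume(fx$el, voxel = 1, sphere_radius = 2, seed = 3)
  v2 <- make_ct_volume(fx$el, voxel = 1, sphere_radius = 2, seed = 3)
  expect_identical(v1$data, v2$data)
  expect_identical(v1$affine, v2$affine)
})

test_that("volume background stays in the tissue range and spheres at metal", {
  fx <- fix_small_patch()
  v <- make_ct_volume(fx$el, voxel = 1, sphere_radius = 2, seed = 3)
  hu <- as.vector(v$data)
  expect_identical(sort(unique(hu > 3000)), c(FALSE, TRUE))
  expect_true(all(hu[hu <= 3000] >= 20 & hu[hu <= 3000] <= 120))
  expect_true(all(hu[hu > 3000] == 3500))
})

test_that("overlapping electrode spheres trigger a warning", {
  m <- make_mesh("plane", width = 20, height = 20, spacing = 1)
  el <- snap_to_mesh(rbind(c(8, 10, 0), c(11, 10, 0)), m)
  expect_warning(make_ct_volume(el, voxel = 1, sphere_radius = 2, seed = 1),
                 "overlap")
})

test_that("synthetic datasets are reproducible and mix event types", {
  d1 <- make_synthetic_dataset(seed = 5, n_events = 8, p_branching = 0.5)
  d2 <- make_synthetic_dataset(seed = 5, n_events = 8, p_branching = 0.5)
  expect_identical(lapply(d1$events, `[[`, "onsets"),
                   lapply(d2$events, `[[`, "onsets"))
  expect_length(d1$events, 8)
  kinds <- vapply(d1$truth, `[[`, character(1), "kind")
  expect_setequal(unique(kinds), c("longitudinal", "branching"))
})
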