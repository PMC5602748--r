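test_that("4-split up-sampling obeys V' = V + E and F' = 4F", {
  tet <- sd_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 1)),
                 rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  u <- upsample_4split(tet)
  expect_identical(nrow(u$vertices), 4L + 6L)
  expect_identical(nrow(u$faces), 16L)
  u2 <- upsample_4split(tet, iterations = 2)
  expect_identical(nrow(u2$vertices), 10L + nrow(mesh_edges(u)))
  expect_identical(nrow(u2$faces), 64L)
})

test_that("up-sampling is interpolating: original vertices never move", {
  m <- make_mesh("gyral", width = 20, height = 16, spacing = 2)
  u <- upsample_4split(m)
  expect_identical(u$vertices[seq_len(nrow(m$vertices)), ], m$vertices)
})

test_that("the butterfly stencil keeps a planar mesh exactly planar", {
  m <- make_mesh("plane", width = 12, height = 8, spacing = 2)
  u <- upsample_4split(m, iterations = 2)
  expect_identical(max(abs(u$vertices[, 3])), 0)
})

test_that("butterfly midpoints bend toward a curved interpolated surface", {
  ic <- make_mesh("icosphere", radius = 50, subdivisions = 2)
  u <- upsample_4split(ic)
  new_r <- sqrt(rowSums(u$vertices[-seq_len(nrow(ic$vertices)), ]^2))
  mid_r <- mean(new_r)
  # flat midpoints would sit strictly inside the sphere; butterfly points
  # must sit further out, close to radius 50
  chord_mid <- 50 * cos(mean(mesh_edge_lengths(ic)) / 100)
  expect_gt(mid_r, chord_mid)
  expect_equal(mid_r, 50, tolerance = 0.01)
})

test_that("up-sampled meshes remain valid oriented manifolds", {
  m <- make_mesh("gyral", width = 20, height = 16, spacing = 2)
  expect_silent(validate_mesh(upsample_4split(m)))
})

test_that("smoothing strictly reduces curvature variance on a noisy sphere
           while preserving edge lengths within 1% and area within 2%", {
  noisy <- fix_noisy_icosphere()
  l0 <- mesh_edge_lengths(noisy)
  a0 <- sum(mesh_face_areas(noisy))
  sm <- smooth_laplacian_edge_preserving(noisy, iterations = 10, monitor = TRUE)
  cv <- attr(sm, "curvature_variance")
  expect_lt(cv[length(cv)], cv[1])              # strict overall decrease
  expect_true(all(diff(cv) <= 0))               # non-increasing per iteration
  l1 <- mesh_edge_lengths(sm)
  expect_lt(mean(abs(l1 - l0) / l0), 0.01)      # metric preserved
  expect_lt(abs(sum(mesh_face_areas(sm)) / a0 - 1), 0.02)
})

test_that("smoothing keeps boundary vertices fixed", {
  g <- make_mesh("gyral", width = 30, height = 20, spacing = 2)
  sm <- smooth_laplacian_edge_preserving(g, iterations = 5)
  b <- mesh_boundary_vertices(g)
  expect_identical(sm$vertices[b, ], g$vertices[b, ])
})

test_that("an already-flat grid is a fixed point of smoothing", {
  m <- make_mesh("plane", width = 10, height = 10, spacing = 1)
  sm <- smooth_laplacian_edge_preserving(m, iterations = 3)
  expect_equal(sm$vertices, m$vertices, tolerance = 1e-9)
})

test_that("invalid smoothing steps are rejected", {
  m <- make_mesh("plane", width = 4, height = 4, spacing = 2)
  expect_error(smooth_laplacian_edge_preserving(m, step = 0), "positive")
  expect_error(smooth_laplacian_edge_preserving(m, step = 1.5), "at most 1")
})

test_that("discrete mean curvature of a sphere equals 1/radius", {
  ic <- make_mesh("icosphere", radius = 50, subdivisions = 3)
  h <- mesh_vertex_curvature(ic)
  expect_equal(mean(h), 1 / 50, tolerance = 0.01)
  ic2 <- make_mesh("icosphere", radius = 25, subdivisions = 3)
  expect_equal(mean(mesh_vertex_curvature(ic2)), 1 / 25, tolerance = 0.01)
})

test_that("discrete mean curvature of a plane is zero", {
  m <- make_mesh("plane", width = 10, height = 10, spacing = 1)
  h <- mesh_vertex_curvature(m)
  expect_equal(max(abs(h), na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("patch boundary vertices lie strictly beyond the patch radius", {
  fx <- fix_plane_strip()
  dmin <- do.call(pmin, lapply(fx$patch$electrode_vertices, function(v)
    geodesic_from(fx$patch$mesh, v)$dist))
  expect_true(all(dmin[fx$patch$boundary_vertices] > fx$patch$radius))
})

test_that("a single-electrode 30 mm patch covers close to a pi r^2 disk", {
  m <- make_mesh("plane", width = 120, height = 80, spacing = 1)
  center <- which(m$vertices[, 1] == 60 & m$vertices[, 2] == 40)
  p <- extract_patch(m, center, radius = 30)
  a <- sum(mesh_face_areas(p$mesh))
  expect_lt(abs(a / (pi * 30^2) - 1), 0.15)
})

test_that("patch extraction refuses electrodes too close to the mesh rim", {
  m <- make_mesh("plane", width = 40, height = 40, spacing = 2)
  corner <- which(m$vertices[, 1] == 2 & m$vertices[, 2] == 2)
  expect_error(extract_patch(m, corner, radius = 30), "insufficient margin")
})

test_that("electrode vertex ids stay valid through patch preparation", {
  fx <- fix_small_patch()
  p <- prep_patch(fx$mesh, fx$el$vertex, radius = 12,
                  smooth_iterations = 2L, upsample_iterations = 1L)
  # electrode labels survive and point at vertices of the processed mesh
  expect_named(p$electrode_vertices, fx$el$labels)
  expect_true(all(p$electrode_vertices <= nrow(p$mesh$vertices)))
  # up-sampling is interpolating, so electrode coordinates are those of the
  # smoothed patch
  sm_only <- prep_patch(fx$mesh, fx$el$vertex, radius = 12,
                        smooth_iterations = 2L)
  expect_equal(p$mesh$vertices[p$electrode_vertices, ],
               sm_only$mesh$vertices[sm_only$electrode_vertices, ])
})
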