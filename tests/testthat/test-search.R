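test_that("candidate disks contain exactly the vertices within r_max and
           store their curvature radii", {
  fx <- fix_small_patch()
  d <- candidate_disk(fx$patch, "E2", r_max = 5)
  dist_all <- geodesic_from(fx$patch$mesh, fx$patch$electrode_vertices[["E2"]])$dist
  expect_setequal(d$members, which(dist_all <= 5))
  expect_equal(d$radii, dist_all[d$members])
  expect_true(all(diff(d$radii) >= 0))
})

test_that("bipartite distances agree with single-source geodesics", {
  fx <- fix_small_patch()
  da <- candidate_disk(fx$patch, "E1", 3)
  db <- candidate_disk(fx$patch, "E2", 3)
  bip <- bipartite_distances(fx$patch, da, db)
  expect_identical(dim(bip$dist), c(length(da$members), length(db$members)))
  for (ia in c(1L, length(da$members))) {
    ref <- geodesic_from(fx$patch$mesh, da$members[ia])$dist[db$members]
    expect_equal(bip$dist[ia, ], ref, tolerance = 1e-12)
  }
})

test_that("solution counts match an exhaustive enumeration oracle", {
  fx <- fix_small_patch()
  p <- search_params(r_diff = 1, v_diff = 1, patch_radius = 12)
  dp <- grow_solutions(fx$patch, fx$sq, p)
  oracle <- brute_force_counts(fx$patch, fx$sq, p)
  ours <- vapply(seq_along(p$centers), function(ci)
    as.double(count_solutions(dp, subrange = ci)), numeric(1))
  expect_identical(ours, oracle)
  expect_identical(as.double(count_solutions(dp)), sum(oracle))
})

test_that("enumerated tuples all satisfy the admissibility constraints", {
  fx <- fix_small_patch()
  p <- search_params(r_diff = 0.5, v_diff = 0.5, patch_radius = 12)
  dp <- grow_solutions(fx$patch, fx$sq, p)
  tup <- enumerate_solutions(dp)
  expect_identical(nrow(tup), as.integer(as.double(count_solutions(dp))))
  gm <- lapply(fx$sq$electrodes, function(lb)
    geodesic_from(fx$patch$mesh, fx$patch$electrode_vertices[[lb]])$dist)
  for (r in seq_len(min(nrow(tup), 50))) {
    sr <- dp$subranges[[tup[r, "subrange"]]]
    verts <- tup[r, seq_along(fx$sq$electrodes)]
    radii <- vapply(seq_along(verts), function(k) gm[[k]][verts[k]], numeric(1))
    expect_true(all(radii <= p$r_max))
    expect_true(all(abs(diff(radii)) <= p$r_diff))
    for (k in seq_along(fx$sq$toads)) {
      v <- geodesic_from(fx$patch$mesh, verts[k])$dist[verts[k + 1]] / fx$sq$toads[k]
      expect_gte(v, sr$lo); expect_lte(v, sr$hi)
    }
  }
})

test_that("deduplicated counts never exceed raw per-subrange sums", {
  fx <- fix_small_patch()
  p <- search_params(r_diff = 1, v_diff = 1, patch_radius = 12)
  dp <- grow_solutions(fx$patch, fx$sq, p)
  raw <- as.double(count_solutions(dp))
  dedup <- as.double(count_solutions(dp, dedup = TRUE))
  expect_lte(dedup, raw)
  expect_gt(dedup, 0)
})

test_that("exact counting survives totals beyond double precision", {
  # the big-integer layer: (10^9)^3 exceeds 2^53 and must print exactly
  x <- sdtraj:::big_from_num(1e9)
  cube <- sdtraj:::big_mul(sdtraj:::big_mul(x, x), x)
  expect_identical(sdtraj:::big_to_string(cube), "1000000000000000000000000000")
  s <- sdtraj:::big_add(cube, sdtraj:::big_from_num(1))
  expect_identical(sdtraj:::big_to_string(s), "1000000000000000000000000001")
})

test_that("sampled trajectories are admissible and reproducible under a seed", {
  fx <- fix_small_patch()
  p <- search_params(r_diff = 1, v_diff = 1, patch_radius = 12)
  dp <- grow_solutions(fx$patch, fx$sq, p)
  s1 <- sample_trajectories(dp, 50, seed = 9)
  s2 <- sample_trajectories(dp, 50, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, verify_trajectory, logical(1), dp = dp)))
  s3 <- sample_trajectories(dp, 50, seed = 10)
  expect_false(identical(s1, s3))
})

test_that("keypoint heatmap counts equal direct enumeration tallies", {
  fx <- fix_small_patch()
  p <- search_params(r_diff = 0.5, v_diff = 0.5, patch_radius = 12)
  dp <- grow_solutions(fx$patch, fx$sq, p)
  hm <- heatmap_solutions(dp, fx$patch, mode = "keypoints")
  tup <- enumerate_solutions(dp)
  expect_equal(hm$total, nrow(tup))
  tall <- table(as.vector(tup[, seq_along(fx$sq$electrodes)]))
  ref <- numeric(nrow(fx$patch$mesh$vertices))
  ref[as.integer(names(tall))] <- as.vector(tall)
  # a trajectory visiting a vertex in two layers still counts once
  dup_rows <- apply(tup[, seq_along(fx$sq$electrodes), drop = FALSE], 1,
                    function(r) any(duplicated(r)))
  expect_false(any(dup_rows))  # distinct disks here, so tallies are exact
  expect_equal(hm$count, ref)
  expect_true(all(hm$percent >= 0 & hm$percent <= 100))
})

test_that("path-mode heatmaps dominate keypoint heatmaps vertexwise", {
  fx <- fix_small_patch()
  p <- search_params(r_diff = 0.25, v_diff = 0.25, patch_radius = 12)
  dp <- grow_solutions(fx$patch, fx$sq, p)
  hk <- heatmap_solutions(dp, fx$patch, mode = "keypoints")
  hp <- heatmap_solutions(dp, fx$patch, mode = "paths")
  expect_true(all(hp$count >= hk$count - 1e-9))
})

test_that("a sequence with an electrode missing from the patch is rejected", {
  fx <- fix_small_patch()
  sq <- hit_sequence(c("E1", "E2", "E9"), c(0, 2, 4))
  expect_error(grow_solutions(fx$patch, sq, search_params()), "E9")
})

test_that("search failure is reported as zero solutions, not an error", {
  fx <- fix_small_patch()
  # TOADs far too short for any admissible velocity <= 15 mm/min
  sq <- hit_sequence(fx$sq$electrodes, fx$sq$times * 1e-3)
  dp <- grow_solutions(fx$patch, sq, search_params(patch_radius = 12))
  expect_false(dp$success)
  expect_identical(as.double(count_solutions(dp)), 0)
})
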