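test_that("segment velocity equals the subrange central value when occupied", {
  fx <- fix_small_patch()
  dp <- grow_solutions(fx$patch, fx$sq,
                       search_params(r_diff = 1, v_diff = 1, patch_radius = 12))
  occupied <- which(vapply(seq_len(15), function(ci)
    as.double(count_solutions(dp, subrange = ci)) > 0, logical(1)))
  expect_gt(length(occupied), 0)
  for (ci in occupied) {
    expect_identical(segment_velocity(dp, 1, ci), dp$subranges[[ci]]$center)
  }
  empty <- setdiff(seq_len(15), occupied)
  expect_true(is.na(segment_velocity(dp, 1, empty[1])))
})

test_that("per-segment velocities are the count-weighted mean of the
           occupied subrange centers", {
  fx <- fix_small_patch()
  dp <- grow_solutions(fx$patch, fx$sq,
                       search_params(r_diff = 1, v_diff = 1, patch_radius = 12))
  wts <- vapply(seq_len(15), function(ci)
    as.double(count_solutions(dp, subrange = ci)), numeric(1))
  ref <- sum((1:15) * wts) / sum(wts)
  sv <- segment_velocities(dp)
  expect_length(sv, length(fx$sq$toads))
  expect_equal(unique(sv), ref)
})

test_that("SD velocity is the TOAD-weighted mean of segment velocities", {
  expect_equal(sd_velocity(c(2, 4), c(1, 3)), (2 * 1 + 4 * 3) / 4)
})

test_that("SD velocity is invariant to rescaling all TOADs", {
  sv <- c(3.2, 4.1, 3.9)
  toads <- c(1.5, 2.5, 2)
  expect_equal(sd_velocity(sv, toads), sd_velocity(sv, toads * 7.3))
})

test_that("non-positive TOAD weights are rejected", {
  expect_error(sd_velocity(c(2, 3), c(1, 0)), "positive")
  expect_error(sd_velocity(c(2, 3), c(1)), "equal length")
})

test_that("leave-one-out reaches a withheld on-path electrode from every
           sampled trajectory", {
  fx <- fix_plane_strip()
  sq <- fix_plane_wave(velocity = 5, radius = 2)
  val <- validate_loo(fx$patch, sq, search_params(r_diff = 1, v_diff = 1),
                      n_samples = 30, seed = 7)
  expect_true(all(val$steps$searched))
  expect_equal(val$reach_fraction, 1.0)
  expect_true(val$success)
})

test_that("leave-one-out is deterministic under its seed", {
  fx <- fix_plane_strip()
  sq <- fix_plane_wave(velocity = 5, radius = 2)
  p <- search_params(r_diff = 1, v_diff = 1)
  v1 <- validate_loo(fx$patch, sq, p, n_samples = 15, seed = 11)
  v2 <- validate_loo(fx$patch, sq, p, n_samples = 15, seed = 11)
  expect_identical(v1$steps, v2$steps)
  expect_identical(v1$spatial_errors, v2$spatial_errors)
})

test_that("a failed reduced search is recorded as a failed step, not an error", {
  fx <- fix_plane_strip()
  # implausible timing: withholding cannot rescue a sequence that admits no
  # velocity below the 15 mm/min cap
  sq <- hit_sequence(paste0("E", 1:4), c(0, 0.01, 0.02, 0.03))
  val <- validate_loo(fx$patch, sq, search_params(), n_samples = 5, seed = 1)
  expect_false(any(val$steps$searched))
  expect_false(val$success)
})

test_that("sequences shorter than a triad cannot be validated", {
  fx <- fix_plane_strip()
  sq <- hit_sequence(c("E1", "E2"), c(0, 2))
  expect_error(validate_loo(fx$patch, sq, search_params()), "triad")
})
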