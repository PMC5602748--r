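events_csv <- function(text) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(text, f)
  f
}

test_that("event tables parse with absent electrodes kept as non-hits", {
  f <- events_csv(c("event_id,electrode,onset_min",
                    "SD1,E1,0", "SD1,E2,2", "SD1,E3,NA",
                    "SD2,E1,10", "SD2,E2,12.5"))
  ev <- read_events(f)
  expect_named(ev, c("SD1", "SD2"))
  expect_named(ev$SD1$onsets, c("E1", "E2"))  # NA onset dropped as non-hit
  expect_equal(ev$SD2$onsets[["E2"]], 12.5)
})

test_that("duplicate (event, electrode) rows are rejected", {
  f <- events_csv(c("event_id,electrode,onset_min",
                    "SD1,E1,0", "SD1,E1,1"))
  expect_error(read_events(f), "duplicate")
})

test_that("missing required columns are reported by name", {
  f <- events_csv(c("event_id,electrode", "SD1,E1"))
  expect_error(read_events(f), "onset_min")
})

test_that("hit sequences order electrodes by onset and store the TOADs", {
  ev <- sd_event("S", c(E3 = 5, E1 = 1, E2 = 2.5))
  sq <- build_hit_sequence(ev)
  expect_identical(sq$electrodes, c("E1", "E2", "E3"))
  expect_equal(sq$toads, c(1.5, 2.5))
})

test_that("fewer than three hits cannot form a searchable sequence", {
  expect_error(build_hit_sequence(sd_event("S", c(E1 = 0, E2 = 2))),
               "insufficient electrodes")
})

test_that("simultaneous onsets are rejected as untimeable", {
  expect_error(build_hit_sequence(sd_event("S", c(E1 = 0, E2 = 2, E3 = 2))),
               "simultaneous")
})

test_that("a strip-monotone sequence passes reduction unchanged", {
  sq <- build_hit_sequence(sd_event("S", setNames(seq(0, 10, 2), paste0("E", 1:6))))
  red <- reduce_hit_sequence(sq, paste0("E", 1:6))
  expect_identical(red$electrodes, sq$electrodes)
  expect_identical(red$removed, character(0))
  expect_true(red$reduced)
})

test_that("a first-hit interior electrode splits the sequence and the shorter
           branch is removed", {
  # E3 first, then up-run E4..E6 and down-run E2, E1
  ons <- c(E3 = 0, E4 = 2, E2 = 3, E5 = 4, E1 = 5, E6 = 6)
  sq <- build_hit_sequence(sd_event("S", ons))
  red <- reduce_hit_sequence(sq, paste0("E", 1:6))
  expect_identical(red$electrodes, c("E3", "E4", "E5", "E6"))
  expect_setequal(red$removed, c("E2", "E1"))
})

test_that("equal-length branches drop the branch finishing later", {
  ons <- c(E3 = 0, E4 = 1, E2 = 2, E5 = 3, E1 = 6)
  sq <- build_hit_sequence(sd_event("S", ons))
  red <- reduce_hit_sequence(sq, paste0("E", 1:6))
  expect_identical(red$electrodes, c("E3", "E4", "E5"))
  expect_setequal(red$removed, c("E2", "E1"))
})

test_that("sequences that do not decompose into two runs are flagged", {
  ons <- c(E1 = 0, E3 = 2, E5 = 3, E2 = 4, E4 = 6, E6 = 8)
  sq <- build_hit_sequence(sd_event("S", ons))
  red <- reduce_hit_sequence(sq, paste0("E", 1:6))
  expect_false(red$reducible)
  expect_identical(red$electrodes, sq$electrodes)
})

test_that("susceptibility metrics aggregate intervals, daily peaks and PTDDD", {
  mk <- function(id, t0, day, dep, active) {
    sd_event(id, c(E1 = t0, E2 = t0 + 2, E3 = t0 + 4),
             depression = c(E1 = dep, E2 = dep, E3 = dep),
             active = c(E1 = active, E2 = active, E3 = active), day = day)
  }
  evs <- list(mk("a", 0, 1, 10, TRUE), mk("b", 60, 1, 20, TRUE),
              mk("c", 150, 2, 5, FALSE))
  s <- susceptibility_metrics(evs)
  expect_identical(s$n_events, 3L)
  expect_equal(s$median_interval_min, median(c(60, 90)))
  expect_identical(s$peak_sds_per_day, 2L)
  expect_identical(s$peak_spreading_depressions_per_day, 2L)
  expect_identical(s$peak_isoelectric_per_day, 1L)
  expect_equal(s$ptddd_min, 90)  # day 1: 3*10 + 3*20
})

test_that("susceptibility metrics degrade to NA without optional annotations", {
  evs <- list(sd_event("a", c(E1 = 0, E2 = 2, E3 = 4)))
  s <- susceptibility_metrics(evs)
  expect_identical(s$n_events, 1L)
  expect_true(is.na(s$median_interval_min))
  expect_true(is.na(s$ptddd_min))
})
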