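#' Read SD events from a CSV/TSV table
#'
#' Expected columns: `event_id`, `electrode`, `onset_min` (NA when the
#' electrode was not hit), and optionally `depression_min`, `dc_shift_min`,
#' `active` (logical: was the tissue electrically active), `day` (recording
#' day index). One row per (event, electrode).
#'
#' @param path CSV (or TSV, by extension) file path
#' @return list of `sd_event` objects
#' @export
read_events <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("event_id", "electrode", "onset_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  key <- paste(df$event_id, df$electrode)
  if (anyDuplicated(key)) {
    rows <- which(key %in% key[duplicated(key)])
    stop(sprintf("duplicate (event, electrode) rows: %s",
                 paste(rows, collapse = ", ")))
  }
  if (!is.numeric(df$onset_min)) stop("onset_min must be numeric")
  lapply(split(df, df$event_id)[unique(as.character(df$event_id))], function(d) {
    sd_event(id = d$event_id[1],
             onsets = setNames(d$onset_min, d$electrode),
             depression = if ("depression_min" %in% names(d))
               setNames(d$depression_min, d$electrode),
             dc_shift = if ("dc_shift_min" %in% names(d))
               setNames(d$dc_shift_min, d$electrode),
             active = if ("active" %in% names(d))
               setNames(as.logical(d$active), d$electrode),
             day = if ("day" %in% names(d)) d$day[1] else NA_integer_)
  })
}

#' A single spreading-depolarization event
#'
#' @param id event identifier
#' @param onsets named numeric vector of per-electrode SD onset times (min);
#'   electrodes that were not hit are NA or omitted
#' @param depression optional named vector of depression durations (min)
#' @param dc_shift optional named vector of DC-shift durations (min)
#' @param active optional named logical: electrode over electrically active tissue
#' @param day recording day index
#' @return an `sd_event`
#' @export
sd_event <- function(id, onsets, depression = NULL, dc_shift = NULL,
                     active = NULL, day = NA_integer_) {
  onsets <- onsets[!is.na(onsets)]
  if (!length(onsets)) stop("at least one onset must be present")
  if (any(!is.finite(onsets)) || any(onsets < 0))
    stop("onsets must be finite and non-negative")
  structure(list(id = id, onsets = onsets, depression = depression,
                 dc_shift = dc_shift, active = active, day = day),
            class = "sd_event")
}

#' @export
print.sd_event <- function(x, ...) {
  cat(sprintf("<sd_event> %s: %d onsets (%s), day %s\n", x$id, length(x$onsets),
              paste(names(sort(x$onsets)), collapse = "-"), x$day))
  invisible(x)
}

#' Order the electrode hits of an SD event
#'
#' Sorts onsets into the hit order and derives the TOADs (time-of-SD-arrival-
#' differences) between consecutive hits. The trajectory search needs at
#' least three hit electrodes; tied onsets are rejected because a zero TOAD
#' would imply infinite segment velocity.
#'
#' @param event an `sd_event`
#' @param min_hits minimum number of hit electrodes (default 3)
#' @return a `hit_sequence`: list(electrodes, times, toads, reduced, removed)
#' @export
build_hit_sequence <- function(event, min_hits = 3L) {
  on <- event$onsets
  if (length(on) < min_hits)
    stop(sprintf("insufficient electrodes: %d hit, need >= %d", length(on), min_hits))
  if (anyDuplicated(on))
    stop("simultaneous onsets: tied onset times are not searchable (zero TOAD)")
  o <- order(on)
  hit_sequence(names(on)[o], unname(on[o]), event_id = event$id)
}

#' Construct a hit sequence directly
#' @param electrodes electrode labels in hit order
#' @param times onset times (min), strictly increasing
#' @param reduced has branch reduction been applied
#' @param removed labels removed by branch reduction
#' @param event_id originating event id
#' @param reducible FALSE when the sequence could not be decomposed into at
#'   most two monotone strip runs
#' @export
hit_sequence <- function(electrodes, times, reduced = FALSE, removed = character(0),
                         event_id = NA_character_, reducible = TRUE) {
  stopifnot(length(electrodes) == length(times))
  if (any(diff(times) <= 0)) stop("hit times must be strictly increasing")
  structure(list(electrodes = as.character(electrodes), times = as.numeric(times),
                 toads = diff(times), reduced = reduced, removed = removed,
                 reducible = reducible, event_id = event_id),
            class = "hit_sequence")
}

#' @export
print.hit_sequence <- function(x, ...) {
  cat(sprintf("<hit_sequence> %s  TOADs: %s min%s%s\n",
              paste(x$electrodes, collapse = "-"),
              paste(signif(x$toads, 4), collapse = ", "),
              if (x$reduced) " [reduced]" else "",
              if (length(x$removed)) paste0(" (removed ", paste(x$removed, collapse = ","), ")") else ""))
  invisible(x)
}

#' Branch reduction of a hit sequence
#'
#' SDs that first arrive at an interior strip electrode can continue in both
#' directions along the strip (branching). When the hits after the first
#' split into two runs monotone in strip index, the shorter branch is removed
#' (on equal branch lengths, the branch whose final hit occurs later).
#' Monotone sequences are returned unchanged; sequences not decomposable into
#' at most two monotone runs are flagged non-reducible and returned
#' unchanged. Reduction is idempotent.
#'
#' @param seq a `hit_sequence`
#' @param strip_order electrode labels in physical strip order (e.g. E1..E6)
#' @return a `hit_sequence` with the `reduced` flag set
#' @export
reduce_hit_sequence <- function(seq, strip_order) {
  if (!all(seq$electrodes %in% strip_order))
    stop(sprintf("electrode(s) not on strip: %s",
                 paste(setdiff(seq$electrodes, strip_order), collapse = ", ")))
  idx <- match(seq$electrodes, strip_order)
  mono <- all(diff(idx) > 0) || all(diff(idx) < 0)
  if (mono) {
    out <- seq
    out$reduced <- TRUE
    return(out)
  }
  first <- idx[1]
  rest <- idx[-1]
  up <- rest > first
  down <- rest < first
  decomposable <- all(up | down) &&
    all(diff(rest[up]) > 0) && all(diff(-rest[down]) > 0)
  if (!decomposable) {
    out <- seq
    out$reduced <- TRUE
    out$reducible <- FALSE
    return(out)
  }
  pos_rest <- seq_along(rest)
  branches <- list(up = pos_rest[up], down = pos_rest[down])
  nlen <- lengths(branches)
  drop_branch <- if (nlen["up"] != nlen["down"]) {
    names(which.min(nlen))
  } else {
    # equal lengths: remove the branch whose final hit occurred later
    last_t <- vapply(branches, function(p) max(seq$times[-1][p]), numeric(1))
    names(which.max(last_t))
  }
  drop_pos <- branches[[drop_branch]] + 1L  # positions in the full sequence
  keep <- setdiff(seq_along(seq$electrodes), drop_pos)
  hit_sequence(seq$electrodes[keep], seq$times[keep], reduced = TRUE,
               removed = seq$electrodes[drop_pos], event_id = seq$event_id)
}

#' Per-patient SD susceptibility summary
#'
#' Computes the COSBID-style occurrence measures: the median interval between
#' an SD and the previous SD (from consecutive first-onset times), peak daily
#' counts of all SDs / spreading depressions / isoelectric SDs, and the PTDDD
#' (peak total SD-induced depression duration of a recording day: the maximum
#' over days of the summed depression durations).
#'
#' An event counts as isoelectric when every hit electrode lies over
#' electrically inactive tissue, and as a spreading depression otherwise
#' (classification requires the `active` flags; days require `day`).
#'
#' @param events list of `sd_event`
#' @return list of summary values (NA/NULL where inputs are absent)
#' @export
susceptibility_metrics <- function(events) {
  if (!length(events)) {
    return(list(n_events = 0L, median_interval_min = NA_real_,
                peak_sds_per_day = NA_integer_,
                peak_spreading_depressions_per_day = NA_integer_,
                peak_isoelectric_per_day = NA_integer_, ptddd_min = NA_real_))
  }
  first_on <- vapply(events, function(e) min(e$onsets), numeric(1))
  o <- order(first_on)
  events <- events[o]; first_on <- first_on[o]
  intervals <- diff(first_on)
  days <- vapply(events, function(e) as.integer(e$day), integer(1))
  isoelectric <- vapply(events, function(e) {
    if (is.null(e$active)) return(NA)
    hit <- names(e$onsets)
    all(!e$active[hit], na.rm = FALSE)
  }, logical(1))
  daily_count <- if (all(is.na(days))) NA_integer_ else
    max(table(days[!is.na(days)]))
  daily_sd <- if (all(is.na(days)) || all(is.na(isoelectric))) NA_integer_ else
    suppressWarnings(max(table(days[!is.na(days) & !is.na(isoelectric) & !isoelectric]), 0L))
  daily_iso <- if (all(is.na(days)) || all(is.na(isoelectric))) NA_integer_ else
    suppressWarnings(max(table(days[!is.na(days) & !is.na(isoelectric) & isoelectric]), 0L))
  dep_by_day <- vapply(events, function(e)
    if (is.null(e$depression)) NA_real_ else sum(e$depression, na.rm = TRUE), numeric(1))
  ptddd <- if (all(is.na(dep_by_day)) || all(is.na(days))) NA_real_ else
    max(rowsum(dep_by_day[!is.na(days)], days[!is.na(days)], na.rm = TRUE))
  list(n_events = length(events),
       median_interval_min = if (length(intervals)) stats::median(intervals) else NA_real_,
       peak_sds_per_day = as.integer(daily_count),
       peak_spreading_depressions_per_day = as.integer(daily_sd),
       peak_isoelectric_per_day = as.integer(daily_iso),
       ptddd_min = as.numeric(ptddd))
}
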