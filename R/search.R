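#' Trajectory-search parameters
#'
#' Tolerances and ranges of the 'could fit' trajectory search. `r_diff` (mm)
#' bounds the change of the wave-front curvature radius between consecutive
#' sub-trajectory sets; `v_diff` (mm/min) is the half-width of the velocity
#' sub-ranges (fifteen overlapping closed intervals centered at 1..15 mm/min
#' by default). The accepted velocity range is 0-15 mm/min and the accepted
#' curvature radius 0-5 mm around each electrode; candidate center disks use
#' `r_max`.
#'
#' @param r_diff radius-difference tolerance (mm), > 0
#' @param v_diff velocity-difference tolerance / subrange half-width (mm/min), > 0
#' @param v_min,v_max accepted velocity range (mm/min)
#' @param r_max candidate disk radius (mm), must be below `patch_radius`
#' @param patch_radius patch radius (mm)
#' @param centers velocity subrange central values (mm/min)
#' @param seed random seed used by sampling helpers
#' @return a `search_params`
#' @export
search_params <- function(r_diff = 1, v_diff = 1, v_min = 0, v_max = 15,
                          r_max = 5, patch_radius = 30, centers = 1:15,
                          seed = 1L) {
  stopifnot(r_diff > 0, v_diff > 0, v_max > v_min, r_max < patch_radius)
  structure(list(r_diff = r_diff, v_diff = v_diff, v_min = v_min, v_max = v_max,
                 r_max = r_max, patch_radius = patch_radius,
                 centers = as.numeric(centers), seed = as.integer(seed)),
            class = "search_params")
}

#' @export
print.search_params <- function(x, ...) {
  cat(sprintf("<search_params> R_diff=%g mm, V_diff=%g mm/min, v in [%g,%g], r_max=%g mm, %d subranges\n",
              x$r_diff, x$v_diff, x$v_min, x$v_max, x$r_max, length(x$centers)))
  invisible(x)
}

#' Candidate center disk around an electrode
#'
#' All patch vertices whose geodesic distance to the electrode vertex is at
#' most `r_max` — the candidate positions for the wave-front curvature
#' center while the front touches that electrode. The stored radius of a
#' member is its geodesic distance to the electrode (the front's curvature
#' radius if the center sits there).
#'
#' @param patch an `sd_patch`
#' @param electrode electrode label (must be named in the patch) or patch
#'   vertex id
#' @param r_max disk radius (mm)
#' @return an `sd_disk`: list(label, vertex, members, radii)
#' @export
candidate_disk <- function(patch, electrode, r_max = 5) {
  if (is.character(electrode)) {
    ev <- patch$electrode_vertices[[electrode]]
    if (is.null(ev)) stop(sprintf("electrode %s not in patch", electrode))
    label <- electrode
  } else {
    ev <- as.integer(electrode)
    hit <- match(ev, patch$electrode_vertices)
    label <- if (!is.na(hit)) names(patch$electrode_vertices)[hit] else NA_character_
  }
  gm <- geodesic_from(patch$mesh, ev)
  members <- which(gm$dist <= r_max)
  o <- order(gm$dist[members], members)
  members <- members[o]
  structure(list(label = label, vertex = as.integer(ev),
                 members = as.integer(members), radii = gm$dist[members]),
            class = "sd_disk")
}

#' Bipartite geodesic distances between two candidate disks
#'
#' Pre-computes the geodesic distance within the patch between every pair of
#' candidate centers (a, b), plus the Dijkstra predecessor trees so the
#' canonical shortest path of any pair can be extracted on demand.
#' Unreachable pairs carry `Inf` and are excluded downstream.
#'
#' @param patch an `sd_patch`
#' @param diskA,diskB `sd_disk` objects
#' @return an `sd_bipartite`: list(dist = |A| x |B| matrix, pred, sources)
#' @export
bipartite_distances <- function(patch, diskA, diskB) {
  if (!length(diskA$members) || !length(diskB$members)) stop("empty candidate disk")
  gm <- geodesic_multi(patch$mesh, diskA$members)
  structure(list(dist = gm$dist[diskB$members, , drop = FALSE] |> t(),
                 pred = gm$pred, sources = diskA$members,
                 members_a = diskA$members, members_b = diskB$members),
            class = "sd_bipartite")
}

# canonical shortest path between diskA member (index ia) and patch vertex b
bipartite_path <- function(bip, ia, b) {
  pred <- bip$pred[, ia]
  path <- integer(0)
  v <- as.integer(b)
  src <- bip$sources[ia]
  while (!is.na(v)) {
    path <- c(v, path)
    if (v == src) break
    v <- pred[v]
  }
  if (path[1] != src) stop("unreachable pair")
  path
}

#' Grow the set of 'could fit' trajectories
#'
#' The layered dynamic program at the heart of the trajectory search.
#' Partial trajectories are grown from zero length, one hit electrode at a
#' time, grouped by their end vertex; for each velocity subrange
#' independently, a pair (a at layer N-1, b at layer N) is admissible iff the
#' segment velocity d(a,b)/TOAD lies in the closed subrange (intersected
#' with the accepted velocity range) and the wave-front curvature radii
#' approximately match: |d(a, E_(N-1)) - d(b, E_N)| <= R_diff. Counts are
#' propagated exactly with big-integer arithmetic; an SD is successfully
#' simulated iff the total count is positive in at least one subrange.
#'
#' @param patch an `sd_patch` containing every electrode of the sequence
#' @param seq a `hit_sequence`
#' @param params a [search_params()]
#' @param min_hits minimum sequence length (3 for SDs; leave-one-out
#'   validation internally searches 2-hit sequences)
#' @return an `sd_solutions` object
#' @export
grow_solutions <- function(patch, seq, params = search_params(), min_hits = 3L) {
  L <- length(seq$electrodes)
  if (L < min_hits) stop(sprintf("hit sequence too short: %d < %d", L, min_hits))
  if (!all(seq$electrodes %in% names(patch$electrode_vertices)))
    stop(sprintf("electrode(s) not in patch: %s",
                 paste(setdiff(seq$electrodes, names(patch$electrode_vertices)),
                       collapse = ", ")))
  if (any(seq$toads <= 0)) stop("TOADs must be strictly positive")
  disks <- lapply(seq$electrodes, function(lb) candidate_disk(patch, lb, params$r_max))
  bip <- vector("list", L - 1L)
  for (k in seq_len(L - 1L)) bip[[k]] <- bipartite_distances(patch, disks[[k]], disks[[k + 1L]])

  subranges <- lapply(params$centers, function(cen) {
    lo <- max(cen - params$v_diff, params$v_min)
    hi <- min(cen + params$v_diff, params$v_max)
    forward <- vector("list", L)
    adm <- vector("list", L - 1L)
    forward[[1]] <- big_layer_init(length(disks[[1]]$members))
    for (k in seq_len(L - 1L)) {
      v <- bip[[k]]$dist / seq$toads[k]
      ok_v <- v >= lo & v <= hi            # |A| x |B|
      ok_r <- abs(outer(disks[[k]]$radii, disks[[k + 1L]]$radii, "-")) <= params$r_diff
      a <- t(ok_v & ok_r) * 1              # rows = layer k+1, cols = layer k
      adm[[k]] <- a
      forward[[k + 1L]] <- big_layer_propagate(a, forward[[k]])
    }
    total <- big_layer_total(forward[[L]])
    list(center = cen, lo = lo, hi = hi, forward = forward, adm = adm,
         total = total)
  })
  total <- Reduce(big_add, lapply(subranges, `[[`, "total"), 0)
  structure(list(seq = seq, params = params, disks = disks, bip = bip,
                 subranges = subranges, total = total,
                 success = !big_is_zero(total)),
            class = "sd_solutions")
}

#' @export
print.sd_solutions <- function(x, ...) {
  cat(sprintf("<sd_solutions> %s: %s, %s 'could fit' trajectories over %d subranges\n",
              paste(x$seq$electrodes, collapse = "-"),
              if (x$success) "success" else "no solution",
              big_to_string(x$total), length(x$subranges)))
  invisible(x)
}

#' Exact total number of 'could fit' trajectories
#'
#' Sum over velocity subranges of the final-layer counts, as an
#' arbitrary-precision integer (counts in patient data reach 1e16 and
#' beyond, far past exact double range). Overlapping subranges count a
#' geometric trajectory once per subrange it is valid in; `dedup = TRUE`
#' enumerates distinct center tuples instead (tiny instances only).
#'
#' @param dp an `sd_solutions`
#' @param dedup count distinct geometric trajectories (enumerates; only
#'   feasible when the raw count is small)
#' @param subrange when given, the count for this velocity subrange alone
#' @return an `sd_bigcount` (decimal string via `format`/`as.character`,
#'   approximate numeric via `as.double`)
#' @export
count_solutions <- function(dp, dedup = FALSE, subrange = NULL) {
  if (!is.null(subrange)) {
    if (dedup) stop("dedup is only available for the overall count")
    return(new_bigcount(dp$subranges[[subrange]]$total))
  }
  if (!dedup) return(new_bigcount(dp$total))
  tuples <- enumerate_solutions(dp)
  if (nrow(tuples)) {
    keys <- apply(tuples[, seq_along(dp$disks), drop = FALSE], 1, paste, collapse = ",")
    new_bigcount(big_from_num(length(unique(keys))))
  } else new_bigcount(0)
}

new_bigcount <- function(limbs) structure(list(limbs = big_trim(limbs)), class = "sd_bigcount")

#' @export
format.sd_bigcount <- function(x, ...) big_to_string(x$limbs)

#' @export
print.sd_bigcount <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
as.character.sd_bigcount <- function(x, ...) big_to_string(x$limbs)

#' @export
as.double.sd_bigcount <- function(x, ...) big_to_double(x$limbs)

# backward counts: completions from each vertex at each layer to the end
solutions_backward <- function(dp) {
  L <- length(dp$disks)
  lapply(dp$subranges, function(sr) {
    backward <- vector("list", L)
    backward[[L]] <- big_layer_init(length(dp$disks[[L]]$members))
    for (k in rev(seq_len(L - 1L))) {
      backward[[k]] <- big_layer_propagate(t(sr$adm[[k]]), backward[[k + 1L]])
    }
    backward
  })
}

#' Enumerate all 'could fit' trajectories (tiny instances)
#'
#' Depth-first enumeration of every admissible center tuple per subrange.
#' Exists for exact-deduplication and inspection; the DP big-integer count is
#' the scalable route.
#'
#' @param dp an `sd_solutions`
#' @param max_n abort if more than this many tuples would be produced
#' @return matrix with one row per (trajectory, subrange): patch vertex ids
#'   per layer plus the subrange index
#' @export
enumerate_solutions <- function(dp, max_n = 1e6) {
  if (big_cmp(dp$total, big_from_num(max_n)) > 0)
    stop("solution set too large to enumerate")
  L <- length(dp$disks)
  out <- list()
  for (s in seq_along(dp$subranges)) {
    sr <- dp$subranges[[s]]
    if (big_is_zero(sr$total)) next
    partial <- matrix(seq_along(dp$disks[[1]]$members), ncol = 1)
    ok <- rep(TRUE, nrow(partial))
    for (k in seq_len(L - 1L)) {
      nxt <- list()
      for (r in seq_len(nrow(partial))) {
        a <- partial[r, k]
        bs <- which(sr$adm[[k]][, a] > 0)
        if (length(bs)) nxt[[length(nxt) + 1L]] <-
            cbind(partial[rep(r, length(bs)), , drop = FALSE], bs)
      }
      if (!length(nxt)) { partial <- matrix(integer(0), 0, k + 1); break }
      partial <- do.call(rbind, nxt)
    }
    if (nrow(partial)) {
      verts <- matrix(0L, nrow(partial), L)
      for (k in seq_len(L)) verts[, k] <- dp$disks[[k]]$members[partial[, k]]
      out[[length(out) + 1L]] <- cbind(verts, subrange = s)
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, L + 1))
  do.call(rbind, out)
}

#' Per-vertex trajectory-inclusion heatmap
#'
#' For every vertex, the number (and percentage) of 'could fit' trajectories
#' that include it — through a key point (candidate center) or, with
#' `mode = "paths"`, through the canonical geodesic path connecting
#' consecutive centers. Computed as total minus the count of trajectories
#' avoiding the vertex (a re-run of the DP with the vertex excluded), which
#' never counts a trajectory twice.
#'
#' @param dp an `sd_solutions` with at least one solution
#' @param patch the patch the search ran on
#' @param mode `"keypoints"` or `"paths"`
#' @return an `sd_heatmap`: list(count, percent, total) over patch vertices
#' @export
heatmap_solutions <- function(dp, patch, mode = c("paths", "keypoints")) {
  mode <- match.arg(mode)
  if (!dp$success) stop("no trajectories")
  L <- length(dp$disks)
  nV <- nrow(patch$mesh$vertices)
  total <- big_to_double(dp$total)

  # vertices that can appear on any trajectory, and (paths mode) the pairs
  # whose canonical connecting path contains each vertex
  member_layers <- lapply(dp$disks, `[[`, "members")
  relevant <- sort(unique(unlist(member_layers)))
  path_hits <- NULL
  if (mode == "paths") {
    path_hits <- vector("list", L - 1L)  # per step: list vertex -> pair index rows
    for (k in seq_len(L - 1L)) {
      any_adm <- Reduce(`+`, lapply(dp$subranges, function(sr) sr$adm[[k]])) > 0
      pairs <- which(any_adm, arr.ind = TRUE)  # rows: (b_idx, a_idx)
      hit <- list()
      for (r in seq_len(nrow(pairs))) {
        b <- pairs[r, 1]; a <- pairs[r, 2]
        pv <- bipartite_path(dp$bip[[k]], a, dp$disks[[k + 1L]]$members[b])
        interior <- setdiff(pv, c(pv[1], pv[length(pv)]))
        for (v in interior) {
          key <- as.character(v)
          hit[[key]] <- rbind(hit[[key]], c(b, a))
        }
      }
      path_hits[[k]] <- hit
      relevant <- sort(unique(c(relevant, as.integer(names(hit)))))
    }
  }

  counts <- numeric(nV)
  for (v in relevant) {
    avoid <- 0
    for (sr in dp$subranges) {
      layer <- as.numeric(member_layers[[1]] != v)
      for (k in seq_len(L - 1L)) {
        a <- sr$adm[[k]]
        if (!is.null(path_hits)) {
          blocked <- path_hits[[k]][[as.character(v)]]
          if (!is.null(blocked)) {
            a <- a + 0  # copy
            a[blocked] <- 0
          }
        }
        layer <- as.vector(a %*% layer)
        layer[member_layers[[k + 1L]] == v] <- 0
      }
      avoid <- avoid + sum(layer)
    }
    counts[v] <- total - avoid
  }
  structure(list(count = counts, percent = 100 * counts / total, total = total,
                 mode = mode),
            class = "sd_heatmap")
}

#' Attach a heatmap to a patch mesh and write it as PLY
#' @param hm an `sd_heatmap`
#' @param patch the `sd_patch` it belongs to
#' @param path output PLY path
#' @export
write_heatmap_ply <- function(hm, patch, path) {
  m <- patch$mesh
  m$scalar <- hm$percent
  write_surface(m, path, format = "ply")
}

#' Sample trajectories uniformly from the solution set
#'
#' Draws `n` trajectories uniformly (with replacement) over all 'could fit'
#' trajectories, by first choosing a velocity subrange proportional to its
#' count and then walking the layers forward with backward-count-proportional
#' vertex choices. Reproducible under `seed`.
#'
#' @param dp an `sd_solutions` with at least one solution
#' @param n number of samples
#' @param seed RNG seed
#' @return list of `sd_trajectory` objects: vertices (one candidate center
#'   per layer), per-segment geodesic distance and velocity, per-layer
#'   curvature radii, and the subrange index
#' @export
sample_trajectories <- function(dp, n, seed = dp$params$seed) {
  if (!dp$success) stop("no trajectories")
  L <- length(dp$disks)
  backward <- solutions_backward(dp)
  wts <- vapply(dp$subranges, function(sr) big_to_double(sr$total), numeric(1))
  set.seed(seed)
  s_pick <- sample.int(length(wts), n, replace = TRUE, prob = wts)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- s_pick[i]
    sr <- dp$subranges[[s]]
    bw <- backward[[s]]
    w1 <- rowSums(bw[[1]] * BIG_BASE^(col(bw[[1]]) - 1))
    idx <- numeric(L)
    idx[1] <- sample.int(length(w1), 1, prob = w1)
    for (k in seq_len(L - 1L)) {
      wnext <- sr$adm[[k]][, idx[k]] *
        rowSums(bw[[k + 1L]] * BIG_BASE^(col(bw[[k + 1L]]) - 1))
      idx[k + 1L] <- sample.int(length(wnext), 1, prob = wnext)
    }
    verts <- vapply(seq_len(L), function(k) dp$disks[[k]]$members[idx[k]], integer(1))
    dists <- vapply(seq_len(L - 1L), function(k) dp$bip[[k]]$dist[idx[k], idx[k + 1L]],
                    numeric(1))
    radii <- vapply(seq_len(L), function(k) dp$disks[[k]]$radii[idx[k]], numeric(1))
    out[[i]] <- structure(list(vertices = verts, member_index = idx,
                               segment_distance = dists,
                               segment_velocity = dists / dp$seq$toads,
                               radii = radii, subrange = s,
                               center = sr$center),
                          class = "sd_trajectory")
  }
  out
}

#' Check a sampled trajectory against every admissibility constraint
#' @param traj an `sd_trajectory`
#' @param dp the `sd_solutions` it was sampled from
#' @return TRUE/FALSE
#' @export
verify_trajectory <- function(traj, dp) {
  sr <- dp$subranges[[traj$subrange]]
  all(traj$segment_velocity >= sr$lo & traj$segment_velocity <= sr$hi) &&
    all(traj$radii <= dp$params$r_max) &&
    all(abs(diff(traj$radii)) <= dp$params$r_diff)
}
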