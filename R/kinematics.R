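#' Quantized velocity of one electrode-to-electrode segment
#'
#' Within one velocity subrange every admissible sub-trajectory velocity on
#' the segment is quantized toward the subrange's central value, so the
#' count-weighted mean over that subrange equals the central value whenever
#' the subrange holds solutions (NA otherwise).
#'
#' @param dp an `sd_solutions`
#' @param segment segment index (1 .. number of TOADs)
#' @param subrange subrange index (1 .. 15 by default)
#' @return velocity in mm/min
#' @export
segment_velocity <- function(dp, segment, subrange) {
  if (segment < 1 || segment > length(dp$seq$toads)) stop("empty segment")
  sr <- dp$subranges[[subrange]]
  if (big_is_zero(sr$total)) return(NA_real_)
  sr$center
}

#' Per-segment velocities aggregated across subranges
#'
#' Count-weighted mean of the quantized (central) velocities over all
#' subranges holding solutions. Because quantization maps every
#' sub-trajectory of a subrange to its central value, the aggregate is the
#' same for every segment of the sequence.
#'
#' @param dp an `sd_solutions`
#' @return numeric vector, one velocity per segment (mm/min)
#' @export
segment_velocities <- function(dp) {
  if (!dp$success) return(rep(NA_real_, length(dp$seq$toads)))
  wts <- vapply(dp$subranges, function(sr) big_to_double(sr$total), numeric(1))
  cen <- vapply(dp$subranges, `[[`, numeric(1), "center")
  v <- sum(cen * wts) / sum(wts)
  rep(v, length(dp$seq$toads))
}

#' TOAD-weighted SD velocity
#'
#' The velocity of a whole SD: the weighted arithmetic mean of the
#' per-segment velocities with the TOADs as weights.
#'
#' @param segment_velocities velocities per segment (mm/min)
#' @param toads TOADs per segment (min), all positive
#' @return velocity in mm/min
#' @export
sd_velocity <- function(segment_velocities, toads) {
  if (length(segment_velocities) != length(toads))
    stop("segment_velocities and toads must have equal length")
  if (any(toads <= 0)) stop("TOADs must be positive")
  sum(segment_velocities * toads) / sum(toads)
}

#' Estimate the SD velocity from a solution set
#'
#' @param dp an `sd_solutions`
#' @return an `sd_velocity_estimate`: list(segment_velocity, toad, velocity)
#' @export
estimate_velocity <- function(dp) {
  sv <- segment_velocities(dp)
  structure(list(segment_velocity = sv, toad = dp$seq$toads,
                 velocity = if (anyNA(sv)) NA_real_ else sd_velocity(sv, dp$seq$toads)),
            class = "sd_velocity_estimate")
}

#' @export
print.sd_velocity_estimate <- function(x, ...) {
  cat(sprintf("<sd_velocity_estimate> %.2f mm/min (segments: %s)\n",
              x$velocity, paste(signif(x$segment_velocity, 3), collapse = ", ")))
  invisible(x)
}

#' Leave-one-electrode-out validation
#'
#' For every interior electrode of every consecutive triad, its hit is
#' withheld, the trajectory search re-run on the reduced sequence, and
#' `n_samples` trajectories sampled. A sample "reaches" the withheld
#' electrode when its wave front — the center moving along the canonical
#' geodesic paths between consecutive sampled centers, with the curvature
#' radius linearly interpolated between segment endpoints — comes within
#' radius + tolerance of the withheld electrode. For reaching samples the
#' predicted hit time is interpolated along the path and converted to a
#' spatial error, error = v_sample * (t_predicted - t_observed): positive
#' when the model predicts a later hit than observed.
#'
#' @param patch an `sd_patch`
#' @param seq a `hit_sequence` (>= 3 hits)
#' @param params a [search_params()]
#' @param n_samples trajectories sampled per validation step (default 100)
#' @param seed RNG seed
#' @param tolerance reach tolerance in mm; default one mean edge length of
#'   the patch
#' @param reach_rule per-SD success rule: `"fraction"` (mean reach fraction
#'   over steps >= `reach_threshold`) or `"any"`
#' @param reach_threshold threshold for the `"fraction"` rule
#' @return an `sd_validation`: per-step table plus per-SD aggregates
#' @export
validate_loo <- function(patch, seq, params = search_params(), n_samples = 100L,
                         seed = params$seed, tolerance = NULL,
                         reach_rule = c("fraction", "any"), reach_threshold = 0.5) {
  reach_rule <- match.arg(reach_rule)
  L <- length(seq$electrodes)
  if (L < 3L) stop("need at least one electrode triad")
  if (is.null(tolerance)) tolerance <- mean(mesh_edge_lengths(patch$mesh))
  steps <- list()
  errors_all <- numeric(0)
  for (i in 2:(L - 1L)) {
    withheld <- seq$electrodes[i]
    t_obs <- seq$times[i]
    red <- hit_sequence(seq$electrodes[-i], seq$times[-i], event_id = seq$event_id)
    dp <- grow_solutions(patch, red, params, min_hits = 2L)
    if (!dp$success) {
      steps[[length(steps) + 1L]] <- data.frame(
        withheld = withheld, searched = FALSE, reach_fraction = NA_real_,
        mean_spatial_error = NA_real_)
      next
    }
    samples <- sample_trajectories(dp, n_samples, seed = seed + i)
    wv <- patch$electrode_vertices[[withheld]]
    dw <- geodesic_from(patch$mesh, wv)$dist
    hit_t <- vapply(samples, function(tr)
      front_hit_time(tr, dp, red, dw, tolerance, patch$mesh), numeric(1))
    reached <- is.finite(hit_t)
    err <- numeric(0)
    if (any(reached)) {
      v_sample <- vapply(samples[reached], function(tr)
        sd_velocity(tr$segment_velocity, red$toads), numeric(1))
      err <- v_sample * (hit_t[reached] - t_obs)
    }
    errors_all <- c(errors_all, err)
    steps[[length(steps) + 1L]] <- data.frame(
      withheld = withheld, searched = TRUE, reach_fraction = mean(reached),
      mean_spatial_error = if (length(err)) mean(err) else NA_real_)
  }
  tab <- do.call(rbind, steps)
  reach <- mean(tab$reach_fraction[tab$searched], na.rm = TRUE)
  if (!any(tab$searched)) reach <- NA_real_
  success <- switch(reach_rule,
                    fraction = isTRUE(reach >= reach_threshold),
                    any = isTRUE(reach > 0))
  structure(list(steps = tab, reach_fraction = reach, success = success,
                 mean_spatial_error = if (length(errors_all)) mean(errors_all) else NA_real_,
                 median_spatial_error = if (length(errors_all)) stats::median(errors_all) else NA_real_,
                 spatial_errors = errors_all, tolerance = tolerance),
            class = "sd_validation")
}

#' @export
print.sd_validation <- function(x, ...) {
  cat(sprintf("<sd_validation> %d steps, reach fraction %.2f, %s, median spatial error %.2f mm\n",
              nrow(x$steps), x$reach_fraction,
              if (x$success) "success" else "failure", x$median_spatial_error))
  invisible(x)
}

# earliest time the sampled wave front reaches the withheld electrode:
# Inf when it never comes within radius + tolerance. The predicted time is
# the model's own touch time (front margin g = dist - radius crossing zero);
# the tolerance only grants reach slack for mesh discretization — when the
# front approaches within tolerance without touching, the time of closest
# approach is used, so the tolerance adds no systematic early-arrival bias.
front_hit_time <- function(traj, dp, seq, dist_withheld, tolerance, mesh) {
  L <- length(traj$vertices)
  for (k in seq_len(L - 1L)) {
    pv <- bipartite_path(dp$bip[[k]], traj$member_index[k], traj$vertices[k + 1L])
    xyz <- mesh$vertices[pv, , drop = FALSE]
    # cumulative arc length along the canonical path
    s <- if (length(pv) > 1L) {
      c(0, cumsum(sqrt(rowSums((xyz[-1, , drop = FALSE] -
                                xyz[-nrow(xyz), , drop = FALSE])^2))))
    } else 0
    stot <- s[length(s)]
    frac <- if (stot > 0) s / stot else rep(0, length(s))
    tt <- seq$times[k] + frac * seq$toads[k]
    rr <- traj$radii[k] + frac * (traj$radii[k + 1L] - traj$radii[k])
    g <- dist_withheld[pv] - rr
    if (any(g <= 0)) {
      m <- which(g <= 0)[1]
      if (m == 1L) return(tt[1])
      # linear interpolation of the zero crossing between points m-1 and m
      return(tt[m - 1L] + (tt[m] - tt[m - 1L]) * g[m - 1L] / (g[m - 1L] - g[m]))
    }
    if (min(g) <= tolerance) return(tt[which.min(g)])
  }
  Inf
}
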