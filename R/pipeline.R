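#' Default tolerance combinations for the trajectory search
#'
#' The six canonical (R_diff, V_diff) pairs swept by the search:
#' R_diff in {1, 0.5} mm crossed with V_diff in {1, 0.5, 0.25} mm/min.
#' @return data.frame with columns r_diff, v_diff
#' @export
tolerance_combinations <- function() {
  data.frame(r_diff = rep(c(1, 0.5), each = 3),
             v_diff = rep(c(1, 0.5, 0.25), times = 2))
}

#' Read a pipeline configuration
#'
#' @param path YAML file path
#' @return the configuration list, validated by [validate_config()]
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' A configuration holds exactly one of a `synthetic` generation block or an
#' `input` block (mesh + electrode centroids or CT volume + events), a
#' `seed`, and optional `params`, `output_dir`, `validate`, `heatmaps`,
#' `log_level` entries. Violations are reported before any computation.
#'
#' @param config a list
#' @return the config, with defaults filled in
#' @export
validate_config <- function(config) {
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp)
    stop("config must contain exactly one of 'synthetic' or 'input'")
  if (is.null(config$seed)) stop("config must set a seed")
  if (has_inp) {
    inp <- config$input
    if (is.null(inp$mesh) || is.null(inp$events))
      stop("input block needs 'mesh' and 'events' paths")
    if (is.null(inp$centroids) && is.null(inp$ct_volume))
      stop("input block needs 'centroids' or 'ct_volume'")
  }
  config$params <- utils::modifyList(
    list(r_max = 5, patch_radius = 30, v_min = 0, v_max = 15,
         upsample = 0L, smooth = 0L), config$params %||% list())
  config$subject <- config$subject %||% "S1"
  config$validate <- isTRUE(config$validate %||% TRUE)
  config$heatmaps <- isTRUE(config$heatmaps)
  config$log_level <- config$log_level %||% "info"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(level, config, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run the full SD trajectory pipeline
#'
#' Orchestrates the workflow: load or generate mesh, electrodes and events;
#' extract (optionally smooth and up-sample) the patch; for every SD and
#' every (R_diff, V_diff) tolerance combination run the trajectory search on
#' both the full and the branch-reduced hit sequence; estimate velocities;
#' optionally run leave-one-out validation and export heatmaps. Per-SD
#' search failures are first-class results, recorded and never fatal. All
#' randomness derives from the config seed.
#'
#' @param config configuration list (see [validate_config()]) or YAML path
#' @return (invisibly) the results bundle; JSON/CSV written to `output_dir`
#'   when one is configured
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  p <- config$params
  combos <- if (!is.null(p$combos)) {
    as.data.frame(do.call(rbind, lapply(p$combos, unlist)) |>
                    `colnames<-`(c("r_diff", "v_diff")))
  } else tolerance_combinations()

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    ds <- make_synthetic_dataset(
      seed = config$seed,
      n_events = syn$n_events %||% 12L,
      mesh_kind = syn$mesh_kind %||% "plane",
      spacing = syn$spacing %||% 1,
      velocity_range = unlist(syn$velocity_range %||% c(2, 9)),
      wave_radius = syn$wave_radius %||% 2,
      p_branching = syn$p_branching %||% 0.25,
      p_complex = syn$p_complex %||% 0,
      width = syn$width %||% 120, height = syn$height %||% 80)
    mesh <- ds$mesh; electrodes <- ds$electrodes; events <- ds$events
  } else {
    inp <- config$input
    mesh <- read_surface(inp$mesh, format = inp$mesh_format %||% "off")
    events <- read_events(inp$events)
    if (!is.null(inp$centroids)) {
      cen <- utils::read.csv(inp$centroids)
      electrodes <- snap_to_mesh(as.matrix(cen[, c("x", "y", "z")]), mesh,
                                 labels = cen$label)
    } else {
      electrodes <- locate_electrodes(read_volume(inp$ct_volume), mesh,
                                      labels = inp$electrode_order)
    }
  }
  strip_order <- electrodes$labels
  pipeline_log("info", config, "patch extraction around %d electrodes",
               length(strip_order))
  patch <- prep_patch(mesh, electrodes$vertex, radius = p$patch_radius,
                      smooth_iterations = p$smooth,
                      upsample_iterations = p$upsample)

  per_event <- list()
  for (ev in events) {
    rec <- list(event_id = ev$id)
    seq_full <- tryCatch(build_hit_sequence(ev), error = function(e) e)
    if (inherits(seq_full, "error")) {
      rec$skipped <- conditionMessage(seq_full)
      pipeline_log("warn", config, "%s skipped: %s", ev$id, rec$skipped)
      per_event[[ev$id]] <- rec
      next
    }
    seq_red <- reduce_hit_sequence(seq_full, strip_order)
    rec$full_sequence <- seq_full$electrodes
    rec$reduced_sequence <- seq_red$electrodes
    rec$removed <- seq_red$removed
    rec$combos <- list()
    for (ci in seq_len(nrow(combos))) {
      params <- search_params(r_diff = combos$r_diff[ci], v_diff = combos$v_diff[ci],
                              v_min = p$v_min, v_max = p$v_max, r_max = p$r_max,
                              patch_radius = p$patch_radius, seed = config$seed)
      res <- list(r_diff = params$r_diff, v_diff = params$v_diff)
      for (variant in c("full", "reduced")) {
        sq <- if (variant == "full") seq_full else seq_red
        dp <- grow_solutions(patch, sq, params)
        vel <- estimate_velocity(dp)
        res[[variant]] <- list(success = dp$success,
                               count = as.character(count_solutions(dp)),
                               velocity = vel$velocity,
                               segment_velocity = vel$segment_velocity)
        if (ci == 1L && variant == "reduced") {
          if (config$validate && dp$success && length(sq$electrodes) >= 3L) {
            val <- validate_loo(patch, sq, params, n_samples = 100L,
                                seed = config$seed)
            rec$validation <- list(reach_fraction = val$reach_fraction,
                                   success = val$success,
                                   median_spatial_error = val$median_spatial_error)
          }
          if (config$heatmaps && dp$success) {
            rec$heatmap <- heatmap_solutions(dp, patch, mode = "keypoints")
          }
        }
      }
      rec$combos[[ci]] <- res
      pipeline_log("debug", config, "%s combo (%g,%g): full=%s reduced=%s",
                   ev$id, params$r_diff, params$v_diff,
                   res$full$success, res$reduced$success)
    }
    per_event[[ev$id]] <- rec
  }

  summary_tab <- pipeline_summary(per_event, combos, config$subject)
  bundle <- list(subject = config$subject, seed = config$seed,
                 combos = combos, events = per_event, summary = summary_tab)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    json <- jsonlite::toJSON(bundle[c("subject", "seed", "events")],
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             null = "null")
    writeLines(json, file.path(config$output_dir, "results.json"))
    utils::write.csv(summary_tab, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
    pipeline_log("info", config, "results written to %s", config$output_dir)
  }
  invisible(bundle)
}

# per-subject success summary shaped rows = subject x variant,
# columns = tolerance combinations, cells = "k/N (pct%)"
pipeline_summary <- function(per_event, combos, subject) {
  searched <- Filter(function(r) is.null(r$skipped), per_event)
  n <- length(searched)
  rows <- lapply(c("full", "reduced"), function(variant) {
    cells <- vapply(seq_len(nrow(combos)), function(ci) {
      k <- sum(vapply(searched, function(r) isTRUE(r$combos[[ci]][[variant]]$success),
                      logical(1)))
      sprintf("%d/%d (%.1f%%)", k, n, if (n) 100 * k / n else 0)
    }, character(1))
    df <- data.frame(subject = subject, sequences = variant, n_events = n)
    for (ci in seq_len(nrow(combos))) {
      df[[sprintf("Rdiff%g_Vdiff%g", combos$r_diff[ci], combos$v_diff[ci])]] <- cells[ci]
    }
    df
  })
  do.call(rbind, rows)
}
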