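#' Run the full quantification pipeline
#'
#' Orchestrates the stages on an acquisition: blur-free frame selection
#' from each burst, phase-correlation registration and Voronoi-seam mosaic
#' composition per time point, rolling-ball background subtraction with
#' mask-based redirected integrated-density measurement, optimal-assignment
#' tracking across time points, artifact exclusions, and the secretion
#' response summary.
#'
#' @param x An `islet_experiment` (from [generate_experiment()]) or the
#'   list returned by [load_experiment()].
#' @param seg A [seg_params()]; the default uses the in vivo minimum
#'   diameter of 10 um (pass `min_diameter_um = 20` for in vitro wells).
#' @param max_displacement_px,max_log_area_ratio Tracking gates.
#' @param reference_time Reference time point for percent traces; defaults
#'   to the stimulation time (start of the first phase with a positive
#'   release fraction) when a phase schedule is available, else the first
#'   time point.
#' @param end_time End of the analysis window (defaults to reference + 15
#'   min, capped at the last time point).
#' @param search_window_px Registration search half-window.
#' @param time_points Optional subset of time points to process.
#' @param keep_mosaics Keep the stitched mosaics in the result (memory).
#' @return An `islet_pipeline` list: `selection`, `offsets` (per time
#'   point), `mosaics` (if kept), `objects`, `traces`, `summary` (NULL if
#'   no retained traces), `meta`.
#' @export
run_pipeline <- function(x,
                         seg = seg_params(),
                         max_displacement_px = 30,
                         max_log_area_ratio = log(2),
                         reference_time = NULL,
                         end_time = NULL,
                         search_window_px = 16L,
                         time_points = NULL,
                         keep_mosaics = FALSE) {
  if (inherits(x, "islet_experiment")) {
    frames <- x$frames
    meta <- list(
      pixel_size_um = x$config$pixel_size_um,
      bit_depth = x$config$bit_depth,
      tile_grid = x$config$tile_grid,
      tile_shape_px = x$config$tile_shape_px,
      overlap_fraction = x$config$overlap_fraction,
      phase_schedule = x$config$phase_schedule,
      time_points = x$truth$time_points
    )
  } else if (is.list(x) && !is.null(x$manifest) && !is.null(x$frames)) {
    frames <- x$frames
    m <- x$manifest
    meta <- list(
      pixel_size_um = m$pixel_size_um,
      bit_depth = m$bit_depth,
      tile_grid = as.integer(m$tile_grid),
      tile_shape_px = as.integer(m$tile_shape_px),
      overlap_fraction = m$overlap_fraction,
      phase_schedule = m$phase_schedule,
      time_points = m$time_points
    )
  } else {
    stop("x must be an islet_experiment or a load_experiment() result",
         call. = FALSE)
  }
  tps <- if (is.null(time_points)) meta$time_points else time_points
  idx <- frames$index
  idx <- idx[idx$time_point %in% tps, ]

  st <- c(round(meta$tile_shape_px[1] * (1 - meta$overlap_fraction)),
          round(meta$tile_shape_px[2] * (1 - meta$overlap_fraction)))
  n_tiles <- prod(meta$tile_grid)

  # Pass 1: score each burst frame once, keep only the selected frame per
  # (time point, tile), register and compose the mosaic.
  offsets_by_tp <- list()
  mosaics <- vector("list", length(tps))
  sel_rows <- list()
  for (k in seq_along(tps)) {
    tp <- tps[k]
    tiles <- vector("list", n_tiles)
    for (tl in sort(unique(idx$tile[idx$time_point == tp]))) {
      bursts <- sort(idx$burst[idx$time_point == tp & idx$tile == tl])
      fr <- lapply(bursts, function(b) frames$get(tp, tl, b))
      sc <- vapply(fr, focus_score, numeric(1))
      best <- which.max(sc)  # first max = lowest burst index
      sel_rows[[length(sel_rows) + 1]] <- data.frame(
        time_point = tp, tile = tl, burst = bursts,
        focus_score = sc, selected = seq_along(bursts) == best
      )
      tiles[[tl + 1L]] <- fr[[best]]
    }
    if (n_tiles > 1) {
      off <- register_tiles(tiles, meta$tile_grid, st, search_window_px)
    } else {
      off <- data.frame(tile = 0L, tile_row = 0L, tile_col = 0L,
                        row = 0L, col = 0L)
    }
    offsets_by_tp[[as.character(tp)]] <- off
    mosaics[[k]] <- compose_mosaic(tiles, off, time_point = tp)
  }
  selection <- do.call(rbind, sel_rows)
  selection <- flag_low_confidence(selection)

  # Pass 2: segment each mosaic, propagating low-confidence tile flags.
  objects_by_tp <- vector("list", length(tps))
  for (k in seq_along(tps)) {
    tp <- tps[k]
    sel_tp <- selection[selection$selected & selection$time_point == tp, ]
    lc <- setNames(sel_tp$low_confidence, sel_tp$tile)[
      as.character(sort(sel_tp$tile))]
    objects_by_tp[[k]] <- segment_mosaic(mosaics[[k]], seg,
                                         meta$pixel_size_um, meta$bit_depth,
                                         low_confidence = lc)
    if (!keep_mosaics) mosaics[k] <- list(NULL)
  }
  mosaics <- Filter(Negate(is.null), mosaics)

  traces <- build_traces(objects_by_tp, max_displacement_px,
                         max_log_area_ratio)
  traces <- apply_exclusions(traces)

  if (is.null(reference_time)) {
    reference_time <- stimulation_time(meta$phase_schedule, tps)
  }
  summary <- NULL
  if (any(!traces$info$excluded & traces$info$complete) &&
      reference_time %in% tps) {
    summary <- summarize_experiment(traces, reference_time, end_time)
  }
  structure(list(
    selection = selection,
    offsets = offsets_by_tp,
    mosaics = if (keep_mosaics) mosaics else NULL,
    objects = objects_by_tp,
    traces = traces,
    summary = summary,
    meta = meta
  ), class = "islet_pipeline")
}

# Stimulation time: start of the first phase with a positive release
# fraction (t15 for the standard in vitro protocol, t0 in vivo).
stimulation_time <- function(phase_schedule, time_points) {
  if (is.null(phase_schedule) || nrow(phase_schedule) == 0) {
    return(min(time_points))
  }
  starts <- c(0, cumsum(phase_schedule$duration_min))
  hit <- which(phase_schedule$release_fraction > 0)
  if (length(hit) == 0) return(min(time_points))
  starts[hit[1]]
}

#' @export
print.islet_pipeline <- function(x, ...) {
  cat(sprintf("<islet_pipeline> %d time point(s), %d trace(s) (%d retained)\n",
              length(x$objects), nrow(x$traces$info),
              sum(!x$traces$info$excluded & x$traces$info$complete)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
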