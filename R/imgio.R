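#' Write a synthetic experiment to disk
#'
#' Writes every burst frame as a page of a per-(time point, tile) grayscale
#' TIFF (12-bit data in the native 16-bit container convention), an
#' acquisition manifest (JSON) indexing each frame by (time point, tile,
#' burst), and the ground truth (catalog/offsets/flags/content as JSON,
#' label map as TIFF).
#'
#' @param experiment An `islet_experiment` from [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  cfg <- experiment$config
  truth <- experiment$truth
  frames <- experiment$frames
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ground_truth"), showWarnings = FALSE)
  scale <- 2^16 - 1
  idx <- frames$index
  groups <- unique(idx[, c("time_point", "tile")])
  frame_index <- vector("list", nrow(idx))
  k <- 0L
  for (g in seq_len(nrow(groups))) {
    tp <- groups$time_point[g]; tl <- groups$tile[g]
    bursts <- sort(idx$burst[idx$time_point == tp & idx$tile == tl])
    pages <- lapply(bursts, function(b) frames$get(tp, tl, b) / scale)
    fn <- sprintf("frames/t%03d_tile%02d.tif", as.integer(tp), tl)
    tiff::writeTIFF(pages, file.path(dir, fn), bits.per.sample = 16L,
                    compression = "none")
    for (j in seq_along(bursts)) {
      k <- k + 1L
      frame_index[[k]] <- list(time_point = tp, tile = tl,
                               burst = bursts[j], file = fn, page = j)
    }
  }
  manifest <- list(
    format = "isletscope-acquisition",
    pixel_size_um = cfg$pixel_size_um,
    bit_depth = cfg$bit_depth,
    time_points = truth$time_points,
    cadence_min = cfg$cadence_min,
    tile_grid = cfg$tile_grid,
    tile_shape_px = cfg$tile_shape_px,
    overlap_fraction = cfg$overlap_fraction,
    burst_size = cfg$burst_size,
    phase_schedule = cfg$phase_schedule,
    frame_index = frame_index
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  gt <- list(
    catalog = truth$catalog,
    release_fractions = truth$release_fractions,
    content = truth$content,
    id_true = truth$id_true,
    time_points = truth$time_points,
    offsets = truth$offsets,
    blur = truth$blur
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth", "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  tiff::writeTIFF(truth$label_map / scale,
                  file.path(dir, "ground_truth", "label_map.tif"),
                  bits.per.sample = 16L, compression = "none")
  invisible(manifest_path)
}

validate_manifest <- function(m, path) {
  required <- c("pixel_size_um", "bit_depth", "time_points", "tile_grid",
                "tile_shape_px", "overlap_fraction", "burst_size",
                "frame_index")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop("invalid manifest ", path, ": missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fi <- m$frame_index
  need <- c("time_point", "tile", "burst", "file", "page")
  if (nrow(fi) == 0 || !all(need %in% names(fi))) {
    stop("invalid manifest ", path, ": malformed frame_index", call. = FALSE)
  }
  stopifnot(
    "overlap_fraction must be in [0, 1)" =
      m$overlap_fraction >= 0 && m$overlap_fraction < 1,
    "tile_grid must be >= 1x1" = all(m$tile_grid >= 1)
  )
  invisible(m)
}

#' Load an experiment from an acquisition manifest
#'
#' Parses and validates the manifest, and returns it together with a lazy
#' frame accessor.  Frames are read from their TIFF pages on first access;
#' shape and declared bit depth are validated then (a pixel above
#' `2^bit_depth - 1` is a validation error), and a missing file or page is
#' reported with the offending (time point, tile, burst) coordinate.
#'
#' @param manifest_path Path to a manifest JSON.
#' @return List with `manifest` and `frames` (an `islet_frameset`).
#' @export
load_experiment <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  m <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  validate_manifest(m, manifest_path)
  base <- dirname(manifest_path)
  fi <- m$frame_index
  scale <- 2^16 - 1
  cache <- new.env(parent = emptyenv())
  maxval <- 2^m$bit_depth - 1
  shape <- as.integer(m$tile_shape_px)

  get_frame <- function(time_point, tile, burst) {
    row <- which(fi$time_point == time_point & fi$tile == tile &
                   fi$burst == burst)
    if (length(row) != 1) {
      stop(sprintf("no frame indexed at (t=%s, tile=%s, burst=%s)",
                   format(time_point), tile, burst), call. = FALSE)
    }
    path <- file.path(base, fi$file[row])
    if (is.null(cache$path) || cache$path != path) {
      if (!file.exists(path)) {
        stop(sprintf("missing frame file for (t=%s, tile=%s, burst=%s): %s",
                     format(time_point), tile, burst, path), call. = FALSE)
      }
      cache$pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      cache$path <- path
    }
    pg <- fi$page[row]
    if (pg > length(cache$pages)) {
      stop(sprintf("missing frame page for (t=%s, tile=%s, burst=%s): page %d of %s",
                   format(time_point), tile, burst, pg, path), call. = FALSE)
    }
    px <- cache$pages[[pg]]
    if (!all(dim(px) == shape)) {
      stop(sprintf("frame shape %dx%d differs from manifest %dx%d at (t=%s, tile=%s, burst=%s)",
                   nrow(px), ncol(px), shape[1], shape[2],
                   format(time_point), tile, burst), call. = FALSE)
    }
    if (max(px) > maxval) {
      stop(sprintf("pixel value %d exceeds declared %d-bit range at (t=%s, tile=%s, burst=%s)",
                   max(px), m$bit_depth, format(time_point), tile, burst),
           call. = FALSE)
    }
    storage.mode(px) <- "integer"
    px
  }

  index <- fi[order(fi$time_point, fi$tile, fi$burst),
              c("time_point", "tile", "burst")]
  rownames(index) <- NULL
  frames <- structure(list(index = index, get = get_frame),
                      class = "islet_frameset")
  list(manifest = m, frames = frames)
}

#' Write trace and summary results as flat files
#'
#' Writes the per-islet trace table as CSV (stable column order; rows
#' sorted by islet id then time point) and the experiment summary as JSON.
#' Outputs are deterministic — no timestamps — so identical inputs
#' re-create identical files.
#'
#' @param traces An `islet_traces` object (possibly after
#'   [apply_exclusions()]).
#' @param summary A `gsis_summary`, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param pixel_size_um Recorded in the summary JSON for provenance.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(traces, summary = NULL, out_dir,
                          pixel_size_um = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- traces$objects
  cols <- c("islet_id", "time_point", "area_px", "area_um2",
            "integrated_density", "percent_of_reference", "edge_proximal",
            "saturated", "low_confidence_frame", "excluded", "reason")
  if (nrow(obj) > 0) {
    tab <- obj
    tab$percent_of_reference <- NA_real_
    if (!is.null(summary)) {
      key <- paste(summary$percent_traces$islet_id,
                   summary$percent_traces$time_point)
      hit <- match(paste(tab$islet_id, tab$time_point), key)
      tab$percent_of_reference <- summary$percent_traces$percent[hit]
    }
    info_m <- match(tab$islet_id, traces$info$islet_id)
    tab$excluded <- traces$info$excluded[info_m]
    tab$reason <- traces$info$reason[info_m]
    tab <- tab[order(tab$islet_id, tab$time_point), cols]
  } else {
    tab <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  }
  trace_path <- file.path(out_dir, "traces.csv")
  write.csv(tab, trace_path, row.names = FALSE, quote = FALSE)

  files <- c(traces = trace_path)
  summary_path <- file.path(out_dir, "summary.json")
  excl <- attr(traces, "exclusion_counts")
  out <- list(
    n_traces = nrow(traces$info),
    n_complete = sum(traces$info$complete),
    n_excluded = sum(traces$info$excluded),
    exclusion_counts = as.list(excl %||% integer(0)),
    pixel_size_um = pixel_size_um
  )
  if (!is.null(summary)) {
    out <- c(out, list(
      reference_time = summary$reference_time,
      end_time = summary$end_time,
      n_islets = summary$n_islets,
      total_response_percent = summary$total_response_percent,
      heterogeneity_sem = summary$heterogeneity_sem,
      per_islet = summary$per_islet
    ))
  }
  jsonlite::write_json(out, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files["summary"] <- summary_path
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a trace table written by [write_results()]
#'
#' @param path Path to a `traces.csv`.
#' @return Data frame with the written columns and types.
#' @export
read_trace_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
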