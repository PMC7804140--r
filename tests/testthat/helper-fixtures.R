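# Small in-code fixtures shared across test files.

# A tiny single-field configuration that runs in well under a second.
tiny_config <- function(n_islets = 3L, seed = 1L, ...) {
  args <- list(
    tile_grid = c(1L, 1L),
    tile_shape_px = c(192L, 224L),
    burst_size = 1L,
    n_islets = as.integer(n_islets),
    diameters_um = if (n_islets > 0) rep(16, n_islets) else NULL,
    diameter_range_um = c(5, 60),
    phase_schedule = data.frame(phase = c("low", "high"),
                                duration_min = c(5, 10),
                                release_fraction = c(0, 0.1)),
    min_separation_px = 20,
    edge_placement_margin_px = 22,
    rng_seed = as.integer(seed)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# Draw a disk of the given value on a matrix (binary coverage).
draw_disk <- function(img, cy, cx, r, value, add = FALSE) {
  d2 <- outer((seq_len(nrow(img)) - cy)^2, (seq_len(ncol(img)) - cx)^2, "+")
  sel <- d2 <= r^2
  if (add) img[sel] <- img[sel] + value else img[sel] <- value
  img
}

# A textured pseudo-tissue image for registration tests: smooth field plus
# fine-grained static noise, values in a 12-bit-like range.
textured_image <- function(nr, nc, seed = 1) {
  set.seed(seed)
  sm <- matrix(rnorm(ceiling(nr / 8) * ceiling(nc / 8)),
               ceiling(nr / 8), ceiling(nc / 8))
  big <- sm[rep(seq_len(nrow(sm)), each = 8)[seq_len(nr)],
            rep(seq_len(ncol(sm)), each = 8)[seq_len(nc)]]
  img <- 200 + 50 * big + matrix(rnorm(nr * nc, 0, 20), nr, nc)
  m <- round(pmin(pmax(img, 0), 4095))
  storage.mode(m) <- "integer"
  m
}

# Minimal hand-built islet_traces object from a long table of
# (islet_id, time_point, area_px, integrated_density).
manual_traces <- function(tab, n_time_points = length(unique(tab$time_point))) {
  obj <- data.frame(
    label = seq_len(nrow(tab)),
    row = tab$row %||% 0, col = tab$col %||% 0,
    area_px = tab$area_px,
    area_um2 = tab$area_px * 0.54^2,
    integrated_density = tab$integrated_density,
    bbox_rmin = 0L, bbox_rmax = 1L, bbox_cmin = 0L, bbox_cmax = 1L,
    edge_proximal = FALSE, saturated = FALSE,
    low_confidence_frame = FALSE,
    time_point = tab$time_point,
    islet_id = tab$islet_id
  )
  ids <- sort(unique(tab$islet_id))
  counts <- vapply(ids, function(i) sum(tab$islet_id == i), integer(1))
  info <- data.frame(
    islet_id = ids,
    first_time_point = vapply(ids, function(i) min(tab$time_point[tab$islet_id == i]), numeric(1)),
    n_points = counts,
    merge_suspect = FALSE,
    complete = counts == n_time_points,
    excluded = FALSE,
    reason = NA_character_
  )
  structure(list(objects = obj, info = info, n_time_points = n_time_points,
                 time_points = sort(unique(tab$time_point))),
            class = "islet_traces")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
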