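#' Register a pair of overlapping tiles by phase correlation
#'
#' Finds the integer translation of `moving` relative to `fixed` that
#' maximizes the phase correlation of their nominal overlap regions, within
#' `nominal_offset` plus/minus `search_window_px`.  Ties are broken by
#' distance to the nominal offset, then row-major candidate order.
#'
#' @param fixed,moving 2-D matrices (same bit-depth contract as frames).
#' @param nominal_offset Integer `c(row, col)`: expected position of
#'   `moving`'s origin in `fixed`'s coordinates (e.g. `c(0, step)` for a
#'   right-hand neighbor at the configured overlap).
#' @param search_window_px Half-width of the search window around the
#'   nominal offset.
#' @param min_overlap_px Minimum overlap extent in each dimension.
#' @return Integer vector `c(row, col)`: the registered offset.
#' @export
register_pair <- function(fixed, moving, nominal_offset,
                          search_window_px = 16L, min_overlap_px = 16L) {
  dr <- as.integer(round(nominal_offset[1]))
  dc <- as.integer(round(nominal_offset[2]))
  hf <- nrow(fixed); wf <- ncol(fixed)
  hm <- nrow(moving); wm <- ncol(moving)

  w <- as.integer(search_window_px)
  fr <- (max(0L, dr) + 1L):(min(hf, hm + dr))
  fc <- (max(0L, dc) + 1L):(min(wf, wm + dc))
  if (length(fr) < min_overlap_px || length(fc) < min_overlap_px ||
      fr[1] > fr[length(fr)] || fc[1] > fc[length(fc)]) {
    stop(sprintf("overlap region smaller than %d px at the nominal offset",
                 min_overlap_px), call. = FALSE)
  }
  # Extend the fixed-side strip by the search window (clamped to the tile)
  # so that for every candidate shift the moving-side strip is a fully
  # contained copy: the correlation peak is then an exact delta rather
  # than being eroded by non-cyclic edge mismatch.
  fr_ext <- max(1L, fr[1] - w):min(hf, fr[length(fr)] + w)
  fc_ext <- max(1L, fc[1] - w):min(wf, fc[length(fc)] + w)
  A <- fixed[fr_ext, fc_ext]; storage.mode(A) <- "double"
  B <- moving[fr - dr, fc - dc]; storage.mode(B) <- "double"
  A <- A - mean(A)
  Bp <- matrix(0, nrow(A), ncol(A))
  off_b <- c(fr[1] - fr_ext[1], fc[1] - fc_ext[1])
  Bp[off_b[1] + seq_len(nrow(B)), off_b[2] + seq_len(ncol(B))] <- B - mean(B)

  # Phase correlation: with Bp(v) = A(v + eps), the cross-power spectrum
  # F_A * conj(F_Bp) carries phase exp(-2*pi*i*k*eps/N); its inverse
  # transform peaks at index eps mod N.
  FA <- stats::fft(A)
  FB <- stats::fft(Bp)
  R <- FA * Conj(FB)
  r <- Re(stats::fft(R / (Mod(R) + 1e-12), inverse = TRUE))
  N1 <- nrow(r); N2 <- ncol(r)

  cand <- expand.grid(eps_c = -w:w, eps_r = -w:w)[, 2:1]  # row-major order
  i1 <- (cand$eps_r %% N1) + 1L
  i2 <- (cand$eps_c %% N2) + 1L
  score <- r[cbind(i1, i2)]
  ord <- order(-score, cand$eps_r^2 + cand$eps_c^2, seq_len(nrow(cand)))
  best <- cand[ord[1], ]
  c(row = dr + best$eps_r, col = dc + best$eps_c)
}

#' Register all tiles of one time point against the grid topology
#'
#' Pairwise phase-correlation registrations of each tile against its left
#' (or, for the first column, top) neighbor, chained from the anchor tile
#' (0,0) along a spanning tree of the grid.  With half a dozen tiles a
#' global least-squares refinement adds nothing.
#'
#' @param tiles List of tile matrices in row-major tile order (tile 0
#'   first).
#' @param tile_grid `c(rows, cols)`.
#' @param nominal_step Integer `c(row_step, col_step)` between adjacent tile
#'   origins (tile extent times one minus the overlap fraction).
#' @param search_window_px Passed to [register_pair()].
#' @return Data frame `tile`, `tile_row`, `tile_col`, `row`, `col` with
#'   integer offsets relative to tile 0.
#' @export
register_tiles <- function(tiles, tile_grid, nominal_step,
                           search_window_px = 16L) {
  rows <- tile_grid[1]; cols <- tile_grid[2]
  stopifnot(length(tiles) == rows * cols)
  pos <- matrix(NA_integer_, rows * cols, 2)
  pos[1, ] <- c(0L, 0L)
  tid <- function(r, c) (r - 1L) * cols + c  # 1-based row-major
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (r == 1 && c == 1) next
      if (c > 1) {
        ref <- tid(r, c - 1L)
        rel <- register_pair(tiles[[ref]], tiles[[tid(r, c)]],
                             c(0L, nominal_step[2]), search_window_px)
      } else {
        ref <- tid(r - 1L, c)
        rel <- register_pair(tiles[[ref]], tiles[[tid(r, c)]],
                             c(nominal_step[1], 0L), search_window_px)
      }
      pos[tid(r, c), ] <- pos[ref, ] + rel
    }
  }
  grid <- expand.grid(tile_col = 0:(cols - 1), tile_row = 0:(rows - 1))[, 2:1]
  data.frame(
    tile = 0:(rows * cols - 1),
    tile_row = grid$tile_row,
    tile_col = grid$tile_col,
    row = pos[, 1],
    col = pos[, 2]
  )
}

#' Compose a mosaic from registered tiles
#'
#' Places each tile at its registered offset and resolves every overlap
#' pixel by the Voronoi seam rule: the pixel is copied verbatim from the
#' tile whose center is nearest.  No intensity is rescaled or blended, so
#' integrated densities measured on the mosaic are sums of raw camera
#' values.
#'
#' @param tiles List of tile matrices in row-major tile order.
#' @param offsets Data frame from [register_tiles()] (columns `tile`,
#'   `row`, `col`; optional `tile_row`/`tile_col` used for sanity checks).
#' @param time_point Time point annotation carried on the mosaic.
#' @return An `islet_mosaic`: list with `pixels` (integer matrix),
#'   `tile_offsets` (offsets normalized to a zero-based canvas),
#'   `seam_map` (integer matrix of source-tile ids + 1, 0 = uncovered),
#'   `time_point`.
#' @export
compose_mosaic <- function(tiles, offsets, time_point = NA_real_) {
  stopifnot(length(tiles) == nrow(offsets))
  offsets <- offsets[order(offsets$tile), ]
  if (length(tiles) == 1) {
    off_out <- data.frame(tile = offsets$tile, row = 0L, col = 0L)
    if (all(c("tile_row", "tile_col") %in% names(offsets))) {
      off_out$tile_row <- offsets$tile_row
      off_out$tile_col <- offsets$tile_col
    }
    return(structure(list(
      pixels = tiles[[1]], tile_offsets = off_out,
      seam_map = matrix(1L, nrow(tiles[[1]]), ncol(tiles[[1]])),
      time_point = time_point
    ), class = "islet_mosaic"))
  }
  hs <- vapply(tiles, nrow, integer(1))
  ws <- vapply(tiles, ncol, integer(1))
  if (all(c("tile_row", "tile_col") %in% names(offsets)) && nrow(offsets) > 1) {
    for (i in seq_len(nrow(offsets))) {
      nb <- which(offsets$tile_row == offsets$tile_row[i] &
                    offsets$tile_col == offsets$tile_col[i] - 1)
      if (length(nb) == 1 && offsets$col[i] - offsets$col[nb] >= ws[nb]) {
        stop("inconsistent offsets: horizontal neighbors do not overlap",
             call. = FALSE)
      }
      nb <- which(offsets$tile_col == offsets$tile_col[i] &
                    offsets$tile_row == offsets$tile_row[i] - 1)
      if (length(nb) == 1 && offsets$row[i] - offsets$row[nb] >= hs[nb]) {
        stop("inconsistent offsets: vertical neighbors do not overlap",
             call. = FALSE)
      }
    }
  }
  r0 <- offsets$row - min(offsets$row)
  c0 <- offsets$col - min(offsets$col)
  H <- max(r0 + hs); W <- max(c0 + ws)
  canvas <- matrix(0L, H, W)
  seam <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  for (i in seq_along(tiles)) {
    rr <- (r0[i] + 1):(r0[i] + hs[i])
    cc <- (c0[i] + 1):(c0[i] + ws[i])
    ctr_r <- r0[i] + (hs[i] + 1) / 2
    ctr_c <- c0[i] + (ws[i] + 1) / 2
    d2 <- outer((rr - ctr_r)^2, (cc - ctr_c)^2, "+")
    sel <- d2 < bestd[rr, cc]
    sub <- canvas[rr, cc]; sub[sel] <- tiles[[i]][sel]
    canvas[rr, cc] <- sub
    ssub <- seam[rr, cc]; ssub[sel] <- i
    seam[rr, cc] <- ssub
    dsub <- bestd[rr, cc]; dsub[sel] <- d2[sel]
    bestd[rr, cc] <- dsub
  }
  off_out <- data.frame(tile = offsets$tile, row = r0, col = c0)
  if (all(c("tile_row", "tile_col") %in% names(offsets))) {
    off_out$tile_row <- offsets$tile_row
    off_out$tile_col <- offsets$tile_col
  }
  structure(list(pixels = canvas, tile_offsets = off_out, seam_map = seam,
                 time_point = time_point),
            class = "islet_mosaic")
}

#' @export
print.islet_mosaic <- function(x, ...) {
  cat(sprintf("<islet_mosaic> %dx%d px, %d tile(s), t = %s min\n",
              nrow(x$pixels), ncol(x$pixels), nrow(x$tile_offsets),
              format(x$time_point)))
  invisible(x)
}
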