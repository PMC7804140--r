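#' Focus score of a frame (variance of the Laplacian)
#'
#' Sharpness metric used to reject motion-blurred burst frames: the variance
#' of the 3x3 Laplacian-filtered raster.  Higher is sharper.  The score is
#' invariant to an additive intensity offset (the Laplacian of a constant is
#' zero) and monotonically degraded by motion blur, which removes the
#' high-frequency structure the Laplacian responds to.
#'
#' @param frame 2-D numeric or integer matrix, at least 3x3.
#' @return Non-negative scalar.
#' @export
focus_score <- function(frame) {
  if (!is.matrix(frame)) stop("frame must be a 2-D matrix", call. = FALSE)
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < 3 || nc < 3) {
    stop("frame smaller than the 3x3 Laplacian kernel", call. = FALSE)
  }
  x <- frame
  storage.mode(x) <- "double"
  ctr <- x[2:(nr - 1), 2:(nc - 1)]
  lap <- x[1:(nr - 2), 2:(nc - 1)] + x[3:nr, 2:(nc - 1)] +
    x[2:(nr - 1), 1:(nc - 2)] + x[2:(nr - 1), 3:nc] - 4 * ctr
  v <- sum((lap - mean(lap))^2) / length(lap)
  v
}

#' Select one blur-free frame per field and time point
#'
#' For every (time point, tile) burst, scores each frame with
#' [focus_score()] and selects the frame with the maximal score; ties are
#' broken by the lowest burst index.  A selection is flagged
#' `low_confidence` when its score falls below half the median best-score of
#' the same tile across time points — the signature of a burst in which
#' every frame is motion-blurred.  Such frames are still selected (artifact
#' objects, not whole time points, are discarded downstream).
#'
#' @param frames An `islet_frameset` (from [generate_experiment()] or
#'   [load_experiment()]), or a list of lists with elements `pixels`,
#'   `time_point`, `tile`, `burst`.
#' @return Data frame with one row per frame: `time_point`, `tile`, `burst`,
#'   `focus_score`, `selected`, `low_confidence` (exactly one selected row
#'   per (time point, tile)).
#' @export
select_frames <- function(frames) {
  if (inherits(frames, "islet_frameset")) {
    idx <- frames$index
    scores <- vapply(seq_len(nrow(idx)), function(i) {
      focus_score(frames$get(idx$time_point[i], idx$tile[i], idx$burst[i]))
    }, numeric(1))
  } else if (is.list(frames) && length(frames) > 0) {
    idx <- do.call(rbind, lapply(frames, function(f) {
      data.frame(time_point = f$time_point, tile = f$tile, burst = f$burst)
    }))
    scores <- vapply(frames, function(f) focus_score(f$pixels), numeric(1))
  } else {
    stop("empty burst collection", call. = FALSE)
  }
  tab <- cbind(idx, focus_score = scores)
  tab <- tab[order(tab$time_point, tab$tile, tab$burst), ]
  rownames(tab) <- NULL

  key <- paste(tab$time_point, tab$tile)
  tab$selected <- FALSE
  for (k in unique(key)) {
    rows <- which(key == k)
    best <- rows[which.max(tab$focus_score[rows])]  # first max = lowest burst
    tab$selected[best] <- TRUE
  }

  flag_low_confidence(tab)
}

# Flag selected frames whose score falls below half the median best-score
# of the same tile across time points (all-blurred-burst signature).
flag_low_confidence <- function(tab) {
  tab$low_confidence <- FALSE
  sel <- tab[tab$selected, ]
  for (tl in unique(sel$tile)) {
    rows <- which(sel$tile == tl)
    ref <- median(sel$focus_score[rows])
    lc <- sel$focus_score[rows] < 0.5 * ref
    tab$low_confidence[tab$selected & tab$tile == tl] <- lc
  }
  tab
}

# Selected frame pixels per tile for one time point, as a named list.
selected_frames_for <- function(frames, selection, time_point) {
  sel <- selection[selection$selected & selection$time_point == time_point, ]
  sel <- sel[order(sel$tile), ]
  out <- lapply(seq_len(nrow(sel)), function(i) {
    frames$get(sel$time_point[i], sel$tile[i], sel$burst[i])
  })
  names(out) <- sel$tile
  attr(out, "low_confidence") <- setNames(sel$low_confidence, sel$tile)
  out
}
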