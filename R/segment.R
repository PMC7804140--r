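#' Segmentation parameters
#'
#' @param rolling_ball_radius_px Radius of the rolling-ball structuring
#'   element for background estimation; must exceed the largest expected
#'   islet radius in pixels (default 200).
#' @param threshold_method `"otsu"` (Otsu's threshold computed on the
#'   log-transformed background-subtracted image, floored at a robust
#'   background level of median + 6 MAD) or `"fixed"`.
#' @param threshold_value Threshold in intensity units when
#'   `threshold_method = "fixed"`.
#' @param min_diameter_um Smallest islet diameter to keep (default 10 for
#'   in vivo mosaics; use 20 for in vitro wells).  Regions smaller than
#'   `round(pi * (min_diameter_um / 2 / pixel_size_um)^2)` pixels are
#'   removed.
#' @param edge_margin_px Objects whose bounding box comes within this many
#'   pixels of the image border are flagged `edge_proximal`.
#' @param fill_holes Fill holes in the mask before labeling.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(rolling_ball_radius_px = 200,
                       threshold_method = c("otsu", "fixed"),
                       threshold_value = NULL,
                       min_diameter_um = 10,
                       edge_margin_px = 20,
                       fill_holes = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(threshold_value)) {
    stop("threshold_value required for fixed thresholding", call. = FALSE)
  }
  stopifnot(rolling_ball_radius_px >= 1, min_diameter_um > 0,
            edge_margin_px >= 0)
  structure(list(
    rolling_ball_radius_px = rolling_ball_radius_px,
    threshold_method = threshold_method,
    threshold_value = threshold_value,
    min_diameter_um = min_diameter_um,
    edge_margin_px = edge_margin_px,
    fill_holes = isTRUE(fill_holes)
  ), class = "seg_params")
}

min_area_px <- function(min_diameter_um, pixel_size_um) {
  round(pi * (min_diameter_um / 2 / pixel_size_um)^2)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale morphological opening of
#' the image by a disc structuring element of the given radius and
#' subtracts it, flooring at zero.  Any feature narrower than the disc is
#' removed from the background estimate, so islets (provided the radius
#' exceeds theirs) survive subtraction intact.  For large radii the opening
#' is computed on a block-minimum-shrunken copy and re-expanded by bilinear
#' interpolation (the standard large-radius strategy), then clipped to
#' never exceed the image.
#'
#' @param image 2-D numeric/integer matrix.
#' @param radius_px Structuring-element radius in pixels.
#' @return List with `background` and `corrected` (both matrices;
#'   `corrected = pmax(image - background, 0)`).
#' @export
subtract_background <- function(image, radius_px) {
  stopifnot(radius_px >= 1)
  if (radius_px >= min(dim(image))) {
    stop("rolling-ball radius larger than the image", call. = FALSE)
  }
  x <- image
  storage.mode(x) <- "double"
  shrink <- max(1L, floor(radius_px / 32))
  if (shrink > 1L) {
    sm <- block_min(x, shrink)
    r2 <- max(1L, round(radius_px / shrink))
    bg <- padded_opening(sm, r2)
    bg <- bilinear_resize(bg, nrow(x), ncol(x))
    bg <- pmin(bg, x)
  } else {
    bg <- padded_opening(x, round(radius_px))
  }
  list(background = bg, corrected = pmax(x - bg, 0))
}

# Grayscale opening by a flat disc, with edge-replication padding so the
# background estimate is unbiased at the borders.  EBImage's grayscale
# morphology operates on [0, 1] intensities, so values are scaled by a
# power of two (exact in binary floating point) and scaled back.
padded_opening <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  padded <- x[ri, ci]
  mx <- max(padded)
  s <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  op <- as.matrix(EBImage::opening(padded / s,
                                   EBImage::makeBrush(2L * r + 1L,
                                                      shape = "disc"))) * s
  op[r + seq_len(nr), r + seq_len(nc)]
}

# Block minimum over sxs blocks (edge blocks padded by replication).
block_min <- function(x, s) {
  nr <- nrow(x); nc <- ncol(x)
  nr2 <- ceiling(nr / s); nc2 <- ceiling(nc / s)
  xp <- x[pmin(seq_len(nr2 * s), nr), pmin(seq_len(nc2 * s), nc)]
  # min over row blocks, then col blocks
  m1 <- matrix(NA_real_, nr2, ncol(xp))
  for (b in seq_len(s)) {
    rows <- pmin((seq_len(nr2) - 1L) * s + b, nr2 * s)
    m1 <- if (b == 1) xp[rows, , drop = FALSE] else pmin(m1, xp[rows, , drop = FALSE])
  }
  m2 <- matrix(NA_real_, nr2, nc2)
  for (b in seq_len(s)) {
    cols <- pmin((seq_len(nc2) - 1L) * s + b, nc2 * s)
    m2 <- if (b == 1) m1[, cols, drop = FALSE] else pmin(m2, m1[, cols, drop = FALSE])
  }
  m2
}

# Threshold on the corrected image.  Otsu is computed on log1p intensities
# (the foreground spans a wide dynamic range from depth attenuation, which
# defeats Otsu on a linear scale) and floored at median + 6 MAD of the
# corrected image so that near-empty fields do not threshold inside the
# background noise.
segmentation_threshold <- function(corrected, params, max_value) {
  if (params$threshold_method == "fixed") return(params$threshold_value)
  if (diff(range(corrected)) < .Machine$double.eps) return(Inf)
  lmax <- log1p(max_value)
  th_log <- EBImage::otsu(EBImage::Image(log1p(corrected) / lmax),
                          range = c(0, 1), levels = 4096)
  th <- expm1(th_log * lmax)
  floor_bg <- median(corrected) + 6 * mad(corrected)
  max(th, floor_bg)
}

#' Build a binary islet mask from a background-subtracted image
#'
#' Thresholds the corrected image, optionally fills holes, and removes
#' 8-connected regions smaller than the minimum islet area implied by
#' `min_diameter_um`.  A degenerate (constant) image yields an empty mask
#' with attribute `no_foreground = TRUE` rather than an error.
#'
#' @param corrected Non-negative 2-D matrix (from [subtract_background()]).
#' @param params A [seg_params()].
#' @param pixel_size_um Pixel size, micrometers.
#' @param max_value Intensity ceiling used to scale the Otsu histogram
#'   (default 4095 for 12-bit data).
#' @return Logical matrix; attribute `threshold` records the value used.
#' @export
make_mask <- function(corrected, params, pixel_size_um, max_value = 4095) {
  stopifnot(all(corrected >= 0))
  th <- segmentation_threshold(corrected, params, max_value)
  if (!is.finite(th)) {
    mask <- matrix(FALSE, nrow(corrected), ncol(corrected))
    attr(mask, "no_foreground") <- TRUE
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  mask <- corrected > th
  if (params$fill_holes) {
    mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  }
  lab <- label_components(mask)
  K <- max(lab)
  if (K > 0) {
    areas <- tabulate(lab[lab > 0], nbins = K)
    keepv <- areas >= min_area_px(params$min_diameter_um, pixel_size_um)
    lut <- integer(K + 1L)
    lut[which(keepv) + 1L] <- seq_len(sum(keepv))
    lab <- matrix(lut[lab + 1L], nrow(mask), ncol(mask))
    mask <- lab > 0
  }
  attr(mask, "labels") <- lab   # compact 8-connected labels, reusable
  attr(mask, "threshold") <- th
  mask
}

# 8-connected labeling: EBImage's bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass (over foreground
# pixels only) and relabeled compactly in raster order of first occurrence.
label_components <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  K <- max(lab)
  if (K == 0) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  nz <- which(lab > 0)
  r <- (nz - 1L) %% nr
  cl <- (nz - 1L) %/% nr
  pairs <- NULL
  for (step in c(nr + 1L, nr - 1L)) {  # down-right and up-right diagonals
    ok <- if (step == nr + 1L) r < nr - 1L & cl < nc - 1L else r > 0L & cl < nc - 1L
    nb <- nz[ok] + step
    lv <- lab[nz[ok]]; lnb <- lab[nb]
    hit <- lnb > 0L & lnb != lv
    if (any(hit)) pairs <- rbind(pairs, cbind(lv[hit], lnb[hit]))
  }
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (!is.null(pairs)) {
    pairs <- unique(pairs)
    for (j in seq_len(nrow(pairs))) {
      ra <- find(pairs[j, 1]); rb <- find(pairs[j, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(K), find, integer(1))
  # compact relabel by raster (row-major) order of first appearance
  ord <- order(r, cl)
  rl <- root[lab[nz[ord]]]
  ord_roots <- rl[!duplicated(rl)]
  newid <- integer(K)
  newid[ord_roots] <- seq_along(ord_roots)
  lab[nz] <- newid[root[lab[nz]]]
  lab
}

#' Measure islet objects: integrated density on the unaltered image
#'
#' Labels the mask (8-connectivity) and measures each connected region on
#' the original, un-background-subtracted image: the integrated density is
#' the exact integer sum of raw pixel values under the mask ("redirected"
#' measurement), so the mask delineates regions but never alters
#' intensities.
#'
#' @param mask Logical matrix (from [make_mask()]), or an integer label
#'   matrix.
#' @param image Original unaltered image, same shape.
#' @param params A [seg_params()].
#' @param pixel_size_um Pixel size, micrometers.
#' @param bit_depth Bit depth used for the saturation flag (default 12).
#' @param low_confidence Logical: the source frame(s) carried a
#'   low-confidence (all-blurred burst) flag.
#' @return Data frame with one row per object: `label`, `row`, `col`
#'   (0-based centroid), `area_px`, `area_um2`, `integrated_density`,
#'   `bbox_*`, `edge_proximal`, `saturated`, `low_confidence_frame`.
#' @export
measure_objects <- function(mask, image, params, pixel_size_um,
                            bit_depth = 12L, low_confidence = FALSE) {
  if (!all(dim(mask) == dim(image))) {
    stop("mask and image shapes differ", call. = FALSE)
  }
  lab <- if (!is.null(attr(mask, "labels"))) {
    attr(mask, "labels")
  } else if (is.logical(mask) || all(mask %in% c(0, 1))) {
    label_components(mask > 0)
  } else {
    m <- mask; storage.mode(m) <- "integer"; m
  }
  K <- max(lab)
  empty <- data.frame(
    label = integer(0), row = numeric(0), col = numeric(0),
    area_px = integer(0), area_um2 = numeric(0),
    integrated_density = numeric(0),
    bbox_rmin = integer(0), bbox_rmax = integer(0),
    bbox_cmin = integer(0), bbox_cmax = integer(0),
    edge_proximal = logical(0), saturated = logical(0),
    low_confidence_frame = logical(0)
  )
  if (K == 0) return(empty)
  nz <- which(lab > 0)
  l <- lab[nz]
  rows0 <- (nz - 1L) %% nrow(lab)        # 0-based
  cols0 <- (nz - 1L) %/% nrow(lab)
  vals <- as.numeric(image[nz])
  area <- tabulate(l, nbins = K)
  id <- rowsum(vals, l)[, 1]
  cr <- rowsum(rows0, l)[, 1] / area
  cc <- rowsum(cols0, l)[, 1] / area
  groups <- split(seq_along(l), l)
  rmin <- vapply(groups, function(g) min(rows0[g]), numeric(1))
  rmax <- vapply(groups, function(g) max(rows0[g]), numeric(1))
  cmin <- vapply(groups, function(g) min(cols0[g]), numeric(1))
  cmax <- vapply(groups, function(g) max(cols0[g]), numeric(1))
  satv <- 2^bit_depth - 1
  sat <- rowsum(as.numeric(image[nz] >= satv), l)[, 1] > 0
  m <- params$edge_margin_px
  edge <- rmin < m | cmin < m |
    rmax >= nrow(lab) - m | cmax >= ncol(lab) - m
  out <- data.frame(
    label = seq_len(K),
    row = cr, col = cc,
    area_px = area,
    area_um2 = area * pixel_size_um^2,
    integrated_density = id,
    bbox_rmin = as.integer(rmin), bbox_rmax = as.integer(rmax),
    bbox_cmin = as.integer(cmin), bbox_cmax = as.integer(cmax),
    edge_proximal = as.logical(edge),
    saturated = as.logical(sat),
    low_confidence_frame = rep(isTRUE(low_confidence), K)
  )
  rownames(out) <- NULL
  out
}

#' Segment a mosaic (or single-field image) at one time point
#'
#' Convenience wrapper: rolling-ball background subtraction, masking, and
#' redirected measurement on the unaltered input.
#'
#' @param mosaic An `islet_mosaic` or a plain matrix.
#' @param params A [seg_params()].
#' @param pixel_size_um Pixel size, micrometers.
#' @param bit_depth Bit depth for the saturation flag.
#' @param low_confidence Per-tile low-confidence flags (named by tile id) or
#'   a single logical; objects inherit the flag of any tile they touch.
#' @return Data frame of objects (see [measure_objects()]) with a
#'   `time_point` column.
#' @export
segment_mosaic <- function(mosaic, params, pixel_size_um, bit_depth = 12L,
                           low_confidence = FALSE) {
  img <- if (inherits(mosaic, "islet_mosaic")) mosaic$pixels else mosaic
  tp <- if (inherits(mosaic, "islet_mosaic")) mosaic$time_point else NA_real_
  bgc <- subtract_background(img, params$rolling_ball_radius_px)
  mask <- make_mask(bgc$corrected, params, pixel_size_um,
                    max_value = 2^bit_depth - 1)
  obj <- measure_objects(mask, img, params, pixel_size_um, bit_depth)
  lc <- unname(low_confidence)
  if (nrow(obj) > 0 && any(lc)) {
    if (inherits(mosaic, "islet_mosaic") && length(lc) > 1) {
      # objects inherit the flag of any source tile they touch
      lab <- attr(mask, "labels") %||% label_components(mask > 0)
      seam <- mosaic$seam_map
      for (i in seq_len(nrow(obj))) {
        tiles_touched <- unique(seam[lab == obj$label[i]])
        tiles_touched <- tiles_touched[tiles_touched > 0]
        obj$low_confidence_frame[i] <- any(lc[tiles_touched])
      }
    } else {
      obj$low_confidence_frame <- TRUE
    }
  }
  if (nrow(obj) > 0) obj$time_point <- tp
  else obj$time_point <- numeric(0)
  obj
}
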