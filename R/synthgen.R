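#' @import EBImage
#' @importFrom stats rnorm runif rlnorm rbeta median mad sd var cor.test
#'   shapiro.test t.test wilcox.test setNames complete.cases
#' @importFrom utils write.csv read.csv head
NULL

# Run code with a private RNG stream, restoring the caller's stream after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-frame seed, independent of frame access order.
frame_seed <- function(base_seed, tp_index, tile, burst, burst_size, n_tiles) {
  k <- ((tp_index - 1) * n_tiles + tile) * burst_size + burst
  as.integer((as.numeric(base_seed) * 1000003 + k * 7919) %% 2147483629L) + 1L
}

# Nominal tile origin steps (px) for the configured overlap.
tile_steps <- function(cfg) {
  c(
    round(cfg$tile_shape_px[1] * (1 - cfg$overlap_fraction)),
    round(cfg$tile_shape_px[2] * (1 - cfg$overlap_fraction))
  )
}

# Nominal mosaic extent (px) covered by the tile grid.
mosaic_shape <- function(cfg) {
  st <- tile_steps(cfg)
  c(
    cfg$tile_shape_px[1] + (cfg$tile_grid[1] - 1) * st[1],
    cfg$tile_shape_px[2] + (cfg$tile_grid[2] - 1) * st[2]
  )
}

SCENE_PAD <- 16L   # scene margin absorbing jitter and blur-kernel support
BLUR_MARGIN <- 8L  # extra crop margin when convolving a blurred frame

# Smooth random field: Gaussian-filtered white noise standardized to zero
# mean / unit SD.  Filtering white noise (rather than interpolating a
# coarse grid) leaves no lattice structure that tile registration could
# spuriously lock onto.
smooth_field <- function(nr, nc, scale_px) {
  white <- matrix(rnorm(nr * nc), nr, nc)
  # gblur's kernel (2 * ceiling(3 * sigma) + 1 wide) must fit in the image
  sigma <- max(min(scale_px / 2, (min(nr, nc) - 3) / 6), 1)
  f <- as.matrix(EBImage::gblur(white, sigma = sigma))
  (f - mean(f)) / max(sd(f), 1e-12)
}

# Bilinear resize of a matrix to nr x nc (used for background fields and for
# re-expanding shrunken rolling-ball backgrounds).  Separable: interpolate
# rows on the small matrix, then columns (transposed so the weight vector
# recycles down columns).
bilinear_resize <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  y <- if (nr == 1) 1 else seq(1, sr, length.out = nr)
  x <- if (nc == 1) 1 else seq(1, sc, length.out = nc)
  y0 <- pmin(floor(y), max(sr - 1L, 1L)); x0 <- pmin(floor(x), max(sc - 1L, 1L))
  wy <- y - y0; wx <- x - x0
  y1 <- pmin(y0 + 1L, sr); x1 <- pmin(x0 + 1L, sc)
  mr <- m[y0, , drop = FALSE] * (1 - wy) + m[y1, , drop = FALSE] * wy
  tm <- t(mr)
  t(tm[x0, , drop = FALSE] * (1 - wx) + tm[x1, , drop = FALSE] * wx)
}

# Anti-aliased disk coverage within a bounding box; returns linear indices
# into the scene matrix plus per-pixel coverage in [0, 1].
disk_coverage <- function(cy, cx, r, scene_dim, soft = TRUE) {
  r0 <- max(0L, floor(cy - r - 1)); r1 <- min(scene_dim[1] - 1L, ceiling(cy + r + 1))
  c0 <- max(0L, floor(cx - r - 1)); c1 <- min(scene_dim[2] - 1L, ceiling(cx + r + 1))
  rows <- r0:r1; cols <- c0:c1
  d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
  cov <- if (soft) pmin(pmax(r + 0.5 - d, 0), 1) else (d <= r) * 1
  keep <- cov > 0
  idx <- outer(rows + 1L, (cols) * scene_dim[1], "+")  # 1-based linear index
  list(idx = idx[keep], cov = cov[keep])
}

place_islets <- function(cfg, radii_px) {
  n <- length(radii_px)
  mo <- mosaic_shape(cfg)
  margin <- cfg$edge_placement_margin_px
  lo_r <- SCENE_PAD + radii_px + margin
  hi_r <- SCENE_PAD + mo[1] - 1 - radii_px - margin
  lo_c <- SCENE_PAD + radii_px + margin
  hi_c <- SCENE_PAD + mo[2] - 1 - radii_px - margin
  if (any(hi_r < lo_r) || any(hi_c < lo_c)) {
    stop("islet placement failed: an islet does not fit in the field",
         call. = FALSE)
  }
  ord <- order(radii_px, decreasing = TRUE)  # place large islets first
  cy <- cx <- rep(NA_real_, n)
  for (i in ord) {
    ok <- FALSE
    for (a in seq_len(cfg$max_placement_attempts)) {
      y <- runif(1, lo_r[i], hi_r[i])
      x <- runif(1, lo_c[i], hi_c[i])
      placed <- !is.na(cy)
      if (!any(placed)) { ok <- TRUE } else {
        dmin <- sqrt((cy[placed] - y)^2 + (cx[placed] - x)^2)
        ok <- all(dmin >= radii_px[placed] + radii_px[i] + cfg$min_separation_px)
      }
      if (ok) { cy[i] <- y; cx[i] <- x; break }
    }
    if (!ok) {
      stop(sprintf(
        "islet placement failed: could not place islet of radius %.0f px after %d attempts",
        radii_px[i], cfg$max_placement_attempts
      ), call. = FALSE)
    }
  }
  cbind(row = cy, col = cx)
}

draw_release_fractions <- function(cfg, n) {
  ph <- cfg$phase_schedule
  K <- nrow(ph)
  fr <- matrix(0, n, K)
  for (p in seq_len(K)) {
    target <- ph$release_fraction[p]
    if (target == 0 || n == 0) next
    if (cfg$response_regime == "homogeneous") {
      fr[, p] <- target
    } else {
      m_resp <- cfg$responsive_beta[1] / sum(cfg$responsive_beta)
      m_bas <- cfg$basal_beta[1] / sum(cfg$basal_beta)
      w <- (target - m_bas) / (m_resp - m_bas)
      if (w < 0 || w > 1) {
        stop("heterogeneous target fraction outside the mixture's mean range",
             call. = FALSE)
      }
      resp <- runif(n) < w
      fr[, p] <- ifelse(resp,
                        rbeta(n, cfg$responsive_beta[1], cfg$responsive_beta[2]),
                        rbeta(n, cfg$basal_beta[1], cfg$basal_beta[2]))
    }
  }
  fr
}

#' Generate a synthetic acquisition with complete ground truth
#'
#' Draws islet geometry, optical depth attenuation, per-phase release
#' fractions and latent content traces, stage jitter, and motion-blur flags
#' under the configured seed, and returns a lazily rendered frame collection
#' plus the full ground truth.  Identical config and seed give bit-identical
#' frames regardless of access order.
#'
#' @param config A [sim_config()].
#' @return An object of class `islet_experiment`: a list with elements
#'   `frames` (an `islet_frameset`: `$index` data frame and
#'   `$get(time_point, tile, burst)` accessor returning an integer matrix),
#'   `truth` (class `islet_ground_truth`: `catalog`, `release_fractions`,
#'   `content` (islets x time points, attenuated measurement expectation in
#'   `id_true`), `label_map`, `offsets`, `blur`, `time_points`) and
#'   `config`.
#' @export
generate_experiment <- function(config) {
  cfg <- validate_sim_config(config)
  tps <- sim_time_points(cfg)
  n_tp <- length(tps)
  n_tiles <- prod(cfg$tile_grid)
  mo <- mosaic_shape(cfg)
  scene_dim <- c(mo[1] + 2L * SCENE_PAD, mo[2] + 2L * SCENE_PAD)
  st <- tile_steps(cfg)
  n <- cfg$n_islets

  truth <- with_seed(cfg$rng_seed, {
    # --- islet geometry ---------------------------------------------------
    if (n > 0) {
      if (!is.null(cfg$diameters_um)) {
        diam <- cfg$diameters_um
      } else {
        diam <- numeric(0)
        while (length(diam) < n) {
          d <- rlnorm(n, cfg$diameter_meanlog, cfg$diameter_sdlog)
          d <- d[d >= cfg$diameter_range_um[1] & d <= cfg$diameter_range_um[2]]
          diam <- c(diam, d)
        }
        diam <- diam[seq_len(n)]
      }
      radii <- diam / 2 / cfg$pixel_size_um
      centers <- place_islets(cfg, radii)
      atten <- runif(n, cfg$depth_attenuation_range[1],
                     cfg$depth_attenuation_range[2])
      dens0 <- runif(n, cfg$intensity_density_range[1],
                     cfg$intensity_density_range[2])
    } else {
      diam <- radii <- atten <- dens0 <- numeric(0)
      centers <- cbind(row = numeric(0), col = numeric(0))
    }

    fractions <- draw_release_fractions(cfg, n)

    # --- latent content: falls only by secretion, multiplicatively --------
    content <- matrix(0, n, n_tp, dimnames = list(NULL, tps))
    coverage <- vector("list", n)
    label_map <- matrix(0L, scene_dim[1], scene_dim[2])
    if (n > 0) {
      for (i in seq_len(n)) {
        coverage[[i]] <- disk_coverage(centers[i, 1], centers[i, 2], radii[i],
                                       scene_dim, cfg$soft_edge)
        label_map[coverage[[i]]$idx[coverage[[i]]$cov >= 0.5]] <- i
      }
      covsum <- vapply(coverage, function(z) sum(z$cov), numeric(1))
      content[, 1] <- dens0 * covsum
      step_phase <- sim_step_phase(cfg)
      durations <- cfg$phase_schedule$duration_min
      for (k in seq_len(n_tp - 1)) {
        p <- step_phase[k]
        f_step <- (1 - fractions[, p])^(cfg$cadence_min / durations[p])
        content[, k + 1] <- content[, k] * f_step
      }
    } else {
      covsum <- numeric(0)
    }

    # --- static background: smooth gradient + tissue texture --------------
    bg <- cfg$background_mean +
      cfg$background_amplitude * smooth_field(scene_dim[1], scene_dim[2],
                                              cfg$background_scale_px) +
      cfg$background_texture_amplitude * smooth_field(scene_dim[1], scene_dim[2],
                                                      cfg$background_texture_scale_px) +
      cfg$background_fine_amplitude * smooth_field(scene_dim[1], scene_dim[2],
                                                   cfg$background_fine_scale_px)
    bg <- pmax(bg, 0)

    # --- stage jitter and blur flags --------------------------------------
    grid_idx <- expand.grid(tile_col = 0:(cfg$tile_grid[2] - 1),
                            tile_row = 0:(cfg$tile_grid[1] - 1))
    grid_idx <- grid_idx[order(grid_idx$tile_row, grid_idx$tile_col), ]
    offsets <- do.call(rbind, lapply(seq_len(n_tp), function(ti) {
      jit <- matrix(pmin(pmax(round(rnorm(2 * n_tiles, 0, cfg$jitter_sigma_px)),
                              -(SCENE_PAD - BLUR_MARGIN)),
                         SCENE_PAD - BLUR_MARGIN),
                    n_tiles, 2)
      data.frame(
        time_point = tps[ti],
        tile = 0:(n_tiles - 1),
        tile_row = grid_idx$tile_row,
        tile_col = grid_idx$tile_col,
        row = SCENE_PAD + grid_idx$tile_row * st[1] + jit[, 1],
        col = SCENE_PAD + grid_idx$tile_col * st[2] + jit[, 2]
      )
    }))
    rownames(offsets) <- NULL

    blur <- expand.grid(burst = 0:(cfg$burst_size - 1),
                        tile = 0:(n_tiles - 1),
                        time_point = tps)[, 3:1]
    blur$blurred <- runif(nrow(blur)) < cfg$blur_frame_prob

    catalog <- data.frame(
      islet = seq_len(n),
      diameter_um = diam,
      row = centers[, "row"],
      col = centers[, "col"],
      radius_px = radii,
      depth_attenuation = atten,
      density0 = dens0
    )

    structure(list(
      catalog = catalog,
      release_fractions = fractions,
      content = content,
      id_true = content * atten,   # expectation of measured integrated density
      label_map = label_map,
      offsets = offsets,
      blur = blur,
      time_points = tps,
      coverage = coverage,
      covsum = covsum,
      background = bg,
      scene_dim = scene_dim
    ), class = "islet_ground_truth")
  })

  index <- expand.grid(burst = 0:(cfg$burst_size - 1),
                       tile = 0:(n_tiles - 1),
                       time_point = tps)[, 3:1]
  rownames(index) <- NULL
  cache <- new.env(parent = emptyenv())
  frames <- structure(list(
    index = index,
    get = function(time_point, tile, burst) {
      render_frame(truth, config = cfg, time_point = time_point,
                   tile = tile, burst = burst, scene_cache = cache)
    }
  ), class = "islet_frameset")

  structure(list(frames = frames, truth = truth, config = cfg),
            class = "islet_experiment")
}

#' @export
print.islet_experiment <- function(x, ...) {
  cat(sprintf(
    "<islet_experiment> %d islets, %d time points, %d tiles, burst %d (%d frames)\n",
    nrow(x$truth$catalog), length(x$truth$time_points),
    prod(x$config$tile_grid), x$config$burst_size, nrow(x$frames$index)
  ))
  invisible(x)
}

# Noise-free scene (islets over background) for one time point, memoized.
render_scene <- function(truth, cfg, tp_index, cache = NULL) {
  key <- sprintf("tp%d", tp_index)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  scene <- truth$background + 0  # copy
  n <- nrow(truth$catalog)
  if (n > 0) {
    for (i in seq_len(n)) {
      cov <- truth$coverage[[i]]
      dens <- truth$catalog$depth_attenuation[i] *
        truth$content[i, tp_index] / truth$covsum[i]
      scene[cov$idx] <- scene[cov$idx] + cov$cov * dens
    }
  }
  if (!is.null(cache)) {
    rm(list = setdiff(ls(cache), key), envir = cache)  # keep only current tp
    cache[[key]] <- scene
  }
  scene
}

# Directional motion-blur kernel: a line of the given length and angle,
# rasterized by supersampling and normalized to unit sum.
motion_blur_kernel <- function(length_px, angle) {
  half <- ceiling(length_px / 2)
  sz <- 2L * half + 1L
  k <- matrix(0, sz, sz)
  ts <- seq(-length_px / 2, length_px / 2, length.out = max(2, ceiling(length_px * 4)))
  ys <- round(half + 1 + ts * sin(angle))
  xs <- round(half + 1 + ts * cos(angle))
  for (j in seq_along(ts)) k[ys[j], xs[j]] <- k[ys[j], xs[j]] + 1
  k / sum(k)
}

#' Render one burst frame
#'
#' Composites the islet disks over the background for the requested time
#' point, crops the jittered tile window, applies directional motion blur if
#' the frame's ground-truth blur flag is set, adds Poisson-Gaussian camera
#' noise, and quantizes to the configured bit depth (clipping at
#' `2^bit_depth - 1`).
#'
#' @param truth An `islet_ground_truth`.
#' @param config The `sim_config` used to generate `truth`.
#' @param time_point Acquisition time in minutes (must be one of
#'   `truth$time_points`).
#' @param tile Tile index (0-based, row-major).
#' @param burst Burst index (0-based).
#' @param scene_cache Internal memo environment (optional).
#' @return Integer matrix `tile_shape_px[1] x tile_shape_px[2]`.
#' @export
render_frame <- function(truth, config, time_point, tile, burst,
                         scene_cache = NULL) {
  cfg <- config
  tp_index <- match(time_point, truth$time_points)
  n_tiles <- prod(cfg$tile_grid)
  if (is.na(tp_index)) stop("unknown time point: ", time_point, call. = FALSE)
  if (!(tile %in% 0:(n_tiles - 1))) stop("tile out of range: ", tile, call. = FALSE)
  if (!(burst %in% 0:(cfg$burst_size - 1))) {
    stop("burst out of range: ", burst, call. = FALSE)
  }
  scene <- render_scene(truth, cfg, tp_index, scene_cache)
  off <- truth$offsets[truth$offsets$time_point == time_point &
                         truth$offsets$tile == tile, ]
  h <- cfg$tile_shape_px[1]; w <- cfg$tile_shape_px[2]
  blurred <- truth$blur$blurred[truth$blur$time_point == time_point &
                                  truth$blur$tile == tile &
                                  truth$blur$burst == burst]
  sd_frame <- frame_seed(cfg$rng_seed, tp_index, tile, burst,
                         cfg$burst_size, n_tiles)
  with_seed(sd_frame, {
    if (blurred) {
      m <- BLUR_MARGIN
      crop <- scene[(off$row - m + 1):(off$row + h + m),
                    (off$col - m + 1):(off$col + w + m)]
      len <- runif(1, cfg$blur_length_px[1], cfg$blur_length_px[2])
      ang <- runif(1, 0, pi)
      k <- motion_blur_kernel(len, ang)
      crop <- as.matrix(EBImage::filter2(crop, k, boundary = "replicate"))
      crop <- crop[(m + 1):(m + h), (m + 1):(m + w)]
    } else {
      crop <- scene[(off$row + 1):(off$row + h),
                    (off$col + 1):(off$col + w)]
    }
    sd2 <- cfg$noise_gaussian_sd^2 + if (cfg$shot_noise) pmax(crop, 0) else 0
    v <- crop + rnorm(length(crop), 0, sqrt(sd2))
    v <- round(pmin(pmax(v, 0), 2^cfg$bit_depth - 1))
    storage.mode(v) <- "integer"
    matrix(v, h, w)
  })
}
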