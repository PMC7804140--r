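test_that("the minimum-area threshold matches the configured detection floor", {
  expect_identical(isletscope:::min_area_px(10, 0.54), 269)
  expect_identical(isletscope:::min_area_px(20, 0.54), 1077)
})

test_that("a flat image yields a flat background and zero corrected image", {
  img <- matrix(57, 64, 64)
  out <- subtract_background(img, 10)
  expect_true(all(out$background == 57))
  expect_true(all(out$corrected == 0))
  expect_error(subtract_background(img, 100), "larger than the image")
})

test_that("a small bright disk on constant background is fully recovered", {
  img <- draw_disk(matrix(10, 64, 64), 32, 30, 4, 110)
  out <- subtract_background(img, 20)
  disk <- draw_disk(matrix(FALSE, 64, 64), 32, 30, 4, TRUE)
  expect_true(all(abs(out$corrected[!disk]) <= 1))   # background flattened
  expect_true(all(out$corrected[disk] >= 99))        # disk intensity kept
  # independent morphological-opening oracle: explicit erosion + dilation
  br <- EBImage::makeBrush(41, shape = "disc") > 0
  ir <- (nrow(br) - 1) / 2
  pad <- matrix(max(img), 64 + 2 * ir, 64 + 2 * ir)
  pad[ir + 1:64, ir + 1:64] <- img
  ero <- matrix(NA_real_, 64, 64)
  offs <- which(br, arr.ind = TRUE) - ir - 1
  for (i in 1:64) for (j in 1:64) {
    ero[i, j] <- min(pad[ir + i + offs[, 1] + nrow(pad) * (ir + j + offs[, 2] - 1)])
  }
  pad2 <- matrix(min(ero), 64 + 2 * ir, 64 + 2 * ir)
  pad2[ir + 1:64, ir + 1:64] <- ero
  dil <- matrix(NA_real_, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    dil[i, j] <- max(pad2[ir + i + offs[, 1] + nrow(pad2) * (ir + j + offs[, 2] - 1)])
  }
  expect_true(all(abs(out$background - dil) <= 1))
})

test_that("the corrected image is bounded by zero and the original", {
  set.seed(20)
  img <- matrix(runif(300 * 300, 0, 4095), 300, 300)
  out <- subtract_background(img, 200)  # shrink-and-expand path
  expect_true(all(out$corrected >= 0))
  expect_true(all(out$corrected <= img + 1e-9))
  expect_true(all(out$background <= img + 1e-9))
})

test_that("masking keeps only objects above the minimum diameter", {
  params <- seg_params(min_diameter_um = 10)
  img <- matrix(0, 200, 200)
  img <- draw_disk(img, 60, 60, 4 / 0.54, 1000)    # 8 um diameter
  img <- draw_disk(img, 140, 140, 6 / 0.54, 1000)  # 12 um diameter
  mask <- make_mask(img, params, pixel_size_um = 0.54)
  obj <- measure_objects(mask, img, params, 0.54)
  expect_identical(nrow(obj), 1L)
  expect_gt(obj$area_px, isletscope:::min_area_px(10, 0.54) - 1)
  expect_equal(obj$row, 139, tolerance = 0.5)  # 0-based centroid
  # blank image: empty mask, not an error
  blank <- make_mask(matrix(0, 50, 50), params, 0.54)
  expect_true(all(!blank))
  expect_true(isTRUE(attr(blank, "no_foreground")))
})

test_that("growing the minimum diameter never increases the object count", {
  set.seed(31)
  img <- matrix(0, 240, 240)
  for (k in 1:6) {
    img <- draw_disk(img, runif(1, 40, 200), runif(1, 40, 200),
                     runif(1, 6, 16), 1200, add = TRUE)
  }
  counts <- vapply(c(5, 8, 10, 14, 18), function(d) {
    params <- seg_params(min_diameter_um = d)
    mask <- make_mask(img, params, 0.54)
    nrow(measure_objects(mask, img, params, 0.54))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("integrated density is the exact integer sum over the mask", {
  mask <- matrix(FALSE, 4, 4)
  mask[cbind(1:4, 1:4)] <- TRUE
  img <- matrix(0L, 4, 4)
  img[cbind(1:4, 1:4)] <- c(100L, 200L, 300L, 400L)
  params <- seg_params(min_diameter_um = 0.1, edge_margin_px = 0)
  obj <- measure_objects(mask, img, params, 0.54)
  expect_identical(sum(obj$integrated_density), 1000)
  # uniform disk: ID = area x intensity, exactly
  img2 <- draw_disk(matrix(0L, 100, 100), 50, 50, 12, 777L)
  mask2 <- img2 > 0
  obj2 <- measure_objects(mask2, img2, seg_params(min_diameter_um = 1), 0.54)
  expect_identical(obj2$integrated_density, obj2$area_px * 777)
  # brute-force oracle on a random labeled image
  set.seed(40)
  img3 <- matrix(sample.int(4095, 80 * 80, TRUE), 80, 80)
  mask3 <- matrix(runif(80 * 80) < 0.2, 80, 80)
  obj3 <- measure_objects(mask3, img3, seg_params(min_diameter_um = 0.1), 0.54)
  lab <- isletscope:::label_components(mask3)
  oracle <- tapply(img3[lab > 0], lab[lab > 0], sum)
  expect_identical(unname(obj3$integrated_density[order(obj3$label)]),
                   as.numeric(oracle[order(as.integer(names(oracle)))]))
  expect_identical(sum(obj3$area_px), sum(mask3))
})

test_that("objects near the border or at saturation are flagged", {
  params <- seg_params(min_diameter_um = 1, edge_margin_px = 20)
  img <- draw_disk(matrix(0L, 120, 120), 25, 60, 8, 1000L)  # bbox near top
  obj <- measure_objects(img > 0, img, params, 0.54)
  expect_true(obj$edge_proximal)
  img2 <- draw_disk(matrix(0L, 120, 120), 60, 60, 8, 4095L)
  obj2 <- measure_objects(img2 > 0, img2, params, 0.54)
  expect_false(obj2$edge_proximal)
  expect_true(obj2$saturated)
  expect_error(measure_objects(matrix(TRUE, 3, 3), matrix(1, 4, 4),
                               params, 0.54), "shapes differ")
})

test_that("eight-connected regions are one object, as for touching islets", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE   # diagonal chain
  lab <- isletscope:::label_components(m)
  expect_identical(max(lab), 1L)
  m[6, 6] <- TRUE
  expect_identical(max(isletscope:::label_components(m)), 2L)
})

test_that("noise-free measurements are proportional to true content", {
  cfg <- sim_preset("invivo_gsis", rng_seed = 9, n_islets = 8L,
                    tile_shape_px = c(320L, 384L),
                    diameter_range_um = c(20, 60),
                    diameter_meanlog = log(30),
                    background_mean = 0, background_amplitude = 0,
                    background_texture_amplitude = 0,
                    background_fine_amplitude = 0,
                    noise_gaussian_sd = 0, shot_noise = FALSE,
                    jitter_sigma_px = 0, blur_frame_prob = 0)
  exp <- generate_experiment(cfg)
  res <- run_pipeline(exp, time_points = 0)
  obj <- res$objects[[1]]
  expect_identical(nrow(obj), 8L)
  tru <- exp$truth$offsets[exp$truth$offsets$time_point == 0, ]
  orig <- c(min(tru$row), min(tru$col))
  cat_ <- exp$truth$catalog
  idx <- vapply(seq_len(nrow(obj)), function(i) {
    which.min((cat_$row - (obj$row[i] + orig[1]))^2 +
                (cat_$col - (obj$col[i] + orig[2]))^2)
  }, integer(1))
  ratio <- obj$integrated_density / exp$truth$id_true[idx, 1]
  expect_true(all(abs(ratio - 1) < 0.02))
})
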