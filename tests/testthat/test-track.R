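mk_objects <- function(rows, cols, areas, time_point = 0) {
  n <- length(rows)
  data.frame(
    label = seq_len(n), row = rows, col = cols,
    area_px = as.integer(areas), area_um2 = areas * 0.54^2,
    integrated_density = areas * 1000,
    bbox_rmin = 0L, bbox_rmax = 1L, bbox_cmin = 0L, bbox_cmax = 1L,
    edge_proximal = FALSE, saturated = FALSE, low_confidence_frame = FALSE,
    time_point = time_point
  )
}

test_that("a rigid translation links every object to itself", {
  a <- mk_objects(c(10, 50, 90), c(10, 60, 20), c(400, 500, 600), 0)
  b <- mk_objects(c(15, 55, 95), c(13, 63, 23), c(400, 500, 600), 5)
  links <- link_objects(a, b)
  expect_identical(links$label_a, 1:3)
  expect_identical(links$label_b, 1:3)
})

test_that("the assignment equals exhaustive minimum-cost matching", {
  # all permutations of 1..n by recursion (oracle helper)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  set.seed(17)
  n <- 8
  all_perms <- perms(seq_len(n))
  for (rep in 1:3) {
    a <- mk_objects(runif(n, 0, 60), runif(n, 0, 60), rep(500, n), 0)
    b <- a
    b$row <- a$row + runif(n, -8, 8)
    b$col <- a$col + runif(n, -8, 8)
    b$time_point <- 5
    shuffle <- sample(n)
    b <- b[shuffle, ]; b$label <- seq_len(n)
    d <- sqrt(outer(a$row, b$row, "-")^2 + outer(a$col, b$col, "-")^2)
    best <- Inf
    for (p in all_perms) {
      cost <- sum(d[cbind(seq_len(n), p)])
      if (cost < best) { best <- cost; bestp <- p }
    }
    links <- link_objects(a, b, max_displacement_px = 1e6,
                          max_log_area_ratio = 10)
    expect_identical(nrow(links), 8L)
    expect_equal(sum(links$cost), best, tolerance = 1e-9)
    expect_identical(links$label_b[order(links$label_a)], bestp)
  }
})

test_that("objects beyond the gates stay unmatched", {
  a <- mk_objects(10, 10, 500, 0)
  b <- mk_objects(10 + 50, 10, 500, 5)   # displaced 50 px, gate 30
  expect_identical(nrow(link_objects(a, b)), 0L)
  # area gate: same position, area ratio > 2
  b2 <- mk_objects(10, 10, 1100, 5)
  expect_identical(nrow(link_objects(a, b2)), 0L)
  expect_identical(nrow(link_objects(a[0, ], b)), 0L)  # empty tables allowed
})

test_that("traces chain across time points and record completeness", {
  a <- mk_objects(c(10, 40), c(10, 40), c(400, 400), 0)
  b <- mk_objects(c(12, 42), c(11, 41), c(400, 400), 5)
  cc <- mk_objects(c(14, 44), c(12, 42), c(400, 400), 10)
  tr <- build_traces(list(a, b, cc))
  expect_identical(nrow(tr$info), 2L)
  expect_true(all(tr$info$complete))
  expect_true(all(table(tr$objects$islet_id) == 3))
  # drop one object at the middle time point: the trace breaks
  b_gap <- b[1, , drop = FALSE]
  tr2 <- build_traces(list(a, b_gap, cc))
  expect_identical(sum(tr2$info$complete), 1L)
  expect_true(any(!tr2$info$complete))
})

test_that("a split candidate losing the assignment opens a merge-suspect trace", {
  a <- mk_objects(20, 20, 500, 0)
  b <- mk_objects(c(21, 24), c(20, 23), c(500, 500), 5)
  tr <- build_traces(list(a, b))
  expect_identical(nrow(tr$info), 2L)
  expect_identical(sum(tr$info$merge_suspect), 1L)
  # the new trace is the one that starts late
  expect_true(tr$info$merge_suspect[tr$info$first_time_point == 5])
})

test_that("exclusion rules flag edge, saturation and incompleteness", {
  a <- mk_objects(c(10, 40, 70), c(10, 40, 70), c(400, 400, 400), 0)
  b <- mk_objects(c(10, 40, 70), c(10, 40, 70), c(400, 400, 400), 5)
  a$edge_proximal[1] <- TRUE
  b$saturated[2] <- TRUE
  tr <- apply_exclusions(build_traces(list(a, b)))
  expect_identical(tr$info$reason[1], "edge")
  expect_identical(tr$info$reason[2], "saturation")
  expect_false(tr$info$excluded[3])
  counts <- attr(tr, "exclusion_counts")
  expect_identical(unname(counts[c("edge", "saturation")]), c(1L, 1L))
  # an incomplete trace is excluded with its own reason
  tr2 <- apply_exclusions(build_traces(list(a[3, , drop = FALSE],
                                            b[0, , drop = FALSE])))
  expect_identical(tr2$info$reason, "incomplete")
})

test_that("simulated tracking recovers ground-truth identities completely", {
  cfg <- sim_preset("invivo_gsis", rng_seed = 4, n_islets = 15L)
  exp <- generate_experiment(cfg)
  res <- run_pipeline(exp)
  info <- res$traces$info
  expect_identical(sum(info$complete & !info$excluded), 15L)
  # each retained trace sits on a distinct ground-truth label
  tru <- exp$truth$offsets[exp$truth$offsets$time_point == 0, ]
  orig <- c(min(tru$row), min(tru$col))
  obj0 <- res$traces$objects[res$traces$objects$time_point == 0, ]
  lab <- exp$truth$label_map[cbind(round(obj0$row + orig[1]) + 1,
                                   round(obj0$col + orig[2]) + 1)]
  expect_identical(sort(lab), 1:15)
})
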