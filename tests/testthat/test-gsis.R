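test_that("percent traces are referenced to the stimulation time point", {
  expect_equal(percent_trace(c(1000, 900), c(0, 15), 0), c(100, 90))
  expect_equal(percent_trace(c(500, 500, 500), c(0, 5, 10), 0),
               rep(100, 3))
  # apparent gains are allowed, as seen for some small islets
  expect_equal(percent_trace(c(800, 900), c(0, 15), 0), c(100, 112.5))
  out <- percent_trace(c(0, 900), c(0, 15), 0)
  expect_true(all(is.na(out)))
  expect_identical(attr(out, "reason"), "zero_reference")
  expect_error(percent_trace(c(1, 2), c(0, 5), 99), "not among")
})

test_that("the experiment summary matches the direct-formula oracle", {
  tab <- data.frame(
    islet_id = rep(1:2, each = 2),
    time_point = rep(c(0, 15), 2),
    area_px = rep(c(900L, 1600L), each = 2),
    integrated_density = c(1000, 900, 1000, 940)
  )
  sm <- summarize_experiment(manual_traces(tab), 0, 15)
  expect_equal(sm$total_response_percent, 8.0)
  expect_equal(sm$per_islet$decline, c(10, 6))
  # SEM of P = [90, 94]: sample SD sqrt(8) over sqrt(2)
  expect_equal(sm$heterogeneity_sem, sqrt(8) / sqrt(2))
  expect_identical(sm$n_islets, 2L)

  # single islet: heterogeneity undefined, reported missing (not 0)
  sm1 <- summarize_experiment(manual_traces(tab[1:2, ]), 0, 15)
  expect_true(is.na(sm1$heterogeneity_sem))

  # identical declines: SEM exactly 0
  tab3 <- data.frame(islet_id = rep(1:3, each = 2),
                     time_point = rep(c(0, 15), 3),
                     area_px = 1000L,
                     integrated_density = rep(c(1000, 900), 3))
  expect_identical(summarize_experiment(manual_traces(tab3), 0, 15)$heterogeneity_sem, 0)
})

test_that("total response equals the content-weighted mean decline", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    id0 <- runif(n, 100, 5000)
    id1 <- id0 * runif(n, 0.5, 1.2)
    tab <- data.frame(islet_id = rep(seq_len(n), each = 2),
                      time_point = rep(c(0, 15), n),
                      area_px = rep(100L, 2 * n),
                      integrated_density = as.vector(rbind(id0, id1)))
    sm <- summarize_experiment(manual_traces(tab), 0, 15)
    weighted <- sum(sm$per_islet$id_ref * sm$per_islet$decline) /
      sum(sm$per_islet$id_ref)
    expect_equal(sm$total_response_percent, weighted, tolerance = 1e-9)
  }
})

test_that("a zero-reference trace is excluded with a reason, not an error", {
  tab <- data.frame(islet_id = rep(1:2, each = 2),
                    time_point = rep(c(0, 15), 2),
                    area_px = 100L,
                    integrated_density = c(0, 50, 1000, 900))
  sm <- summarize_experiment(manual_traces(tab), 0, 15)
  expect_identical(sm$n_islets, 1L)
  expect_identical(sm$per_islet$islet_id, 2L)
})

test_that("the size-response relation is a report, with constructed extremes", {
  # perfectly size-proportional declines: rank correlation exactly -1
  n <- 12
  area <- seq(300, 3000, length.out = n)
  id0 <- rep(1000, n)
  id1 <- id0 * (1 - seq(0.05, 0.6, length.out = n))
  tab <- data.frame(islet_id = rep(seq_len(n), each = 2),
                    time_point = rep(c(0, 15), n),
                    area_px = as.integer(rep(area, each = 2)),
                    integrated_density = as.vector(rbind(id0, id1)))
  sm <- summarize_experiment(manual_traces(tab), 0, 15)
  rel <- size_response_relation(sm)
  expect_equal(rel$rho, -1)
  # constant areas: undefined, reported missing
  tabc <- tab; tabc$area_px <- 500L
  relc <- size_response_relation(summarize_experiment(manual_traces(tabc), 0, 15))
  expect_true(is.na(relc$rho))
  # fewer than 3 islets is a precondition violation
  sm2 <- summarize_experiment(manual_traces(tab[1:4, ]), 0, 15)
  expect_error(size_response_relation(sm2), "at least 3")
})

test_that("simulated heterogeneous responses are size-independent", {
  exp <- generate_experiment(sim_preset("invivo_fullpancreas", rng_seed = 2))
  it <- exp$truth$id_true
  n <- nrow(it)
  tab <- data.frame(islet_id = rep(seq_len(n), each = 2),
                    time_point = rep(c(0, 15), n),
                    area_px = rep(as.integer(round(exp$truth$covsum)), each = 2),
                    integrated_density = as.vector(rbind(it[, 1], it[, 4])))
  rel <- size_response_relation(summarize_experiment(manual_traces(tab), 0, 15))
  expect_lt(abs(rel$rho), 0.2)
})

test_that("heterogeneity comparison picks the right test and direction", {
  identical_groups <- compare_heterogeneity(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(identical_groups$p_value, 0.05)
  expect_error(compare_heterogeneity(1, c(1, 2)), "at least 2")

  # 8 simulated culture wells vs 5 simulated pancreata, with light
  # measurement noise on the ground-truth content traces
  set.seed(99)
  sem_of <- function(preset, seed) {
    ex <- generate_experiment(sim_preset(preset, rng_seed = seed))
    it <- ex$truth$id_true
    last <- ncol(it)
    ref <- if (preset == "invitro_gsis") which(colnames(it) == "15") else 1
    end <- if (preset == "invitro_gsis") which(colnames(it) == "30") else last
    p <- 100 * (it[, end] * (1 + rnorm(nrow(it), 0, 0.003))) / it[, ref]
    sd(p) / sqrt(length(p))
  }
  sem_vitro <- vapply(1:8, function(s) sem_of("invitro_gsis", 300 + s), numeric(1))
  sem_vivo <- vapply(1:5, function(s) sem_of("invivo_gsis", 400 + s), numeric(1))
  expect_gt(mean(sem_vivo), mean(sem_vitro))
  cmp <- compare_heterogeneity(sem_vitro, sem_vivo)
  expect_lt(cmp$p_value, 0.05)
  expect_true(cmp$test_used %in% c("t", "mann_whitney"))
})
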