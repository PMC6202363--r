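test_that("sensitivity fields validate their inputs", {
  expect_error(sensitivity_field(rep(10, 55), 70), "length 56")
  expect_error(sensitivity_field(c(25, rep(10, 55)), 70), "0-20 dB")
  expect_error(sensitivity_field(rep(10, 56), 70, fp_rate = 1.2), "rate")
  f <- sensitivity_field(rep(10, 56), 70, fp_rate = 0.10)
  expect_true(check_reliability(f))
  f$fp_rate <- 0.15   # boundary: exactly 15% is unreliable
  expect_false(check_reliability(f))
  f$fp_rate <- 0
  expect_true(check_reliability(f))
})

test_that("normative fitting recovers the generating age slope", {
  cfg <- generator_config(seed = 5)
  cohort <- generate_normative_cohort(cfg, 200, seed = 501, grid = the_grid)
  m <- fit_normative(cohort)
  expect_s3_class(m, "mp_normative")
  # per-location slopes concentrate near the configured -0.05 dB/yr
  expect_gte(mean(abs(m$slope - (-0.05)) <= 0.02), 0.9)
  # model-level slope within 10% of truth
  expect_lt(abs(mean(m$slope) - (-0.05)), 0.005)
  # quantiles are ordered at every location
  expect_true(all(m$td_q[, "p5"] >= m$td_q[, "p2"]))
  expect_true(all(m$td_q[, "p2"] >= m$td_q[, "p1"]))
  expect_true(all(m$pd_q[, "p5"] >= m$pd_q[, "p2"]))
  expect_true(all(m$pd_q[, "p2"] >= m$pd_q[, "p1"]))
  expect_true(all(m$resid_sd > 0))
})

test_that("normative fitting rejects degenerate cohorts", {
  cfg <- generator_config(seed = 6)
  small <- generate_normative_cohort(cfg, 10, seed = 1, grid = the_grid)
  expect_error(fit_normative(small), "at least 30")
  cohort <- generate_normative_cohort(cfg, 32, seed = 2, grid = the_grid)
  same_age <- lapply(cohort, function(f) { f$age <- 70; f })
  expect_error(fit_normative(same_age), "age range")
  holey <- lapply(cohort, function(f) { f$values[8] <- NA; f })
  expect_error(fit_normative(holey), "location 7")
})

test_that("zero-variance locations get the residual-SD floor", {
  base <- sensitivity_field(rep(15, 56), 60)
  cohort <- lapply(1:40, function(i) {
    f <- base; f$age <- 50 + i %% 30; f
  })
  m <- fit_normative(cohort)
  expect_true(all(m$resid_sd == 0.5))
})

test_that("Total Deviation is measured minus expected, exactly", {
  m <- exact_model(expected = rep(16, 56))
  f <- sensitivity_field(rep(16, 56), 73)
  expect_equal(unclass(total_deviation(f, m)), rep(0, 56))
  f5 <- sensitivity_field(rep(11, 56), 73)
  expect_equal(unclass(total_deviation(f5, m)), rep(-5, 56))
  fna <- sensitivity_field(c(NA, rep(16, 55)), 73)
  expect_true(is.na(total_deviation(fna, m)[1]))
  expect_warning(total_deviation(sensitivity_field(rep(16, 56), 95), m),
                 "extrapolat")
})

test_that("TD recovers a known depression within measurement noise", {
  cfg <- generator_config(seed = 9,
                          measurement = list(test_retest_sd = 1.5,
                                             staircase = TRUE))
  set.seed(99)
  eye <- generate_pcv_eye(cfg, the_grid, exudative = TRUE)
  m <- normative_from_config(cfg, the_grid)
  td <- total_deviation(eye$field, m)
  truth <- eye$ground_truth$true_db -
    mpconcord:::.normative_surface(cfg, the_grid$locations$ecc,
                                   eye$ground_truth$age)
  expect_lt(median(abs(unclass(td) - truth)), 2)
})

test_that("Pattern Deviation removes diffuse loss via the general height", {
  mk_td <- function(v) structure(v, class = "mp_td")
  pd <- pattern_deviation(mk_td(rep(-4, 56)))
  expect_equal(attr(pd, "general_height"), -4)
  expect_equal(unclass(pd), rep(0, 56), ignore_attr = TRUE)
  pd0 <- pattern_deviation(mk_td(rep(0, 56)))
  expect_equal(unclass(pd0), rep(0, 56), ignore_attr = TRUE)
  # 8 deep locations leave the 85th percentile at zero: PD equals TD
  v <- c(rep(-20, 8), rep(0, 48))
  pdv <- pattern_deviation(mk_td(v))
  expect_equal(attr(pdv, "general_height"), 0)
  expect_equal(unclass(pdv), v, ignore_attr = TRUE)
  expect_error(pattern_deviation(mk_td(c(rep(NA, 50), rep(1, 6)))),
               "at least 10")
})

test_that("adding a constant to the field leaves PD unchanged", {
  m <- exact_model(expected = rep(16, 56))
  set.seed(31)
  for (rep_i in 1:25) {
    # interior values so the shift never clamps at the 0/20 dB bounds
    v <- sample(seq(4, 16, by = 2), 56, replace = TRUE)
    shift <- sample(c(-4, -2, 2, 4), 1)
    f1 <- sensitivity_field(v, 70)
    f2 <- sensitivity_field(v + shift, 70)
    pd1 <- pattern_deviation(total_deviation(f1, m))
    pd2 <- pattern_deviation(total_deviation(f2, m))
    expect_identical(as.vector(unclass(pd1)), as.vector(unclass(pd2)))
  }
})

test_that("probability maps are monotone with inclusive thresholds", {
  m <- exact_model(q = c(-4, -6, -8))
  mk_td <- function(v) structure(v, class = "mp_td")
  dev <- rep(0, 56)
  dev[1] <- -4    # exactly at q5: flagged
  dev[2] <- -30   # extreme: p1
  dev[3] <- NA    # missing: normal
  pm <- probability_map(mk_td(dev), m)
  expect_equal(as.character(pm[1]), "p5")
  expect_equal(as.character(pm[2]), "p1")
  expect_equal(as.character(pm[3]), "normal")
  # monotonicity: making one deviation more negative never relaxes a level
  set.seed(17)
  for (i in 1:50) {
    v <- runif(56, -10, 2)
    pm1 <- probability_map(mk_td(v), m)
    j <- sample(56, 1)
    v[j] <- v[j] - runif(1, 0, 10)
    pm2 <- probability_map(mk_td(v), m)
    expect_gte(unclass(pm2)[j], unclass(pm1)[j])
    expect_equal(unclass(pm2)[-j], unclass(pm1)[-j])
  }
})

test_that("empirical quantile flags are calibrated near their level", {
  cfg <- generator_config(seed = 13, measurement = list(staircase = FALSE))
  cohort <- generate_normative_cohort(cfg, 200, seed = 77, grid = the_grid)
  m <- fit_normative(cohort)
  fresh <- generate_normative_cohort(cfg, 2000, seed = 78, grid = the_grid)
  rates <- vapply(fresh, function(f) {
    pm <- suppressWarnings(probability_map(total_deviation(f, m), m))
    mean(unclass(pm) >= 2)
  }, 0)
  expect_lt(abs(mean(rates) - 0.05), 0.01)
})

test_that("field-loss detection applies the three-contiguous rule", {
  m <- exact_model(q = c(-4, -6, -8))
  mk_pd <- function(v) structure(v, class = "mp_pd")
  # two adjacent flagged locations only: below the cluster criterion
  adj <- the_grid$adjacency
  pair <- adj[1, ]
  v <- rep(0, 56); v[pair + 1L] <- -30
  pm <- probability_map(mk_pd(v), m)
  expect_identical(detect_field_loss(pm, the_grid), integer(0))
  # a triangle of mutually contiguous locations is returned whole
  tri <- NULL
  for (i in 0:55) {
    nb <- c(adj[adj[, 1] == i, 2], adj[adj[, 2] == i, 1])
    for (a in nb) for (b in nb) {
      if (a < b && any((adj[, 1] == a & adj[, 2] == b) |
                       (adj[, 1] == b & adj[, 2] == a))) {
        tri <- c(i, a, b); break
      }
    }
    if (!is.null(tri)) break
  }
  v <- rep(0, 56); v[tri + 1L] <- -30
  pm <- probability_map(mk_pd(v), m)
  expect_identical(detect_field_loss(pm, the_grid), sort(as.integer(tri)))
})

test_that("field-loss detection equals exhaustive component search", {
  m <- exact_model(q = c(-4, -6, -8))
  set.seed(23)
  for (i in 1:100) {
    flagged <- sample(0:55, rbinom(1, 56, 0.2))
    v <- rep(0, 56); v[flagged + 1L] <- -30
    pm <- probability_map(structure(v, class = "mp_pd"), m)
    expect_identical(detect_field_loss(pm, the_grid),
                     as.integer(bf_field_loss(flagged, the_grid$adjacency)))
  }
})

test_that("healthy-eye field-loss rate is stable across seeds", {
  cfg <- generator_config(seed = 1, measurement = list(staircase = FALSE))
  cohort <- generate_normative_cohort(cfg, 150, seed = 41, grid = the_grid)
  m <- fit_normative(cohort)
  rate <- function(seed) {
    eyes <- generate_normative_cohort(cfg, 2000, seed = seed, grid = the_grid)
    mean(vapply(eyes, function(f) {
      pm <- suppressWarnings(
        probability_map(pattern_deviation(total_deviation(f, m)), m))
      length(detect_field_loss(pm, the_grid)) > 0
    }, TRUE))
  }
  r1 <- rate(101); r2 <- rate(202)
  expect_lt(abs(r1 - r2), 0.02)
})

test_that("field summaries report means and p1 counts", {
  m <- exact_model(expected = rep(20, 56))
  f <- sensitivity_field(rep(20, 56), 70)
  td <- total_deviation(f, m)
  pd <- pattern_deviation(td)
  pm <- probability_map(pd, m)
  s <- summarize_field(f, td, pd, pm)
  expect_equal(s$mean_td, 0)
  expect_equal(s$n_pd_defects_p1, 0)
  # explicit arithmetic on a two-location field
  f2 <- sensitivity_field(c(20, 14, rep(NA, 54)), 70)
  td2 <- total_deviation(f2, m)
  expect_equal(mean(unclass(td2), na.rm = TRUE), -3)
  # p1 count comes straight from the probability map
  v <- rep(0, 56); v[1:38] <- -30
  pm38 <- probability_map(structure(v, class = "mp_pd"), m)
  s38 <- summarize_field(f, td, pd, pm38)
  expect_equal(s38$n_pd_defects_p1, 38)
})
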