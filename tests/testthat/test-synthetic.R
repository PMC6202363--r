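test_that("config validation and partial overrides work", {
  cfg <- generator_config(lesion = list(irregularity = 0))
  expect_equal(cfg$lesion$irregularity, 0)
  expect_equal(cfg$lesion$icga_median_area_mm2, 10)  # untouched default
  expect_error(generator_config(exudative_fraction = 1.5), "fraction")
  expect_error(generator_config(lesion = list(icga_median_area_mm2 = -1)),
               "> 0")
  expect_error(generator_config(measurement = list(test_retest_sd = -1)),
               "SD")
})

test_that("the 4-2 staircase brackets a deterministic observer", {
  # threshold 11, step observer: 10 seen, 14 not (reversal, step 2),
  # 12 not, 10 seen (second reversal) -> last seen 10
  expect_equal(simulate_staircase(11, slope = 0), 10)
  expect_equal(simulate_staircase(0, slope = 0), 0)    # floor
  expect_equal(simulate_staircase(20, slope = 0), 20)  # ceiling
  for (t in seq(0, 20, by = 0.5))
    expect_lte(abs(simulate_staircase(t, slope = 0) - t), 2)
})

test_that("noise-free normative cohorts equal the deterministic surface", {
  cfg <- generator_config(normative = list(resid_sd = 0),
                          measurement = list(staircase = FALSE))
  cohort <- generate_normative_cohort(cfg, 5, seed = 3, grid = the_grid)
  for (f in cohort) {
    want <- pmin(20, pmax(0, mpconcord:::.normative_surface(
      cfg, the_grid$locations$ecc, f$age)))
    expect_equal(f$values, want)
  }
})

test_that("generation is reproducible from the master seed", {
  cfg <- generator_config(seed = 99, n_eyes = 4)
  c1 <- generate_cohort(cfg, the_grid)
  c2 <- generate_cohort(cfg, the_grid)
  expect_identical(c1, c2)
  n1 <- generate_normative_cohort(cfg, 5, seed = 8, grid = the_grid)
  n2 <- generate_normative_cohort(cfg, 5, seed = 8, grid = the_grid)
  expect_identical(n1, n2)
})

test_that("degenerate lesion configs give identical circles", {
  cfg <- generator_config(lesion = list(irregularity = 0,
                                        oct_dilation_deg = 0,
                                        boundary_noise_deg = 0,
                                        center_jitter_deg = 0))
  pair <- generate_lesion_pair(cfg, seed = 12)
  expect_equal(pair$icga$rings[[1]], pair$oct$rings[[1]], tolerance = 1e-12)
  r <- sqrt(rowSums(pair$icga$rings[[1]]^2))
  expect_lt(diff(range(r)), 1e-9)  # a circle
})

test_that("sampled lesion areas are calibrated to the configured median", {
  cfg <- generator_config()
  set.seed(15)
  areas <- replicate(500, {
    exud <- runif(1) < cfg$exudative_fraction
    polygon_area_mm2(generate_lesion_pair(cfg, exudative = exud)$icga,
                     cfg$mm_per_degree)
  })
  expect_lt(abs(median(areas) - 10) / 10, 0.15)
})

test_that("exudative eyes draw systematically larger lesions", {
  cfg <- generator_config()
  set.seed(16)
  a_ex <- replicate(200, polygon_area_mm2(
    generate_lesion_pair(cfg, exudative = TRUE)$icga))
  a_non <- replicate(200, polygon_area_mm2(
    generate_lesion_pair(cfg, exudative = FALSE)$icga))
  expect_gt(median(a_ex), median(a_non))
})

test_that("an undepressed noise-free eye has no detectable field loss", {
  cfg <- generator_config(depression = list(depth_db = 0, halo_depth_db = 0),
                          measurement = list(staircase = FALSE,
                                             test_retest_sd = 0))
  eye <- generate_pcv_eye(cfg, the_grid, seed = 21)
  want <- pmin(20, pmax(0, mpconcord:::.normative_surface(
    cfg, the_grid$locations$ecc, eye$ground_truth$age)))
  expect_equal(eye$field$values, want)
  m <- normative_from_config(cfg, the_grid)
  a <- analyze_eye(eye, m, the_grid)
  expect_identical(a$sets$mp, integer(0))
})

test_that("deep noise-free depression is recovered as the mapped OCT set", {
  cfg <- generator_config(depression = list(depth_db = 30, halo_width_deg = 0,
                                            halo_depth_db = 0),
                          measurement = list(staircase = FALSE,
                                             test_retest_sd = 0))
  m <- normative_from_config(cfg, the_grid)
  set.seed(25)
  for (i in 1:5) {
    eye <- generate_pcv_eye(cfg, the_grid)
    a <- analyze_eye(eye, m, the_grid)
    oct <- eye$ground_truth$oct_set
    # flaggable: depressed locations surviving the >= 3 contiguity rule
    want <- as.integer(bf_field_loss(oct, the_grid$adjacency))
    # guard: general height must not have been swallowed by the lesion
    if (length(oct) <= 46) expect_identical(a$sets$mp, want)
  }
})

test_that("a depression halo extends field loss beyond the OCT set", {
  cfg <- generator_config(depression = list(halo_width_deg = 2,
                                            halo_depth_db = 15))
  m <- normative_from_config(cfg, the_grid)
  set.seed(27)
  comps <- replicate(50, {
    eye <- generate_pcv_eye(cfg, the_grid)
    a <- analyze_eye(eye, m, the_grid)
    relative_complement_pct(a$sets$mp, a$sets$oct)
  })
  expect_gt(median(comps), 0)
})

test_that("eye records carry ground truth and plausible structure", {
  cfg <- generator_config(seed = 31, n_eyes = 6)
  cohort <- generate_cohort(cfg, the_grid)
  expect_length(cohort, 6)
  for (eye in cohort) {
    expect_false(is.null(eye$ground_truth))
    thk <- eye$thickness$total_retinal_um
    expect_true(all(is.na(thk[the_grid$locations$ecc > 7])))
    expect_true(all(thk[!is.na(thk)] > 0))
    ch <- eye$thickness$subfoveal_choroid_um
    if (!is.na(ch)) expect_gt(ch, 0)
  }
  # exact exudative count under the default configuration
  expect_equal(sum(vapply(cohort, `[[`, TRUE, "exudative")),
               round(6 * 16 / 25))
})

test_that("an empty cohort is valid", {
  cfg <- generator_config(seed = 1, n_eyes = 0)
  cohort <- generate_cohort(cfg, the_grid)
  expect_length(cohort, 0)
})
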