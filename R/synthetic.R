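#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the clinical conditions the analysis targets: a
#' PCV case series of 25 eyes examined after the 3-month anti-VEGF
#' loading phase, 16/25 with exudative change, lesion areas lognormal
#' with an all-eyes median near 10 mm^2 (exudative eyes larger),
#' subfoveal choroid Normal(251, 100) um, functional depression inside
#' the OCT lesion with a probabilistic halo of shallower loss beyond it,
#' and retinal thickening coupled to the depression. Partial overrides
#' merge into the defaults (e.g. `lesion = list(irregularity = 0)`).
#'
#' @param seed Master seed; every stochastic draw of [generate_cohort()]
#'   descends from it.
#' @param n_eyes Number of patient eyes.
#' @param exudative_fraction Probability (or exact fraction, see
#'   `exudative_exact`) of exudative change.
#' @param exudative_exact If `TRUE` (default) exactly
#'   `round(fraction * n)` eyes are exudative; otherwise Bernoulli.
#' @param age_range Patient age range in years (uniform).
#' @param normative Healthy-surface parameters: `baseline_db` (fovea, at
#'   the reference age), `ecc_slope` (dB lost per degree of
#'   eccentricity), `age_slope` (regression slope, dB per year),
#'   `resid_sd` (between-eye residual SD, dB), `reference_age`.
#' @param lesion ICGA/OCT polygon parameters: `icga_median_area_mm2`,
#'   `area_sdlog`, `exudative_area_scale` (multiplicative meanlog shift
#'   applied +/- by exudative status), `oct_dilation_deg` (median radial
#'   margin of OCT beyond ICGA; 0 disables dilation),
#'   `oct_dilation_sdlog`, `boundary_noise_deg` (SD of smooth radial
#'   noise on the OCT boundary), `irregularity` (radial spline roughness;
#'   0 gives circles), `n_vertices`, `center_jitter_deg`.
#' @param depression Functional-loss parameters: `depth_db` inside the
#'   OCT lesion, `halo_width_deg` and `halo_depth_db` for the shallower
#'   fringe beyond it, `halo_prob` (per-location probability that the
#'   fringe depresses a location; < 1 creates eyes where field loss is
#'   not a strict superset of the OCT set).
#' @param thickness Structural parameters: `baseline_um`,
#'   `lesion_thickening_um`, `pd_coupling_um_per_db` (extra thickening
#'   per dB of true depression, producing the negative PD-thickness
#'   association), `noise_um`, `choroid_mean_um`, `choroid_sd_um`,
#'   `choroid_available_fraction`, `choroid_pd_coupling` (um of choroid
#'   per dB of central depression; default 0).
#' @param measurement `staircase` (simulate the 4-2 procedure),
#'   `test_retest_sd` (dB), `psychometric_slope` (dB),
#'   `fp_rate_range` (uniform range of false-positive rates).
#' @param mm_per_degree Degree-to-mm scale shared with
#'   [polygon_area_mm2()].
#' @param vertical_halfwidth Vertical analysis extent (5 or 10 deg).
#' @return Object of class `mp_genconfig`.
#' @export
generator_config <- function(seed = 1L, n_eyes = 25L,
                             exudative_fraction = 16 / 25,
                             exudative_exact = TRUE,
                             age_range = c(63, 88),
                             normative = list(), lesion = list(),
                             depression = list(), thickness = list(),
                             measurement = list(),
                             mm_per_degree = 0.288,
                             vertical_halfwidth = 10) {
  cfg <- list(
    seed = as.integer(seed), n_eyes = as.integer(n_eyes),
    exudative_fraction = exudative_fraction,
    exudative_exact = exudative_exact,
    age_range = age_range,
    normative = utils::modifyList(list(
      baseline_db = 18, ecc_slope = 0.3, age_slope = -0.05,
      resid_sd = 1.2, reference_age = 70), normative),
    lesion = utils::modifyList(list(
      icga_median_area_mm2 = 10, area_sdlog = 0.5,
      exudative_area_scale = 1.25, oct_dilation_deg = 0.7,
      oct_dilation_sdlog = 0.4, boundary_noise_deg = 0.25,
      irregularity = 0.35, n_vertices = 48L,
      center_jitter_deg = 3.5), lesion),
    depression = utils::modifyList(list(
      depth_db = 12, halo_width_deg = 2, halo_depth_db = 8,
      halo_prob = 0.7), depression),
    thickness = utils::modifyList(list(
      baseline_um = 280, lesion_thickening_um = 25,
      pd_coupling_um_per_db = 1.5, noise_um = 12,
      choroid_mean_um = 251, choroid_sd_um = 100,
      choroid_available_fraction = 21 / 25,
      choroid_pd_coupling = 0), thickness),
    measurement = utils::modifyList(list(
      staircase = TRUE, test_retest_sd = 1.5,
      psychometric_slope = 0.5, fp_rate_range = c(0, 0.12)), measurement),
    mm_per_degree = mm_per_degree,
    vertical_halfwidth = vertical_halfwidth
  )
  sds <- c(cfg$normative$resid_sd, cfg$lesion$boundary_noise_deg,
           cfg$measurement$test_retest_sd, cfg$thickness$noise_um,
           cfg$thickness$choroid_sd_um)
  if (any(sds < 0)) stop("all SD parameters must be >= 0")
  if (cfg$lesion$icga_median_area_mm2 <= 0) stop("lesion areas must be > 0")
  if (cfg$exudative_fraction < 0 || cfg$exudative_fraction > 1)
    stop("exudative_fraction must be in [0, 1]")
  structure(cfg, class = "mp_genconfig")
}

# healthy expected dB at given age/eccentricity under the configured plane
.normative_surface <- function(config, ecc, age) {
  nc <- config$normative
  nc$baseline_db - nc$ecc_slope * ecc + nc$age_slope * (age - nc$reference_age)
}

#' Simulate one 4-2 dB staircase threshold estimate
#'
#' Runs the two-reversal 4-2 staircase over the 0-20 dB range against a
#' logistic psychometric observer centered at the true threshold: steps
#' of 4 dB until the first response reversal, then 2 dB until the second;
#' the estimate is the last seen level. A stimulus seen at the 20 dB
#' ceiling returns 20; a field with no seen presentation returns 0.
#' Stochastic via the current RNG unless `slope = 0`, which gives the
#' deterministic step-function observer (seen iff level <= threshold).
#'
#' @param true_threshold True threshold in dB (0-20).
#' @param slope Psychometric slope in dB (0 = deterministic).
#' @param start Starting level (default 10 dB).
#' @return Measured threshold in dB (integer-valued on the staircase
#'   lattice).
#' @export
#' @examples
#' simulate_staircase(11, slope = 0)  # 10 (within one 2-dB step of truth)
simulate_staircase <- function(true_threshold, slope = 0.5, start = 10) {
  stopifnot(true_threshold >= 0, true_threshold <= 20)
  seen <- function(level) {
    if (slope == 0) level <= true_threshold
    else stats::runif(1) < stats::plogis((true_threshold - level) / slope)
  }
  level <- start
  step <- 4
  reversals <- 0L
  last_seen <- NA_real_
  prev <- NULL
  for (trial in 1:50) {
    s <- seen(level)
    if (s) last_seen <- level
    if (!is.null(prev) && s != prev) {
      reversals <- reversals + 1L
      if (reversals == 1L) step <- 2
      if (reversals == 2L) break
    }
    prev <- s
    if (s && level >= 20) return(20)      # ceiling: seen at the dimmest stimulus
    if (!s && level <= 0) return(if (is.na(last_seen)) 0 else last_seen)
    level <- min(20, max(0, level + if (s) step else -step))
  }
  if (is.na(last_seen)) 0 else last_seen
}

# measured field given true thresholds (vector), honouring the
# measurement config (test-retest noise, staircase quantization)
.measure_field <- function(true_db, config) {
  mc <- config$measurement
  t_obs <- true_db + stats::rnorm(length(true_db), 0, mc$test_retest_sd)
  t_obs <- pmin(20, pmax(0, t_obs))
  if (mc$staircase) {
    vapply(t_obs, simulate_staircase, 0, slope = mc$psychometric_slope)
  } else {
    t_obs
  }
}

#' Generate a healthy normative cohort
#'
#' Draws `n` reliable healthy fields from the configured normative
#' surface: expected dB minus eccentricity and age effects plus Gaussian
#' between-eye noise, clamped to 0-20 dB and staircase-quantized when
#' measurement simulation is on. Ages are uniform on `age_range`.
#'
#' @param config A [generator_config()].
#' @param n Number of eyes (>= 30 for downstream fitting).
#' @param age_range Age range (years) of the healthy cohort.
#' @param grid An [mp_grid()].
#' @param seed Optional seed (set once before all draws).
#' @return List of [sensitivity_field()] objects.
#' @export
generate_normative_cohort <- function(config, n, age_range = c(45, 85),
                                      grid = mp_grid(), seed = NULL) {
  stopifnot(inherits(config, "mp_genconfig"))
  if (!is.null(seed)) set.seed(seed)
  ecc <- grid$locations$ecc
  lapply(seq_len(n), function(i) {
    age <- stats::runif(1, age_range[1], age_range[2])
    true_db <- .normative_surface(config, ecc, age) +
      stats::rnorm(56, 0, config$normative$resid_sd)
    true_db <- pmin(20, pmax(0, true_db))
    vals <- if (config$measurement$staircase) {
      vapply(true_db, simulate_staircase, 0,
             slope = config$measurement$psychometric_slope)
    } else true_db
    sensitivity_field(vals, age = age,
                      laterality = sample(c("OD", "OS"), 1),
                      fp_rate = stats::runif(1, 0, 0.1))
  })
}

# smooth periodic field from low-order Fourier harmonics, evaluated at
# angles ang; sd scales the pointwise spread
.smooth_periodic <- function(ang, sd, harmonics = 2:5) {
  if (sd == 0) return(numeric(length(ang)))
  f <- numeric(length(ang))
  w <- 1 / harmonics
  w <- w / sqrt(sum(w^2) / 2)  # unit pointwise variance before scaling
  for (k in seq_along(harmonics)) {
    f <- f + sd * w[k] * (stats::rnorm(1) * cos(harmonics[k] * ang) +
                          stats::rnorm(1) * sin(harmonics[k] * ang))
  }
  f
}

# star-shaped ring with given area (deg^2) around a center
.star_ring <- function(center, area_deg2, irregularity, n_vertices) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  logr <- .smooth_periodic(ang, irregularity)
  r <- exp(logr)
  a0 <- abs(.ring_signed_area(cbind(r * cos(ang), r * sin(ang))))
  r <- r * sqrt(area_deg2 / a0)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

#' Generate a co-registered ICGA/OCT lesion polygon pair
#'
#' The ICGA lesion is a star-shaped polygon (radial log-Gaussian spline)
#' scaled to a lognormally sampled target area; the OCT lesion is the
#' same boundary radially dilated by a sampled margin plus independent
#' smooth boundary noise, so the OCT set is mostly -- but with noise not
#' strictly -- a superset of the ICGA set. Both are centered near the
#' fovea with jitter. With irregularity, dilation and noise all zero the
#' two polygons are identical circles.
#'
#' @param config A [generator_config()].
#' @param exudative Whether the eye has exudative change (scales the
#'   sampled area up; non-exudative eyes are scaled down symmetrically).
#' @param seed Optional seed.
#' @return List with elements `icga` and `oct` ([lesion_polygon()]s).
#' @export
generate_lesion_pair <- function(config, exudative = FALSE, seed = NULL) {
  stopifnot(inherits(config, "mp_genconfig"))
  if (!is.null(seed)) set.seed(seed)
  lc <- config$lesion
  median_deg2 <- lc$icga_median_area_mm2 / config$mm_per_degree^2
  meanlog <- log(median_deg2) +
    (if (exudative) 1 else -1) * log(lc$exudative_area_scale)
  area <- stats::rlnorm(1, meanlog, lc$area_sdlog)
  center <- stats::rnorm(2, 0, lc$center_jitter_deg)
  icga_ring <- .star_ring(center, area, lc$irregularity, lc$n_vertices)
  # radial dilation + smooth boundary noise relative to the shared center
  ang <- atan2(icga_ring[, 2] - center[2], icga_ring[, 1] - center[1])
  r <- sqrt((icga_ring[, 1] - center[1])^2 + (icga_ring[, 2] - center[2])^2)
  margin <- if (lc$oct_dilation_deg > 0)
    stats::rlnorm(1, log(lc$oct_dilation_deg), lc$oct_dilation_sdlog) else 0
  r_oct <- pmax(r + margin + .smooth_periodic(ang, lc$boundary_noise_deg),
                0.2 * r)
  oct_ring <- cbind(center[1] + r_oct * cos(ang),
                    center[2] + r_oct * sin(ang))
  # pull overlong vertices radially inside the representable +-15 deg
  # domain; per-vertex radial shrink keeps the ring star-shaped (simple)
  shrink <- function(ring) {
    if (all(abs(ring) <= 14.9)) return(ring)
    rr <- cbind(ring[, 1] - center[1], ring[, 2] - center[2])
    room <- 14.9 - pmax(abs(center[1]), abs(center[2]))
    sc <- pmin(1, room / pmax(abs(rr[, 1]), abs(rr[, 2])))
    cbind(center[1] + sc * rr[, 1], center[2] + sc * rr[, 2])
  }
  icga_ring <- shrink(icga_ring)
  oct_ring <- shrink(oct_ring)
  list(icga = lesion_polygon(icga_ring, "ICGA"),
       oct = lesion_polygon(oct_ring, "OCT"))
}

#' Generate one synthetic PCV eye
#'
#' Composes the structure-function model the pipeline assumes: lesion
#' polygon pair, functional depression (full depth at locations of the
#' mapped OCT set, shallower probabilistic halo within `halo_width_deg`
#' beyond the OCT boundary), measurement noise and staircase
#' quantization, retinal thickening inside the lesion coupled to the
#' depression, and a truncated-Normal subfoveal choroid. The generating
#' truth (depression map, mapped sets, halo picks) is retained in
#' `$ground_truth`.
#'
#' @param config A [generator_config()].
#' @param grid An [mp_grid()].
#' @param eye_id Identifier.
#' @param exudative Exudative status; drawn from
#'   `config$exudative_fraction` when `NULL`.
#' @param seed Optional seed.
#' @return Object of class `mp_eye`: `eye_id`, `field`
#'   ([sensitivity_field()]), `polygons` (list `icga`, `oct`),
#'   `thickness` (list `total_retinal_um` (56, `NA` beyond 7 deg),
#'   `subfoveal_choroid_um`), `exudative`, `va_logmar`, `ground_truth`.
#' @export
generate_pcv_eye <- function(config, grid = mp_grid(), eye_id = "eye_01",
                             exudative = NULL, seed = NULL) {
  stopifnot(inherits(config, "mp_genconfig"), inherits(grid, "mp_grid"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(exudative))
    exudative <- stats::runif(1) < config$exudative_fraction
  loc <- grid$locations
  age <- stats::runif(1, config$age_range[1], config$age_range[2])
  polys <- generate_lesion_pair(config, exudative = exudative)
  vh <- config$vertical_halfwidth
  oct_set <- map_lesion(polys$oct, grid, vh)
  icga_set <- map_lesion(polys$icga, grid, vh)

  dc <- config$depression
  depression <- numeric(56)
  depression[oct_set + 1L] <- dc$depth_db
  halo_set <- integer(0)
  if (dc$halo_width_deg > 0 && dc$halo_depth_db > 0) {
    outside <- setdiff(loc$id, oct_set)
    d_out <- vapply(outside + 1L, function(i)
      .dist_point_region(loc$x[i], loc$y[i], polys$oct$rings), 0)
    cand <- outside[d_out <= dc$halo_width_deg]
    picked <- cand[stats::runif(length(cand)) < dc$halo_prob]
    depression[picked + 1L] <- dc$halo_depth_db
    halo_set <- sort(picked)
  }

  true_db <- pmin(20, pmax(0, .normative_surface(config, loc$ecc, age) -
                             depression))
  values <- .measure_field(true_db, config)
  field <- sensitivity_field(
    values, age = age, laterality = sample(c("OD", "OS"), 1),
    fp_rate = stats::runif(1, config$measurement$fp_rate_range[1],
                           config$measurement$fp_rate_range[2]))

  tc <- config$thickness
  thick <- rep(NA_real_, 56)
  in7 <- loc$ecc <= 7
  thick[in7] <- tc$baseline_um +
    tc$lesion_thickening_um * (loc$id[in7] %in% oct_set) +
    tc$pd_coupling_um_per_db * depression[in7] +
    stats::rnorm(sum(in7), 0, tc$noise_um)
  choroid <- NA_real_
  if (stats::runif(1) < tc$choroid_available_fraction) {
    central <- loc$ecc <= 1.4
    repeat {
      choroid <- stats::rnorm(1, tc$choroid_mean_um +
                                tc$choroid_pd_coupling *
                                  mean(depression[central]),
                              tc$choroid_sd_um)
      if (choroid > 0) break
    }
  }
  va <- round(pmax(0, stats::rnorm(1, 0.2 + 0.1 * exudative, 0.15)), 2)

  structure(list(
    eye_id = eye_id, field = field,
    polygons = list(icga = polys$icga, oct = polys$oct),
    thickness = list(total_retinal_um = thick,
                     subfoveal_choroid_um = choroid),
    exudative = exudative, va_logmar = va,
    ground_truth = list(depression = depression,
                        depressed_set = sort(loc$id[depression > 0]),
                        oct_set = oct_set, icga_set = icga_set,
                        halo_set = halo_set, age = age,
                        true_db = true_db)),
    class = "mp_eye")
}

#' @export
print.mp_eye <- function(x, ...) {
  cat(if (!is.null(x$ground_truth)) "Synthetic eye" else "Eye",
      x$eye_id, "- age", round(x$field$age),
      if (x$exudative) "(exudative)" else "(non-exudative)", "\n")
  invisible(x)
}

#' Generate a synthetic PCV cohort
#'
#' Seeds the RNG from `config$seed` and draws `config$n_eyes` eyes with
#' [generate_pcv_eye()]. Exudative status is assigned exactly
#' (`round(fraction * n)` eyes, shuffled) or by Bernoulli draws per
#' `config$exudative_exact`. Fully reproducible: the same config yields
#' an identical cohort.
#'
#' @param config A [generator_config()].
#' @param grid An [mp_grid()].
#' @return Object of class `mp_cohort`: list of `mp_eye` with the config
#'   in attribute `config`.
#' @export
generate_cohort <- function(config = generator_config(), grid = mp_grid()) {
  stopifnot(inherits(config, "mp_genconfig"))
  set.seed(config$seed)
  n <- config$n_eyes
  exud <- if (n == 0) logical(0)
  else if (config$exudative_exact) {
    k <- round(config$exudative_fraction * n)
    sample(rep(c(TRUE, FALSE), c(k, n - k)))
  } else {
    stats::runif(n) < config$exudative_fraction
  }
  eyes <- lapply(seq_len(n), function(i)
    generate_pcv_eye(config, grid, eye_id = sprintf("eye_%02d", i),
                     exudative = exud[i]))
  structure(eyes, class = "mp_cohort", config = config)
}

#' @export
print.mp_cohort <- function(x, ...) {
  cat("Synthetic PCV cohort:", length(x), "eyes (",
      sum(vapply(x, `[[`, TRUE, "exudative")), "exudative ), seed",
      attr(x, "config")$seed, "\n")
  invisible(x)
}
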