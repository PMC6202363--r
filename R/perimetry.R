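#' One eye's microperimetric sensitivity field
#'
#' Bundles the 56 differential light sensitivity (DLS) thresholds measured
#' with a 4-2 dB staircase (0-20 dB dynamic range, `NA` = not measured)
#' with the demographics the normative analysis needs.
#'
#' @param values Numeric vector, length 56, dB in \[0, 20\] or `NA`,
#'   ordered by grid location id.
#' @param age Age in years.
#' @param laterality `"OD"` (right) or `"OS"` (left). Analysis is always
#'   in right-eye convention; left eyes are mirrored at ingest.
#' @param fp_rate Fraction of false-positive catch trials answered
#'   incorrectly, in \[0, 1\].
#' @return Object of class `mp_field`.
#' @export
sensitivity_field <- function(values, age, laterality = c("OD", "OS"),
                              fp_rate = 0) {
  laterality <- match.arg(laterality)
  values <- as.numeric(values)
  if (length(values) != 56)
    stop("sensitivity values must have length 56")
  bad <- which(!is.na(values) & (values < 0 | values > 20))
  if (length(bad))
    stop("sensitivity out of the 0-20 dB range at location(s) ",
         paste(bad - 1L, collapse = ", "))
  if (!is.numeric(age) || length(age) != 1 || age < 0)
    stop("age must be a single non-negative number")
  if (fp_rate < 0 || fp_rate > 1)
    stop("false-positive rate must be in [0, 1]")
  structure(list(values = values, age = age, laterality = laterality,
                 fp_rate = fp_rate), class = "mp_field")
}

#' Reliability of a microperimetry examination
#'
#' A field is reliable when fewer than 15% of false-positive catch trials
#' were answered incorrectly (strict inequality: exactly 15% fails).
#'
#' @param field An [sensitivity_field()].
#' @return `TRUE` if reliable.
#' @export
check_reliability <- function(field) {
  stopifnot(inherits(field, "mp_field"))
  field$fp_rate < 0.15
}

#' Fit the age- and eccentricity-referenced normative model
#'
#' Per grid location, regresses healthy DLS on age (ordinary least
#' squares), giving the expected normal sensitivity at any age; the
#' residual spread is summarised by empirical per-location quantiles of
#' the Total Deviation (TD) residuals and, after general-height removal,
#' of the Pattern Deviation (PD) values, at probability levels 5, 2 and
#' 1%. Quantiles are order statistics with linear interpolation
#' (`quantile` type 7), not Gaussian approximations; the residual SD is
#' floored at 0.5 dB so zero-variance locations stay usable.
#'
#' @param cohort List of [sensitivity_field()] objects from healthy eyes
#'   (at least 30; ages must vary, ideally spanning 20+ years; at least 10
#'   non-missing values per location).
#' @param gh_prob Percentile of TD used as the general height (default
#'   0.85).
#' @return Object of class `mp_normative`: per-location `intercept`,
#'   `slope`, `resid_sd`; `td_q` and `pd_q` 56 x 3 matrices (columns
#'   `p5`, `p2`, `p1`); `age_range`; `n`.
#' @export
fit_normative <- function(cohort, gh_prob = 0.85) {
  if (length(cohort) < 30)
    stop("normative cohort must contain at least 30 eyes (got ",
         length(cohort), ")")
  stopifnot(all(vapply(cohort, inherits, TRUE, "mp_field")))
  ages <- vapply(cohort, `[[`, 0, "age")
  if (diff(range(ages)) == 0)
    stop("degenerate age range: all cohort ages are equal")
  if (diff(range(ages)) < 20)
    warning("normative cohort ages span less than 20 years; ",
            "age extrapolation will be unstable")
  Y <- t(vapply(cohort, `[[`, numeric(56), "values"))  # eyes x locations
  intercept <- slope <- resid_sd <- numeric(56)
  resids <- matrix(NA_real_, nrow(Y), 56)
  for (j in 1:56) {
    ok <- !is.na(Y[, j])
    if (sum(ok) < 10)
      stop("location ", j - 1L, " has fewer than 10 non-missing values (",
           sum(ok), ")")
    fit <- stats::lm.fit(cbind(1, ages[ok]), Y[ok, j])
    intercept[j] <- fit$coefficients[1]
    slope[j] <- fit$coefficients[2]
    resids[ok, j] <- fit$residuals
    resid_sd[j] <- max(sqrt(sum(fit$residuals^2) / max(sum(ok) - 2, 1)), 0.5)
  }
  probs <- c(p5 = 0.05, p2 = 0.02, p1 = 0.01)
  td_q <- t(apply(resids, 2, stats::quantile, probs = probs, na.rm = TRUE,
                  names = FALSE))
  # PD residuals: general height removed per eye before pooling
  gh <- apply(resids, 1, stats::quantile, probs = gh_prob, na.rm = TRUE,
              names = FALSE)
  pd_resids <- resids - gh
  pd_q <- t(apply(pd_resids, 2, stats::quantile, probs = probs, na.rm = TRUE,
                  names = FALSE))
  colnames(td_q) <- colnames(pd_q) <- names(probs)
  structure(list(intercept = intercept, slope = slope, resid_sd = resid_sd,
                 td_q = td_q, pd_q = pd_q, age_range = range(ages),
                 gh_prob = gh_prob, n = length(cohort),
                 gh_estimator = sprintf("%gth percentile of TD", 100 * gh_prob)),
            class = "mp_normative")
}

#' Analytic normative model from generator parameters
#'
#' Builds an `mp_normative` object directly from the known parameters of
#' the synthetic normative surface (see [generator_config()]) instead of
#' fitting a cohort: expected dB is the configured plane in age and
#' eccentricity, and the deviation quantiles are Gaussian quantiles of the
#' configured residual SD. Useful as ground truth when validating the
#' fitting and flagging machinery.
#'
#' @param config A [generator_config()].
#' @param grid An [mp_grid()].
#' @return Object of class `mp_normative`.
#' @export
normative_from_config <- function(config, grid) {
  stopifnot(inherits(config, "mp_genconfig"), inherits(grid, "mp_grid"))
  nc <- config$normative
  ecc <- grid$locations$ecc
  intercept <- nc$baseline_db - nc$ecc_slope * ecc -
    nc$age_slope * nc$reference_age
  slope <- rep(nc$age_slope, 56)
  sdv <- rep(max(nc$resid_sd, 0.5), 56)
  probs <- c(p5 = 0.05, p2 = 0.02, p1 = 0.01)
  q <- outer(sdv, stats::qnorm(probs))
  colnames(q) <- names(probs)
  structure(list(intercept = intercept, slope = slope, resid_sd = sdv,
                 td_q = q, pd_q = q, age_range = c(40, 90), gh_prob = 0.85,
                 n = 0L, gh_estimator = "85th percentile of TD (analytic)"),
            class = "mp_normative")
}

#' @export
print.mp_normative <- function(x, ...) {
  cat("Microperimetry normative model (", x$n, " eyes, ages ",
      round(x$age_range[1]), "-", round(x$age_range[2]), ")\n", sep = "")
  cat("  mean age slope:", round(mean(x$slope), 3), "dB/yr;",
      "median residual SD:", round(stats::median(x$resid_sd), 2), "dB\n")
  cat("  general height:", x$gh_estimator, "\n")
  invisible(x)
}

#' Expected normal sensitivity at a given age
#'
#' @param object An `mp_normative` model.
#' @param age Age in years.
#' @param ... Unused.
#' @return Numeric vector of 56 expected dB values.
#' @export
predict.mp_normative <- function(object, age, ...) {
  object$intercept + object$slope * age
}

#' Total Deviation map
#'
#' Measured sensitivity minus the age-referenced normal expectation,
#' location by location. Ages outside the model's reference span are
#' extrapolated with a warning.
#'
#' @param field A [sensitivity_field()].
#' @param model An [fit_normative()] model.
#' @return Numeric vector of 56 TD values (dB, `NA` where unmeasured),
#'   class `mp_td`.
#' @export
total_deviation <- function(field, model) {
  stopifnot(inherits(field, "mp_field"), inherits(model, "mp_normative"))
  if (field$age < model$age_range[1] || field$age > model$age_range[2])
    warning("age ", field$age, " outside the normative reference span (",
            model$age_range[1], "-", model$age_range[2], "); extrapolating")
  structure(field$values - predict(model, field$age), class = "mp_td")
}

#' Pattern Deviation map
#'
#' Removes the diffuse component of loss: the general height is the 85th
#' percentile of the non-missing TD values (linear-interpolation order
#' statistic) and PD is TD minus the general height, so a uniform
#' depression of the whole field leaves PD at zero while focal defects
#' remain.
#'
#' @param td An `mp_td` map with at least 10 non-missing values.
#' @param gh_prob General-height percentile (default 0.85).
#' @return Numeric vector of 56 PD values, class `mp_pd`, with the scalar
#'   general height in attribute `general_height`.
#' @export
pattern_deviation <- function(td, gh_prob = 0.85) {
  stopifnot(inherits(td, "mp_td"))
  v <- unclass(td)
  if (sum(!is.na(v)) < 10)
    stop("Pattern Deviation needs at least 10 non-missing TD values")
  gh <- stats::quantile(v, probs = gh_prob, na.rm = TRUE, names = FALSE,
                        type = 7)
  structure(v - gh, general_height = gh, class = "mp_pd")
}

#' Probability map of deviation values
#'
#' Flags each location at the most extreme probability level whose
#' empirical normative quantile the deviation reaches: `p1` if deviation
#' <= 1% quantile, else `p2` (<= 2%), else `p5` (<= 5%), else `normal`.
#' Thresholds are inclusive, so a deviation exactly at a quantile is
#' flagged. Unmeasured locations are conservatively `normal`. TD maps are
#' referenced to the TD quantiles and PD maps to the PD quantiles.
#'
#' @param dev An `mp_td` or `mp_pd` map.
#' @param model An [fit_normative()] model.
#' @return Factor of length 56 with ordered levels
#'   `normal < p5 < p2 < p1`, class `mp_pmap`, attribute `type`.
#' @export
probability_map <- function(dev, model) {
  stopifnot(inherits(model, "mp_normative"))
  type <- if (inherits(dev, "mp_pd")) "pd"
          else if (inherits(dev, "mp_td")) "td"
          else stop("dev must be an mp_td or mp_pd map")
  q <- if (type == "pd") model$pd_q else model$td_q
  v <- unclass(dev)
  lev <- rep("normal", 56)
  lev[!is.na(v) & v <= q[, "p5"]] <- "p5"
  lev[!is.na(v) & v <= q[, "p2"]] <- "p2"
  lev[!is.na(v) & v <= q[, "p1"]] <- "p1"
  structure(factor(lev, levels = c("normal", "p5", "p2", "p1"),
                   ordered = TRUE),
            type = type, class = c("mp_pmap", "ordered", "factor"))
}

#' Detect visual field loss by the contiguity criterion
#'
#' Visual field loss is defined as 3 or more contiguous locations with PD
#' probability level <= 5%. Flagged locations are grouped into connected
#' components of the grid's contiguity graph and the union of all
#' components of size >= `min_cluster` is returned.
#'
#' @param pmap An `mp_pmap` (from a PD map).
#' @param grid An [mp_grid()].
#' @param min_cluster Minimum component size (default 3).
#' @return Sorted integer vector of 0-based location ids (the
#'   microperimetry abnormality set).
#' @export
detect_field_loss <- function(pmap, grid, min_cluster = 3) {
  stopifnot(inherits(pmap, "mp_pmap"), inherits(grid, "mp_grid"))
  flagged <- which(unclass(pmap) >= 2) # p5 or worse
  if (length(flagged) == 0) return(integer(0))
  adj <- grid$adjacency + 1L  # to 1-based
  keep_e <- adj[, 1] %in% flagged & adj[, 2] %in% flagged
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(adj[keep_e, , drop = FALSE]),
    directed = FALSE,
    vertices = data.frame(name = flagged))
  comp <- igraph::components(g)
  big <- which(comp$csize >= min_cluster)
  ids <- as.integer(igraph::V(g)$name[comp$membership %in% big])
  sort(ids - 1L)
}

#' Summary indices of one eye's field
#'
#' @param field A [sensitivity_field()].
#' @param td,pd Deviation maps from the same eye.
#' @param pmap PD probability map from the same eye.
#' @return One-row data.frame: `mean_sensitivity`, `mean_td`, `mean_pd`
#'   (dB, over non-missing locations), `n_pd_defects_p1` (locations at
#'   level p1).
#' @export
summarize_field <- function(field, td, pd, pmap) {
  data.frame(
    mean_sensitivity = mean(field$values, na.rm = TRUE),
    mean_td = mean(unclass(td), na.rm = TRUE),
    mean_pd = mean(unclass(pd), na.rm = TRUE),
    n_pd_defects_p1 = sum(unclass(pmap) == 4L)
  )
}
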