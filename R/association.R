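.slope_sign <- function(b, tol = 1e-12) {
  if (is.na(b) || abs(b) <= tol) "zero" else if (b < 0) "negative" else "positive"
}

# simple OLS of y on x across eyes; returns the association result shape
.ols_association <- function(x, y, region) {
  n <- length(x)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    # zero-variance regressor (or response): no association estimable
    return(structure(list(r_squared = 0, p_value = NA_real_,
                          slope = 0, slope_sign = "zero",
                          n_eyes = n, region = region),
                     class = "mp_association"))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  df <- n - 2
  fstat <- if (rss > 0) (tss - rss) / (rss / df) else Inf
  p <- if (is.finite(fstat)) stats::pf(fstat, 1, df, lower.tail = FALSE) else 0
  structure(list(r_squared = r2, p_value = p,
                 slope = fit$coefficients[[2]],
                 slope_sign = .slope_sign(fit$coefficients[[2]]),
                 n_eyes = n, region = region),
            class = "mp_association")
}

#' @export
print.mp_association <- function(x, ...) {
  cat("Structure-function association [", x$region, "]: R^2 = ",
      signif(x$r_squared, 3), ", p = ",
      ifelse(is.na(x$p_value), "NA", format.pval(x$p_value, digits = 3)),
      ", slope ", x$slope_sign, ", n = ", x$n_eyes, " eyes\n", sep = "")
  invisible(x)
}

#' Pattern Deviation versus retinal thickness across eyes
#'
#' For each eye, sums the PD values and the total retinal thicknesses
#' over the locations of the chosen region that have a valid thickness
#' (thickness is only measured out to 7 deg eccentricity; locations
#' without thickness are skipped, not imputed), then regresses the PD sum
#' on the thickness sum across eyes by ordinary least squares. Focal
#' depression co-occurring with retinal thickening shows up as a negative
#' slope.
#'
#' @param analyses List of [analyze_eye()] results.
#' @param region `"abnormal"` (each eye's detected field-loss set) or
#'   `"concordant"` (the three-way intersection of the eye's MP, OCT and
#'   ICGA sets).
#' @return Object of class `mp_association`: `r_squared`, `p_value`,
#'   `slope`, `slope_sign`, `n_eyes`, `region`.
#' @export
pd_thickness_association <- function(analyses,
                                     region = c("abnormal", "concordant")) {
  region <- match.arg(region)
  xs <- ys <- numeric(0)
  for (a in analyses) {
    ids <- if (region == "abnormal") a$sets$mp
           else Reduce(intersect, a$sets)
    thk <- a$eye$thickness$total_retinal_um
    ids <- ids[!is.na(thk[ids + 1L])]
    if (length(ids) == 0) next
    xs <- c(xs, sum(thk[ids + 1L]))
    ys <- c(ys, sum(unclass(a$pd)[ids + 1L], na.rm = TRUE))
  }
  if (length(xs) == 0)
    stop("no eye has a non-empty ", region,
         " region with valid thickness coverage")
  if (length(xs) < 3)
    stop("need at least 3 eyes with non-empty regions (got ", length(xs), ")")
  .ols_association(xs, ys, region)
}

#' Subfoveal choroidal thickness versus central Pattern Deviation
#'
#' Regresses the mean PD of the central locations (eccentricity <=
#' `max_ecc`, default 1.4 deg: the innermost ring of the default grid) on
#' the subfoveal choroidal thickness across eyes. Eyes without a
#' choroidal measurement are excluded.
#'
#' @param analyses List of [analyze_eye()] results.
#' @param grid The [mp_grid()] the analyses used.
#' @param max_ecc Central eccentricity limit in degrees (inclusive).
#' @return Object of class `mp_association` with region `"central"`.
#' @export
choroid_pd_association <- function(analyses, grid, max_ecc = 1.4) {
  central <- which(grid$locations$ecc <= max_ecc)
  if (length(central) == 0)
    stop("configuration error: no grid locations within ", max_ecc,
         " degrees eccentricity")
  xs <- ys <- numeric(0)
  for (a in analyses) {
    ch <- a$eye$thickness$subfoveal_choroid_um
    if (is.null(ch) || is.na(ch)) next
    xs <- c(xs, ch)
    ys <- c(ys, mean(unclass(a$pd)[central], na.rm = TRUE))
  }
  if (length(xs) < 3)
    stop("need at least 3 eyes with a choroidal measurement (got ",
         length(xs), ")")
  .ols_association(xs, ys, "central")
}
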