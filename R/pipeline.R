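#' Analyze one eye through the full structure-function pipeline
#'
#' Computes, for one eye: the Total Deviation map, the Pattern Deviation
#' map, the PD probability map, the microperimetric field-loss set
#' ([detect_field_loss()]), the projected OCT and ICGA abnormality sets
#' ([map_lesion()]), the per-eye concordance row ([concordance_eye()])
#' and the field summary indices.
#'
#' @param eye An `mp_eye`.
#' @param model An [fit_normative()] model.
#' @param grid An [mp_grid()].
#' @param vertical_halfwidth Vertical analysis extent (5 or 10 deg),
#'   applied to all three modality sets alike.
#' @param min_cluster Contiguity criterion for field loss (default 3).
#' @param threshold_pct Greater-extent threshold (default 20).
#' @return Object of class `mp_eye_analysis`: `eye`, `td`, `pd`, `pmap`,
#'   `sets` (list `mp`, `oct`, `icga` of 0-based ids), `summary`,
#'   `concordance` (one-row data.frame).
#' @export
analyze_eye <- function(eye, model, grid = mp_grid(),
                        vertical_halfwidth = 10, min_cluster = 3,
                        threshold_pct = 20) {
  stopifnot(inherits(eye, "mp_eye"), inherits(model, "mp_normative"))
  td <- total_deviation(eye$field, model)
  pd <- pattern_deviation(td, gh_prob = model$gh_prob)
  pmap <- probability_map(pd, model)
  mp_set <- clip_to_extent(detect_field_loss(pmap, grid, min_cluster),
                           grid, vertical_halfwidth)
  oct_set <- map_lesion(eye$polygons$oct, grid, vertical_halfwidth)
  icga_set <- map_lesion(eye$polygons$icga, grid, vertical_halfwidth)
  structure(list(
    eye = eye, td = td, pd = pd, pmap = pmap,
    sets = list(mp = mp_set, oct = oct_set, icga = icga_set),
    summary = summarize_field(eye$field, td, pd, pmap),
    concordance = concordance_eye(mp_set, oct_set, icga_set,
                                  eye_id = eye$eye_id,
                                  threshold_pct = threshold_pct)),
    class = "mp_eye_analysis")
}

#' @export
print.mp_eye_analysis <- function(x, ...) {
  cat("Eye", x$eye$eye_id, "- field loss at",
      length(x$sets$mp), "locations; OCT", length(x$sets$oct),
      "; ICGA", length(x$sets$icga), "\n")
  cat("  three-way concordance:",
      round(x$concordance$conc3, 1), "%\n")
  invisible(x)
}

#' Run the full concordance pipeline over a cohort
#'
#' Fits or accepts a normative model, analyses every eye
#' ([analyze_eye()]), assembles the per-eye concordance table, the cohort
#' summary ([summarize_cohort()]) and the structure-function association
#' regressions, and (optionally) writes a per-eye CSV, a cohort summary
#' JSON and a human-readable report. Every threshold in effect is
#' recorded in the outputs. A stage failure aborts with the stage and eye
#' identified.
#'
#' @param cohort An `mp_cohort`, a list of `mp_eye`, or the path of a
#'   cohort manifest.
#' @param normative An `mp_normative` model, or a list of healthy
#'   [sensitivity_field()]s to fit one from.
#' @param grid An [mp_grid()].
#' @param vertical_halfwidth Vertical analysis extent (5 or 10 deg).
#' @param threshold_pct Greater-extent threshold (20, or 10 for the
#'   sensitivity analysis).
#' @param min_cluster Contiguity criterion for field loss.
#' @param out_dir Optional output directory.
#' @return Object of class `mp_results`: `per_eye` (data.frame),
#'   `summary` (`mp_cohort_summary`), `associations` (list `abnormal`,
#'   `concordant`, `choroid`), `analyses`, `params`.
#' @export
run_pipeline <- function(cohort, normative, grid = mp_grid(),
                         vertical_halfwidth = 10, threshold_pct = 20,
                         min_cluster = 3, out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort, grid)
  model <- if (inherits(normative, "mp_normative")) normative
           else fit_normative(normative)
  analyses <- lapply(cohort, function(eye) {
    tryCatch(
      analyze_eye(eye, model, grid, vertical_halfwidth, min_cluster,
                  threshold_pct),
      error = function(e) stop("stage per-eye analysis failed for eye ",
                               eye$eye_id, ": ", conditionMessage(e)))
  })
  per_eye <- do.call(rbind, lapply(analyses, function(a)
    cbind(a$concordance, a$summary,
          exudative = a$eye$exudative, row.names = NULL)))
  exud <- vapply(analyses, function(a) isTRUE(a$eye$exudative), TRUE)
  summary <- summarize_cohort(per_eye, exud)
  assoc <- list(
    abnormal = tryCatch(pd_thickness_association(analyses, "abnormal"),
                        error = function(e) NULL),
    concordant = tryCatch(pd_thickness_association(analyses, "concordant"),
                          error = function(e) NULL),
    choroid = tryCatch(choroid_pd_association(analyses, grid),
                       error = function(e) NULL))
  params <- list(vertical_halfwidth = vertical_halfwidth,
                 threshold_pct = threshold_pct, min_cluster = min_cluster,
                 pd_levels = c(5, 2, 1), gh_estimator = model$gh_estimator,
                 coverage_radii = c(inner = 0.7, outer = 1.4))
  res <- structure(list(per_eye = per_eye, summary = summary,
                        associations = assoc, analyses = analyses,
                        params = params),
                   class = "mp_results")
  if (!is.null(out_dir)) .write_results(res, out_dir)
  res
}

.write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$per_eye, file.path(out_dir, "per_eye.csv"),
                   row.names = FALSE)
  assoc <- lapply(res$associations, function(a)
    if (is.null(a)) NULL else unclass(a))
  jsonlite::write_json(
    list(schema_version = .SCHEMA_VERSION, params = res$params,
         groups = lapply(res$summary$groups, function(g)
           if (is.null(g)) NULL else list(
             n = g$n, stats = as.data.frame(g$stats),
             extent_counts = g$extent_counts)),
         contrasts = as.list(res$summary$contrasts),
         associations = assoc),
    file.path(out_dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = 10, na = "null")
  rep_file <- file.path(out_dir, "report.txt")
  con <- file(rep_file, open = "wt")
  on.exit(close(con))
  sink(con)
  cat("Structure-function concordance report\n")
  cat("=====================================\n")
  cat("Parameters: vertical extent +-", res$params$vertical_halfwidth,
      " deg; greater-extent threshold ", res$params$threshold_pct,
      "%; cluster criterion >= ", res$params$min_cluster,
      " contiguous locations; PD levels <= 5/2/1%; general height ",
      res$params$gh_estimator, "\n\n", sep = "")
  print(res$summary)
  cat("\nAssociations\n------------\n")
  for (a in res$associations) if (!is.null(a)) print(a)
  sink()
  invisible(rep_file)
}

#' @export
print.mp_results <- function(x, ...) {
  print(x$summary)
  cat("\n")
  for (a in x$associations) if (!is.null(a)) print(a)
  invisible(x)
}
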