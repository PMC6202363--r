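.as_set <- function(x) sort(unique(as.integer(x)))

#' Three-way concordance of abnormality sets
#'
#' Area of mutual overlap relative to the maximum total abnormal area of
#' the three modalities: `100 * |A n B n C| / |A u B u C|`. When all
#' three sets are empty the modalities agree on the absence of
#' abnormality and the concordance is defined as 100 (configurable).
#'
#' @param A,B,C Integer vectors of 0-based location ids over the same grid.
#' @param empty Value returned for an empty union (default 100).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' concordance3(1:3, 2:4, 3:5)  # 20
concordance3 <- function(A, B, C, empty = 100) {
  A <- .as_set(A); B <- .as_set(B); C <- .as_set(C)
  u <- union(union(A, B), C)
  if (length(u) == 0) return(empty)
  100 * length(intersect(intersect(A, B), C)) / length(u)
}

#' Pairwise concordance of abnormality sets
#'
#' `100 * |A n B| / |A u B|` (intersection over union, as a percentage);
#' an empty union is full agreement on absence (100 by default).
#'
#' @inheritParams concordance3
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' concordance2(1:4, 3:5)  # 40
concordance2 <- function(A, B, empty = 100) {
  A <- .as_set(A); B <- .as_set(B)
  u <- union(A, B)
  if (length(u) == 0) return(empty)
  100 * length(intersect(A, B)) / length(u)
}

#' Relative complement of one modality with respect to another
#'
#' The areal excess of modality A over modality B as a proportion of
#' their union: `100 * |A \ B| / |A u B|`; 0 for an empty union. For any
#' pair, `concordance2(A, B) + relative_complement_pct(A, B) +
#' relative_complement_pct(B, A) == 100`.
#'
#' @inheritParams concordance3
#' @param empty Value returned for an empty union (default 0).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' relative_complement_pct(1:6, 5:8)  # 50
relative_complement_pct <- function(A, B, empty = 0) {
  A <- .as_set(A); B <- .as_set(B)
  u <- union(A, B)
  if (length(u) == 0) return(empty)
  100 * length(setdiff(A, B)) / length(u)
}

#' Classify which modality has the greater areal extent
#'
#' A modality has a greater areal extent when its relative complement
#' exceeds `threshold_pct` of the union (strictly; the conventional
#' criterion is 20%, with 10% as a less conservative sensitivity
#' analysis). Both complements may exceed the threshold (`"both"`).
#'
#' @inheritParams concordance3
#' @param threshold_pct Threshold percentage in (0, 100), default 20.
#' @return One of `"A_greater"`, `"B_greater"`, `"both"`, `"neither"`.
#' @export
#' @examples
#' greater_extent(1:9, 7:9)       # "A_greater"
#' greater_extent(1:3, 1:3, 20)   # "neither"
greater_extent <- function(A, B, threshold_pct = 20) {
  if (!is.numeric(threshold_pct) || threshold_pct <= 0 || threshold_pct >= 100)
    stop("threshold_pct must be in (0, 100)")
  ca <- relative_complement_pct(A, B)
  cb <- relative_complement_pct(B, A)
  if (ca > threshold_pct && cb > threshold_pct) "both"
  else if (ca > threshold_pct) "A_greater"
  else if (cb > threshold_pct) "B_greater"
  else "neither"
}

#' Per-eye concordance metrics for the three modalities
#'
#' @param mp,oct,icga Abnormality sets (0-based ids) for microperimetry,
#'   SD-OCT and ICGA of one eye.
#' @param eye_id Identifier carried through to the output row.
#' @param threshold_pct Greater-extent threshold (default 20).
#' @return One-row data.frame with the three-way concordance, the three
#'   pairwise concordances, all six ordered relative complements, the
#'   three greater-extent classifications and the set sizes.
#' @export
concordance_eye <- function(mp, oct, icga, eye_id = NA_character_,
                            threshold_pct = 20) {
  data.frame(
    eye_id = eye_id,
    n_mp = length(.as_set(mp)), n_oct = length(.as_set(oct)),
    n_icga = length(.as_set(icga)),
    conc3 = concordance3(mp, oct, icga),
    conc_mp_icga = concordance2(mp, icga),
    conc_oct_icga = concordance2(oct, icga),
    conc_mp_oct = concordance2(mp, oct),
    comp_mp_icga = relative_complement_pct(mp, icga),
    comp_icga_mp = relative_complement_pct(icga, mp),
    comp_oct_icga = relative_complement_pct(oct, icga),
    comp_icga_oct = relative_complement_pct(icga, oct),
    comp_mp_oct = relative_complement_pct(mp, oct),
    comp_oct_mp = relative_complement_pct(oct, mp),
    extent_mp_icga = greater_extent(mp, icga, threshold_pct),
    extent_oct_icga = greater_extent(oct, icga, threshold_pct),
    extent_mp_oct = greater_extent(mp, oct, threshold_pct),
    stringsAsFactors = FALSE
  )
}

.median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  c(median = q[2], q25 = q[1], q75 = q[3])
}

.extent_counts <- function(cls) {
  c(A_greater = sum(cls == "A_greater") + sum(cls == "both"),
    B_greater = sum(cls == "B_greater") + sum(cls == "both"),
    both = sum(cls == "both"), neither = sum(cls == "neither"))
}

#' Cohort summary of concordance metrics
#'
#' Medians and interquartile ranges (25th/75th percentiles, linear
#' interpolation) of every concordance and complement metric, per group
#' (exudative / non-exudative / all eyes); counts of eyes per
#' greater-extent category for each modality pair (an eye classified
#' `both` contributes to each side and is also reported separately); and
#' two-sided Wilcoxon rank-sum contrasts of the areal extents between the
#' exudative groups (exact where sample sizes permit).
#'
#' @param results Data.frame of [concordance_eye()] rows.
#' @param exudative Logical vector, one flag per row of `results`.
#' @return Object of class `mp_cohort_summary`: list with `groups` (named
#'   list of per-group stats), `extent_counts`, `contrasts` (rank-sum p
#'   values for n_mp / n_oct / n_icga), `n`.
#' @export
summarize_cohort <- function(results, exudative = rep(FALSE, nrow(results))) {
  stopifnot(nrow(results) >= 1, length(exudative) == nrow(results))
  metric_cols <- c("conc3", "conc_mp_icga", "conc_oct_icga", "conc_mp_oct",
                   "comp_mp_icga", "comp_icga_mp", "comp_oct_icga",
                   "comp_icga_oct", "comp_mp_oct", "comp_oct_mp",
                   "n_mp", "n_oct", "n_icga")
  grp <- list(exudative = which(exudative),
              non_exudative = which(!exudative),
              all = seq_len(nrow(results)))
  groups <- lapply(grp, function(idx) {
    if (length(idx) == 0) return(NULL)
    sub <- results[idx, , drop = FALSE]
    stats <- t(vapply(metric_cols, function(m) .median_iqr(sub[[m]]),
                      numeric(3)))
    list(n = length(idx), stats = stats,
         extent_counts = list(
           mp_vs_icga = .extent_counts(sub$extent_mp_icga),
           oct_vs_icga = .extent_counts(sub$extent_oct_icga),
           mp_vs_oct = .extent_counts(sub$extent_mp_oct)))
  })
  contrasts <- NULL
  if (length(grp$exudative) >= 2 && length(grp$non_exudative) >= 2) {
    contrasts <- vapply(c("n_mp", "n_oct", "n_icga"), function(m) {
      suppressWarnings(stats::wilcox.test(
        results[[m]][exudative], results[[m]][!exudative],
        alternative = "two.sided")$p.value)
    }, 0)
  } else if (any(vapply(grp[1:2], length, 0L) == 0)) {
    warning("a group is empty; rank-sum contrasts skipped")
  }
  structure(list(groups = groups, contrasts = contrasts,
                 n = nrow(results)),
            class = "mp_cohort_summary")
}

#' @export
print.mp_cohort_summary <- function(x, digits = 1, ...) {
  cat("Cohort concordance summary (", x$n, " eyes)\n", sep = "")
  fmt <- function(v) sprintf("%.*f (%.*f, %.*f)", digits, v[1], digits,
                             v[2], digits, v[3])
  lab <- c(conc3 = "MP, SD-OCT, ICGA concordance (%)",
           conc_mp_icga = "MP, ICGA concordance (%)",
           conc_oct_icga = "SD-OCT, ICGA concordance (%)",
           conc_mp_oct = "MP, SD-OCT concordance (%)")
  for (gname in names(x$groups)) {
    g <- x$groups[[gname]]
    if (is.null(g)) next
    cat("\n[", gname, "] n = ", g$n, "\n", sep = "")
    for (m in names(lab))
      cat(sprintf("  %-32s median (IQR): %s\n", lab[m], fmt(g$stats[m, ])))
    ec <- g$extent_counts
    cat("  greater extent (eyes): MP>ICGA ", ec$mp_vs_icga["A_greater"],
        ", ICGA>MP ", ec$mp_vs_icga["B_greater"],
        "; OCT>ICGA ", ec$oct_vs_icga["A_greater"],
        ", ICGA>OCT ", ec$oct_vs_icga["B_greater"],
        "; MP>OCT ", ec$mp_vs_oct["A_greater"],
        ", OCT>MP ", ec$mp_vs_oct["B_greater"], "\n", sep = "")
  }
  if (!is.null(x$contrasts)) {
    cat("\nExudative vs non-exudative rank-sum p:",
        paste(names(x$contrasts),
              signif(x$contrasts, 2), sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}
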