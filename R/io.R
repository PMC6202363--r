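# File formats:
#   sensitivity.csv  eye_id,age,laterality,fp_rate,loc_0..loc_55  (dB, blank = missing)
#   thickness.csv    eye_id,subfoveal_choroid_um,thk_0..thk_55    (um, blank = missing)
#   polygons/<eye>.geojson  FeatureCollection, one feature per modality,
#                           coordinates in fovea-centered degrees
#   manifest.json    cohort id, schema version, config hash, file paths
# All tabular files are RFC-4180 CSV with a header row; left (OS) eyes are
# stored in their native orientation and mirrored to right-eye convention
# at ingest.

.SCHEMA_VERSION <- "1.0"

# mirror permutation: location id i maps to the id at (-x, y)
.mirror_permutation <- function(grid) {
  loc <- grid$locations
  key <- paste(round(loc$x, 6), round(loc$y, 6))
  mkey <- paste(round(-loc$x, 6), round(loc$y, 6))
  match(mkey, key)  # 1-based positions
}

.mirror_values <- function(v, grid) v[.mirror_permutation(grid)]

.mirror_polygon <- function(poly, grid) {
  rings <- lapply(poly$rings, function(r) {
    r[, 1] <- -r[, 1]
    r[rev(seq_len(nrow(r))), , drop = FALSE]  # keep winding orientation
  })
  lesion_polygon(rings, poly$modality)
}

# stable FNV-1a hash of a config (for the manifest)
.config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 10)
  bytes <- utf8ToInt(as.character(s)) %% 256
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h a double mod 2^32
    h <- h - h %% 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.loc_cols <- function(prefix) paste0(prefix, 0:55)

.write_polygons_geojson <- function(polys, path) {
  feat <- lapply(polys, function(p) {
    coords <- lapply(p$rings, function(r) {
      r <- rbind(r, r[1, ])  # close the ring
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(modality = p$modality),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "fovea-centered-degrees")),
             features = feat)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
}

.read_polygons_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  polys <- list()
  for (f in fc$features) {
    modality <- f$properties$modality
    if (!modality %in% c("ICGA", "OCT"))
      stop("polygon file ", path, ": unknown modality '", modality, "'")
    rings <- lapply(f$geometry$coordinates, function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt) unlist(pt)))
      .close_ring(m)
    })
    polys[[modality]] <- lesion_polygon(rings, modality)
  }
  polys
}

#' Write a cohort to disk
#'
#' Serializes a cohort in the pipeline's file formats (see above) plus,
#' for synthetic cohorts, a `ground_truth.json`, and a `manifest.json`
#' recording the schema version, the generator seed and a hash of the
#' configuration. Left eyes are written in their native (unmirrored)
#' orientation.
#'
#' @param cohort An `mp_cohort` or list of `mp_eye`.
#' @param dir Output directory (created if needed).
#' @param grid The [mp_grid()] the cohort lives on.
#' @param cohort_id Identifier recorded in the manifest.
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, grid = mp_grid(),
                         cohort_id = "cohort") {
  dir.create(file.path(dir, "polygons"), recursive = TRUE,
             showWarnings = FALSE)
  perm <- .mirror_permutation(grid)
  sens <- thk <- NULL
  poly_files <- character(0)
  exud <- logical(0)
  gt <- list()
  for (eye in cohort) {
    os <- eye$field$laterality == "OS"
    vals <- eye$field$values
    tvals <- eye$thickness$total_retinal_um
    polys <- eye$polygons
    if (os) {
      vals <- vals[perm]; tvals <- tvals[perm]
      polys <- lapply(polys, .mirror_polygon, grid = grid)
    }
    srow <- data.frame(eye_id = eye$eye_id, age = eye$field$age,
                       laterality = eye$field$laterality,
                       fp_rate = eye$field$fp_rate)
    srow[.loc_cols("loc_")] <- as.list(vals)
    sens <- rbind(sens, srow)
    trow <- data.frame(eye_id = eye$eye_id,
                       subfoveal_choroid_um = eye$thickness$subfoveal_choroid_um)
    trow[.loc_cols("thk_")] <- as.list(tvals)
    thk <- rbind(thk, trow)
    pf <- file.path("polygons", paste0(eye$eye_id, ".geojson"))
    .write_polygons_geojson(polys, file.path(dir, pf))
    poly_files[eye$eye_id] <- pf
    exud[eye$eye_id] <- isTRUE(eye$exudative)
    if (!is.null(eye$ground_truth))
      gt[[eye$eye_id]] <- eye$ground_truth[c("depression", "depressed_set",
                                             "oct_set", "icga_set",
                                             "halo_set", "age")]
  }
  utils::write.csv(sens, file.path(dir, "sensitivity.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(thk, file.path(dir, "thickness.csv"),
                   row.names = FALSE, na = "")
  if (length(gt))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = 10, na = "null")
  config <- attr(cohort, "config")
  manifest <- list(
    schema_version = .SCHEMA_VERSION, cohort_id = cohort_id,
    seed = if (!is.null(config)) config$seed else NA,
    config_hash = if (!is.null(config)) .config_hash(config) else NA,
    sensitivity_csv = "sensitivity.csv", thickness_csv = "thickness.csv",
    polygon_files = as.list(poly_files), exudative = as.list(exud))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Read a cohort from a manifest
#'
#' Reads and validates the files referenced by a cohort manifest. Left
#' (OS) eyes are mirrored to right-eye convention (an audit note is
#' attached to each mirrored eye). Eyes failing the reliability criterion
#' (false-positive rate >= 15%) are excluded with a warning unless
#' `keep_unreliable = TRUE`, in which case they are only flagged.
#' Out-of-range values and malformed polygons raise errors identifying
#' the offending cell or ring.
#'
#' @param manifest Path to `manifest.json`.
#' @param grid The [mp_grid()].
#' @param keep_unreliable Keep unreliable eyes (flagged, not excluded).
#' @return List of `mp_eye` objects (no ground truth), with attribute
#'   `manifest`.
#' @export
read_cohort <- function(manifest, grid = mp_grid(),
                        keep_unreliable = FALSE) {
  man <- jsonlite::read_json(manifest)
  if (is.null(man$schema_version) || man$schema_version != .SCHEMA_VERSION)
    stop("unrecognized cohort schema version: ",
         format(man$schema_version))
  dir <- dirname(manifest)
  sens <- utils::read.csv(file.path(dir, man$sensitivity_csv))
  thk <- utils::read.csv(file.path(dir, man$thickness_csv))
  perm <- .mirror_permutation(grid)
  eyes <- list()
  for (i in seq_len(nrow(sens))) {
    id <- sens$eye_id[i]
    vals <- as.numeric(sens[i, .loc_cols("loc_")])
    bad <- which(!is.na(vals) & (vals < 0 | vals > 20))
    if (length(bad))
      stop("sensitivity.csv row ", i, " (", id, "): value out of 0-20 dB ",
           "range in column loc_", bad[1] - 1L)
    ti <- match(id, thk$eye_id)
    tvals <- rep(NA_real_, 56)
    choroid <- NA_real_
    if (!is.na(ti)) {
      tvals <- as.numeric(thk[ti, .loc_cols("thk_")])
      if (any(!is.na(tvals) & tvals <= 0))
        stop("thickness.csv (", id, "): non-positive thickness value")
      choroid <- thk$subfoveal_choroid_um[ti]
    }
    polys <- .read_polygons_geojson(file.path(dir, man$polygon_files[[id]]))
    mirrored <- FALSE
    if (sens$laterality[i] == "OS") {
      vals <- vals[perm]; tvals <- tvals[perm]
      polys <- lapply(polys, .mirror_polygon, grid = grid)
      mirrored <- TRUE
    }
    field <- sensitivity_field(vals, age = sens$age[i],
                               laterality = sens$laterality[i],
                               fp_rate = sens$fp_rate[i])
    reliable <- check_reliability(field)
    if (!reliable && !keep_unreliable) {
      warning("eye ", id, " excluded: false-positive catch-trial rate ",
              sens$fp_rate[i], " >= 0.15")
      next
    }
    eye <- structure(list(
      eye_id = id, field = field, polygons = polys,
      thickness = list(total_retinal_um = tvals,
                       subfoveal_choroid_um = choroid),
      exudative = isTRUE(man$exudative[[id]]),
      va_logmar = NA_real_, ground_truth = NULL), class = "mp_eye")
    attr(eye, "mirrored") <- mirrored
    attr(eye, "reliable") <- reliable
    eyes[[id]] <- eye
  }
  attr(eyes, "manifest") <- man
  eyes
}

#' Serialize a normative model to a versioned text file
#'
#' @param model An [fit_normative()] model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_normative <- function(model, path) {
  stopifnot(inherits(model, "mp_normative"))
  obj <- unclass(model)
  obj$schema_version <- .SCHEMA_VERSION
  obj$td_q <- as.data.frame(obj$td_q)
  obj$pd_q <- as.data.frame(obj$pd_q)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}

#' Read a serialized normative model
#'
#' @param path JSON path written by [write_normative()].
#' @return An `mp_normative` model.
#' @export
read_normative <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != .SCHEMA_VERSION)
    stop("unrecognized normative model schema version")
  obj$schema_version <- NULL
  obj$td_q <- as.matrix(obj$td_q)
  obj$pd_q <- as.matrix(obj$pd_q)
  structure(obj, class = "mp_normative")
}
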