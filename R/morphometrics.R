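#' Rectangular crown area from linear measurements
#'
#' Occlusal crown area as the product of mesio-distal length and the mean
#' of the trigonid and talonid bucco-lingual breadths.
#'
#' @param length mesio-distal length (mm).
#' @param breadth_trigonid,breadth_talonid bucco-lingual breadths (mm) of
#'   the mesial (trigonid) and distal (talonid) moieties of the crown.
#' @return crown area in mm^2.
#' @export
crown_area <- function(length, breadth_trigonid, breadth_talonid) {
  vals <- c(length, breadth_trigonid, breadth_talonid)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("crown_area requires positive length and breadths")
  length * (breadth_trigonid + breadth_talonid) / 2
}

#' Elliptical crown area from a rectangular area
#'
#' The inscribed-ellipse estimate \eqn{ea = \pi\, bl / 4} of occlusal area,
#' expressed in terms of the rectangular area \eqn{ra = bl}.
#'
#' @param rectangular rectangular area \eqn{bl} in mm^2 (non-negative).
#' @return elliptical area \eqn{\pi \cdot ra / 4} in mm^2.
#' @export
elliptical_area <- function(rectangular) {
  stopifnot(is.numeric(rectangular), all(rectangular >= 0, na.rm = TRUE))
  pi * rectangular / 4
}

#' Molar shape coefficient from outline, rectangular, and elliptical areas
#'
#' Solves for the coefficient x placing the traced outline area on the
#' segment between the elliptical and rectangular estimates:
#' \eqn{x = (oa - ea) / (ra - ea)}. x = 0 is a pure ellipse, x = 1 a pure
#' rectangle. Values outside [0, 1] are legal (the outline can undershoot
#' the ellipse or overshoot the rectangle) and are returned unclamped.
#'
#' @param outline traced outline area (mm^2).
#' @param rectangular rectangular area (mm^2); must exceed `elliptical`.
#' @param elliptical elliptical area (mm^2).
#' @return shape coefficient (unitless).
#' @export
shape_coefficient <- function(outline, rectangular, elliptical) {
  if (any(rectangular <= elliptical))
    stop("degenerate geometry: rectangular area must exceed elliptical area")
  (outline - elliptical) / (rectangular - elliptical)
}

#' Corrected crown area from a shape coefficient
#'
#' \eqn{ca = ra\,x + ea\,(1 - x)}: the convex (for x in [0,1]) combination
#' of the rectangular and elliptical estimates that reproduces outline
#' areas on the calibration set.
#'
#' @param rectangular,elliptical areas (mm^2).
#' @param x shape coefficient from [shape_coefficient()].
#' @return corrected area (mm^2).
#' @export
corrected_area <- function(rectangular, elliptical, x) {
  rectangular * x + elliptical * (1 - x)
}

#' Sample coefficient of variation corrected for small samples
#'
#' \eqn{(1 + 1/(4n)) (s / \bar x)} with s the n-1 sample standard
#' deviation. Unitless and scale-invariant.
#'
#' @param values numeric vector, n >= 2, positive mean.
#' @return corrected coefficient of variation.
#' @export
small_sample_cv <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("small_sample_cv needs at least two values")
  m <- mean(values)
  if (m <= 0) stop("small_sample_cv needs a positive mean")
  (1 + 1 / (4 * n)) * stats::sd(values) / m
}

specimen_columns <- function() {
  c("species", "sex", "wear", "provenance",
    paste0("m", rep(1:3, each = 3), "_",
           rep(c("length", "breadth_trigonid", "breadth_talonid"), 3)))
}

#' Read a specimen-level morphometric CSV
#'
#' One row per specimen. Required columns: `species`, `sex`
#' (male/female/indeterminate), `wear` (acceptable/high/unreported),
#' `provenance` (wild/zoo), and `m{1,2,3}_length`,
#' `m{1,2,3}_breadth_trigonid`, `m{1,2,3}_breadth_talonid` in mm (NA where
#' the molar is absent). Optional: `m{1,2,3}_outline_area` (mm^2),
#' `body_mass_kg`, `diet`, `m3_agenesis` (logical; congenital absence of
#' M3, so missing M3 measurements are expected rather than incomplete).
#'
#' @param path CSV file path.
#' @return a data.frame of specimen records.
#' @export
read_specimens <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_specimens(rec)
}

#' @keywords internal
validate_specimens <- function(records) {
  missing_cols <- setdiff(specimen_columns(), names(records))
  if (length(missing_cols))
    stop("specimen table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(records$m3_agenesis)) records$m3_agenesis <- FALSE
  records$m3_agenesis[is.na(records$m3_agenesis)] <- FALSE
  # absent wear reporting is itself an exclusion criterion later on
  records$wear[is.na(records$wear) | records$wear == ""] <- "unreported"
  records
}

molar_present <- function(records, k) {
  cols <- paste0("m", k, c("_length", "_breadth_trigonid", "_breadth_talonid"))
  stats::complete.cases(records[cols]) &
    rowSums(records[cols] <= 0, na.rm = TRUE) == 0
}

#' Filter specimens by the study's exclusion criteria
#'
#' Applies, in order: (1) high or unreported wear, (2) indeterminate sex,
#' (3) zoo provenance, (4) incomplete lower molar dentitions (a molar
#' missing that is not explained by recorded M3 agenesis); then drops
#' whole species represented by fewer than `min_specimens` specimens or by
#' a single sex. Each rule's removal count is logged.
#'
#' @param records specimen data.frame (see [read_specimens()]).
#' @param min_specimens minimum specimens per retained species (default 4).
#' @return list with `retained` (data.frame) and `exclusion_log` (named
#'   integer vector: wear, sex, zoo, incomplete, small_species).
#' @export
filter_specimens <- function(records, min_specimens = 4) {
  log <- c(wear = 0L, sex = 0L, zoo = 0L, incomplete = 0L, small_species = 0L)
  if (nrow(records) == 0) return(list(retained = records, exclusion_log = log))
  records <- validate_specimens(records)

  drop <- records$wear %in% c("high", "unreported")
  log["wear"] <- sum(drop); records <- records[!drop, , drop = FALSE]

  drop <- records$sex == "indeterminate"
  log["sex"] <- sum(drop); records <- records[!drop, , drop = FALSE]

  drop <- records$provenance == "zoo"
  log["zoo"] <- sum(drop); records <- records[!drop, , drop = FALSE]

  complete <- molar_present(records, 1) & molar_present(records, 2) &
    (molar_present(records, 3) | records$m3_agenesis)
  log["incomplete"] <- sum(!complete)
  records <- records[complete, , drop = FALSE]

  n_by_sp <- table(records$species)
  sexes_by_sp <- tapply(records$sex, records$species,
                        function(s) length(unique(s)))
  keep_sp <- names(n_by_sp)[n_by_sp >= min_specimens &
                              sexes_by_sp[names(n_by_sp)] >= 2]
  drop <- !(records$species %in% keep_sp)
  log["small_species"] <- sum(drop)
  records <- records[!drop, , drop = FALSE]
  rownames(records) <- NULL
  list(retained = records, exclusion_log = log)
}

#' Estimate molar shape coefficients from a calibration subset
#'
#' Uses the records that carry traced outline areas to estimate the shape
#' coefficient per molar position: x is computed per tooth, averaged within
#' each calibration species, and the species values averaged per molar
#' position (`level = "position"`, applied dataset-wide) or kept per
#' species (`level = "species"`).
#'
#' @param records specimen data.frame with `m{k}_outline_area` columns.
#' @param level aggregation level of the returned coefficients.
#' @return for `"position"`, a numeric vector `x_1, x_2, x_3`; for
#'   `"species"`, a data.frame with species rows and `x_1..x_3` columns.
#' @export
estimate_shape_coefficients <- function(records, level = c("position", "species")) {
  level <- match.arg(level)
  per_species <- vector("list", 3)
  for (k in 1:3) {
    oa_col <- paste0("m", k, "_outline_area")
    if (!oa_col %in% names(records))
      stop("no outline areas present for molar ", k)
    has <- is.finite(records[[oa_col]]) & molar_present(records, k)
    sub <- records[has, , drop = FALSE]
    if (nrow(sub) == 0) stop("no calibration records with outline areas for molar ", k)
    ra <- with(sub, crown_area_vec(sub, k))
    ea <- elliptical_area(ra)
    x <- shape_coefficient(sub[[oa_col]], ra, ea)
    per_species[[k]] <- tapply(x, sub$species, mean)
  }
  if (level == "position") {
    vapply(per_species, mean, numeric(1)) |> stats::setNames(paste0("x_", 1:3))
  } else {
    sp <- sort(unique(unlist(lapply(per_species, names))))
    out <- data.frame(species = sp)
    for (k in 1:3) out[[paste0("x_", k)]] <- as.numeric(per_species[[k]][sp])
    out
  }
}

crown_area_vec <- function(records, k) {
  l <- records[[paste0("m", k, "_length")]]
  bt <- records[[paste0("m", k, "_breadth_trigonid")]]
  bl <- records[[paste0("m", k, "_breadth_talonid")]]
  l * (bt + bl) / 2
}

#' Per-specimen occlusal areas
#'
#' Converts linear measurements to per-molar occlusal areas (mm^2):
#' rectangular areas, optionally corrected through per-position shape
#' coefficients (see [estimate_shape_coefficients()]).
#'
#' @param records specimen data.frame.
#' @param shape_coefficients optional numeric vector `x_1..x_3`; when
#'   supplied, corrected areas `ra*x + ea*(1-x)` are returned.
#' @return data.frame: `species`, `sex`, `m1_area`, `m2_area`, `m3_area`
#'   (NA where the molar is absent), plus `body_mass_kg`, `diet`,
#'   `m3_agenesis` columns carried through when present.
#' @export
specimen_areas <- function(records, shape_coefficients = NULL) {
  out <- data.frame(species = records$species, sex = records$sex)
  for (k in 1:3) {
    ra <- crown_area_vec(records, k)
    ra[!molar_present(records, k)] <- NA_real_
    if (!is.null(shape_coefficients)) {
      x <- shape_coefficients[[paste0("x_", k)]]
      ra <- corrected_area(ra, elliptical_area(ra), x)
    }
    out[[paste0("m", k, "_area")]] <- ra
  }
  for (col in c("body_mass_kg", "diet", "m3_agenesis"))
    if (!is.null(records[[col]])) out[[col]] <- records[[col]]
  out
}

#' Sex-pooled weighted species mean areas
#'
#' Two-stage weighting for unbalanced sex sampling: specimen areas are
#' averaged within each sex, and the two sex means are averaged with equal
#' weight. Errors if only one sex is represented.
#'
#' @param values numeric vector of specimen areas for one species/molar.
#' @param sex character vector (male/female) parallel to `values`.
#' @return the sex-pooled mean.
#' @export
species_weighted_mean <- function(values, sex) {
  keep <- is.finite(values)
  values <- values[keep]; sex <- sex[keep]
  present <- intersect(c("male", "female"), unique(sex))
  if (length(present) < 2)
    stop("species mean needs both sexes; missing: ",
         setdiff(c("male", "female"), present))
  mean(tapply(values, factor(sex, levels = c("male", "female")), mean))
}

#' Species-level summaries from specimen areas
#'
#' Aggregates specimen areas to one row per species: sex-pooled weighted
#' mean areas, small-sample coefficients of variation, molar proportions,
#' total molar area, and carried covariates.
#'
#' @param areas data.frame from [specimen_areas()].
#' @return data.frame with columns `species`, `n_specimens`,
#'   `mean_area_1..3`, `cv_1..3`, `m2m1`, `m3m1`, `total_area`,
#'   `body_mass_kg`, `diet`, `m3_agenesis`. For species with M3 agenesis
#'   `mean_area_3`, `cv_3`, `m3m1`, `total_area` are NA.
#' @export
species_summaries <- function(areas) {
  species <- sort(unique(areas$species))
  rows <- lapply(species, function(sp) {
    a <- areas[areas$species == sp, , drop = FALSE]
    agen <- if (!is.null(a$m3_agenesis)) any(a$m3_agenesis %in% TRUE) else FALSE
    means <- cvs <- rep(NA_real_, 3)
    for (k in 1:3) {
      v <- a[[paste0("m", k, "_area")]]
      if (k == 3 && agen) next
      means[k] <- species_weighted_mean(v, a$sex)
      cvs[k] <- small_sample_cv(v)
    }
    data.frame(
      species = sp, n_specimens = nrow(a),
      mean_area_1 = means[1], mean_area_2 = means[2], mean_area_3 = means[3],
      cv_1 = cvs[1], cv_2 = cvs[2], cv_3 = cvs[3],
      m2m1 = means[2] / means[1],
      m3m1 = if (agen) NA_real_ else means[3] / means[1],
      total_area = if (agen) NA_real_ else sum(means),
      body_mass_kg = if (!is.null(a$body_mass_kg)) mean(a$body_mass_kg) else NA_real_,
      diet = if (!is.null(a$diet)) a$diet[1] else NA_character_,
      m3_agenesis = agen)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species centroid in molar-proportion morphospace
#'
#' The (M2/M1, M3/M1) point from a species' mean molar areas. Species with
#' third-molar agenesis have no centroid; they belong in the agenesis
#' analysis ([run_agenesis_anthropoid()]) instead.
#'
#' @param summary one row of [species_summaries()] output (or a list with
#'   `mean_area_1..3` and `m3_agenesis`).
#' @return named numeric vector `c(m2m1 = , m3m1 = )`.
#' @export
species_centroid <- function(summary) {
  if (isTRUE(summary$m3_agenesis) || !is.finite(summary$mean_area_3))
    stop("species '", summary$species, "' exhibits M3 agenesis and has no ",
         "morphospace centroid; use the agenesis analysis instead")
  stopifnot(summary$mean_area_1 > 0, summary$mean_area_2 > 0,
            summary$mean_area_3 > 0)
  c(m2m1 = summary$mean_area_2 / summary$mean_area_1,
    m3m1 = summary$mean_area_3 / summary$mean_area_1)
}
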