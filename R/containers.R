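#' CT image volume
#'
#' The unit of all voxel arithmetic in the package: a 3-D array of
#' Hounsfield units (HU) plus the grid metadata needed to interpret it
#' physically. Two volumes are "congruent" when dimensions, spacing and
#' origin agree; all longitudinal comparisons require congruent grids
#' (deformable registration is assumed to have happened upstream).
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm.
#' @param contrast_enhanced logical flag: iodinated-contrast acquisition.
#' @param scanner_tag free-text scanner/reconstruction-kernel identifier.
#' @param clip clamp voxel values into \[-1000, 1000\] (the analysis range;
#'   clamping is idempotent).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         contrast_enhanced = FALSE, scanner_tag = "",
                         clip = FALSE) {
  if (length(dim(voxels)) != 3L)
    stop_pericor("voxels must be a 3-D array", class = "pericor_format_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_pericor("spacing must be 3 strictly positive values",
                 class = "pericor_validation_error")
  if (any(!is.finite(voxels)))
    stop_pericor("voxel values must all be finite",
                 class = "pericor_validation_error")
  if (clip) voxels <- clip_hu(voxels)
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin),
                 contrast_enhanced = isTRUE(contrast_enhanced),
                 scanner_tag = as.character(scanner_tag)),
            class = "image_volume")
}

#' Clamp HU values to the analysis range
#'
#' CT values outside \[-1000, 1000\] carry no meaning for pericardial
#' composition analysis; ingest clamps them to the nearest bound.
#' @param x numeric array or vector.
#' @export
clip_hu <- function(x) pmin(pmax(x, -1000), 1000)

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              if (x$contrast_enhanced) "contrast-enhanced" else "non-contrast"))
  cat(sprintf("  HU range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask on an image grid
#'
#' @param voxels 3-D logical (or 0/1) array.
#' @param spacing,origin grid metadata, as for [image_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop_pericor("mask must be a 3-D array", class = "pericor_format_error")
  storage.mode(voxels) <- "logical"
  if (any(is.na(voxels)))
    stop_pericor("mask contains NA", class = "pericor_validation_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_pericor("spacing must be 3 strictly positive values",
                 class = "pericor_validation_error")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d, %d voxels set (%.2f cm^3)\n",
              d[1], d[2], d[3], sum(x$voxels),
              sum(x$voxels) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Radiotherapy dose grid
#'
#' Physical dose per voxel plus the fractionation metadata needed for the
#' EQD2 conversion. `dose_per_fraction_map` defaults to
#' `physical_dose / n_fractions` (uniform fractionation of the plan).
#'
#' @param physical_dose 3-D numeric array, Gy, congruent with the baseline
#'   volume.
#' @param spacing,origin grid metadata.
#' @param n_fractions positive integer count of delivered fractions.
#' @param dose_per_fraction_map optional 3-D array, Gy per fraction.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(physical_dose, spacing, origin = c(0, 0, 0),
                      n_fractions = 1L, dose_per_fraction_map = NULL) {
  if (length(dim(physical_dose)) != 3L)
    stop_pericor("dose must be a 3-D array", class = "pericor_format_error")
  if (any(physical_dose < 0) || any(!is.finite(physical_dose)))
    stop_pericor("dose must be finite and non-negative everywhere",
                 class = "pericor_validation_error")
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop_pericor("n_fractions must be a positive integer",
                 class = "pericor_validation_error")
  if (is.null(dose_per_fraction_map))
    dose_per_fraction_map <- physical_dose / n_fractions
  if (!identical(dim(dose_per_fraction_map), dim(physical_dose)))
    stop_pericor("dose_per_fraction_map grid mismatch",
                 class = "pericor_validation_error")
  structure(list(physical_dose = physical_dose,
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 n_fractions = n_fractions,
                 dose_per_fraction_map = dose_per_fraction_map),
            class = "dose_grid")
}

#' One patient's imaging study
#'
#' Bundles the baseline volume, candidate follow-ups (already registered to
#' the baseline grid), the heart mask, the dose grid and clinical metadata.
#'
#' @param patient_id character scalar.
#' @param baseline an [image_volume()].
#' @param followup_candidates non-empty list of [image_volume()] on the
#'   baseline grid.
#' @param heart_mask a non-empty [binary_mask()] on the baseline grid.
#' @param dose a [dose_grid()] on the baseline grid.
#' @param metadata list with fields `sex`, `age`, `diagnosis`
#'   ("SCLC"/"NSCLC"), `n_fractions`.
#' @return An object of class `patient_study`.
#' @export
patient_study <- function(patient_id, baseline, followup_candidates,
                          heart_mask, dose, metadata = list()) {
  stopifnot(inherits(baseline, "image_volume"),
            inherits(heart_mask, "binary_mask"),
            inherits(dose, "dose_grid"))
  if (!is.list(followup_candidates) || length(followup_candidates) < 1L)
    stop_pericor("at least one follow-up candidate is required",
                 class = "pericor_validation_error")
  if (!any(heart_mask$voxels))
    stop_pericor("heart mask is empty", class = "pericor_validation_error")
  for (fu in followup_candidates) {
    if (!inherits(fu, "image_volume") ||
        !grids_congruent(baseline, fu))
      stop_pericor("all follow-up candidates must share the baseline grid",
                   class = "pericor_validation_error")
  }
  if (!grids_congruent(baseline, heart_mask) ||
      !grids_congruent(baseline, dose))
    stop_pericor("heart mask and dose must share the baseline grid",
                 class = "pericor_validation_error")
  structure(list(patient_id = as.character(patient_id), baseline = baseline,
                 followup_candidates = followup_candidates,
                 heart_mask = heart_mask, dose = dose, metadata = metadata),
            class = "patient_study")
}

#' @export
print.patient_study <- function(x, ...) {
  cat(sprintf("<patient_study> %s: %d follow-up candidate(s), %s, %s fx\n",
              x$patient_id, length(x$followup_candidates),
              x$metadata$diagnosis %||% "?", x$metadata$n_fractions %||% "?"))
  invisible(x)
}

#' Test whether two gridded objects share a grid
#'
#' @param a,b objects with `voxels`/`physical_dose`, `spacing`, `origin`.
#' @param tol spatial tolerance in mm.
#' @export
grids_congruent <- function(a, b, tol = 1e-6) {
  da <- dim(a$voxels %||% a$physical_dose)
  db <- dim(b$voxels %||% b$physical_dose)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Clinical record for survival endpoints
#'
#' Dates may be `Date` objects or plain numeric day offsets; internally the
#' survival clock is days from the end of radiotherapy.
#'
#' @param patient_id character scalar.
#' @param rt_end_date end of radiotherapy.
#' @param last_date date of death or last follow-up (censoring date).
#' @param death logical: `TRUE` if the patient died at `last_date`.
#' @param events data.frame with columns `date` and `icd10`, the
#'   diagnosis-registry event stream (may be empty).
#' @return An object of class `clinical_record`.
#' @export
clinical_record <- function(patient_id, rt_end_date, last_date, death,
                            events = data.frame(date = numeric(),
                                                icd10 = character())) {
  rt_end_date <- as_day(rt_end_date)
  last_date <- as_day(last_date)
  if (last_date < rt_end_date)
    stop_pericor("last_date precedes rt_end_date",
                 class = "pericor_validation_error")
  events <- as.data.frame(events)
  if (nrow(events)) {
    events$date <- as_day(events$date)
    events$icd10 <- as.character(events$icd10)
    bad <- !grepl("^[A-Z][0-9]{2}(\\.[0-9A-Za-z]{1,4})?$", events$icd10)
    if (any(bad))
      stop_pericor("malformed ICD-10 code(s): ",
                   paste(unique(events$icd10[bad]), collapse = ", "),
                   class = "pericor_validation_error")
    events <- events[order(events$date), , drop = FALSE]
  }
  structure(list(patient_id = as.character(patient_id),
                 rt_end_date = rt_end_date, last_date = last_date,
                 death = isTRUE(death), events = events),
            class = "clinical_record")
}

# calendar parsing stays at the I/O boundary: ISO-8601 strings and Date
# become numeric days, numerics pass through
as_day <- function(x) {
  if (inherits(x, "Date")) return(as.numeric(x))
  if (is.character(x)) return(as.numeric(as.Date(x)))
  as.numeric(x)
}
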