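#' Read a CT volume, mask or dose grid from NIfTI or NRRD
#'
#' Dispatches on the file extension: `.nii`/`.nii.gz` through RNifti,
#' `.nrrd` through the built-in NRRD reader. Only axis-aligned grids are
#' accepted; an oblique affine is rejected rather than silently resampled.
#'
#' @param path file path.
#' @param clip clamp HU into \[-1000, 1000\] on ingest (use `FALSE` for
#'   masks and dose grids).
#' @param contrast_enhanced,scanner_tag metadata attached to the volume;
#'   CT headers do not carry the contrast flag, so it travels in the
#'   clinical table and is supplied here.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, clip = TRUE, contrast_enhanced = FALSE,
                        scanner_tag = "") {
  if (!file.exists(path))
    stop_pericor("cannot read volume: ", path, class = "pericor_io_error")
  raw <- read_any_volume(path)
  image_volume(raw$voxels, raw$spacing, raw$origin,
               contrast_enhanced = contrast_enhanced,
               scanner_tag = scanner_tag, clip = clip)
}

#' Read a binary mask from NIfTI or NRRD
#'
#' Nonzero voxels become `TRUE`.
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  raw <- read_any_volume(path)
  binary_mask(raw$voxels != 0, raw$spacing, raw$origin)
}

#' Read a dose grid from NIfTI or NRRD
#'
#' @inheritParams read_volume
#' @param n_fractions fraction count for the plan.
#' @return A [dose_grid()].
#' @export
read_dose <- function(path, n_fractions) {
  raw <- read_any_volume(path)
  dose_grid(raw$voxels, raw$spacing, raw$origin, n_fractions = n_fractions)
}

read_any_volume <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) return(read_nrrd(path))
  if (grepl("\\.nii(\\.gz)?$", lower)) return(read_nifti(path))
  stop_pericor("unrecognized volume format (expect .nii, .nii.gz, .nrrd): ",
               path, class = "pericor_format_error")
}

read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop_pericor("NIfTI data is not 3-D scalar: ", path,
                 class = "pericor_format_error")
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot[row(rot) != col(rot)]
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)))))
    stop_pericor("oblique NIfTI affine is not supported: ", path,
                 class = "pericor_format_error")
  list(voxels = array(as.numeric(arr), dim = dim(arr)),
       spacing = abs(diag(rot)), origin = as.numeric(xf[1:3, 4]))
}

#' Write a volume, mask or dose array to NIfTI or NRRD
#'
#' @param x an [image_volume()], [binary_mask()] or [dose_grid()].
#' @param path destination; extension selects the format.
#' @export
write_volume <- function(x, path) {
  voxels <- x$voxels %||% x$physical_dose
  if (is.logical(voxels)) storage.mode(voxels) <- "integer"
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) {
    type <- if (is.integer(voxels) ||
                all(voxels == round(voxels))) "int" else "double"
    if (type == "int") storage.mode(voxels) <- "integer"
    write_nrrd(voxels, x$spacing, x$origin, path, type = type)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(voxels)
    RNifti::pixdim(img) <- x$spacing
    xf <- diag(c(x$spacing, 1))
    xf[1:3, 4] <- x$origin
    RNifti::qform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    stop_pericor("unrecognized volume format for writing: ", path,
                 class = "pericor_format_error")
  }
  invisible(path)
}

#' Is an ICD-10 code a cardiovascular-disease code?
#'
#' CVD is defined as ischaemic heart disease (I20-I25) or heart failure
#' (I50). Matching is by the 3-character category, so registry subcodes
#' such as "I50.9" count by prefix.
#'
#' @param icd10 character vector of ICD-10 codes.
#' @return logical vector.
#' @export
is_cvd_code <- function(icd10) {
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9A-Za-z]{1,4})?$", icd10)
  if (any(!ok))
    stop_pericor("malformed ICD-10 code(s): ",
                 paste(unique(icd10[!ok]), collapse = ", "),
                 class = "pericor_validation_error")
  substr(icd10, 1, 3) %in% c("I20", "I21", "I22", "I23", "I24", "I25", "I50")
}

#' Deduplicate clustered diagnosis events
#'
#' Registry streams record the same clinical episode repeatedly; events
#' separated by at most `window_days` are counted as one and only the
#' first entry of each cluster is kept. The scan is greedy left-to-right,
#' anchored at the most recently *kept* event.
#'
#' @param dates numeric or `Date` vector, ascending.
#' @param window_days cluster window in days (default 28).
#' @return indices (into `dates`) of the kept events.
#' @export
dedup_events <- function(dates, window_days = 28) {
  d <- as_day(dates)
  if (length(d) == 0L) return(integer())
  if (is.unsorted(d))
    stop_pericor("event dates must be sorted ascending",
                 class = "pericor_validation_error")
  keep <- 1L
  last <- d[1]
  for (i in seq_along(d)[-1]) {
    if (d[i] - last > window_days) {
      keep <- c(keep, i)
      last <- d[i]
    }
  }
  keep
}

#' Time to first post-RT cardiovascular event
#'
#' Days from the end of radiotherapy to the first deduplicated CVD event
#' strictly after RT end; patients without such an event are censored at
#' their last follow-up or death date. Events on the RT end date itself
#' count as pre-RT (strict inequality).
#'
#' @param record a [clinical_record()].
#' @param window_days dedup window passed to [dedup_events()].
#' @return list with `time` (days), `event` (1 = CVD diagnosis observed,
#'   0 = censored).
#' @export
first_post_rt_cvd <- function(record, window_days = 28) {
  stopifnot(inherits(record, "clinical_record"))
  ev <- record$events
  censored <- list(time = record$last_date - record$rt_end_date, event = 0L)
  if (!nrow(ev)) return(censored)
  cvd <- ev[is_cvd_code(ev$icd10), , drop = FALSE]
  if (!nrow(cvd)) return(censored)
  kept <- cvd[dedup_events(cvd$date, window_days), , drop = FALSE]
  post <- kept$date[kept$date > record$rt_end_date]
  if (!length(post)) return(censored)
  list(time = post[1] - record$rt_end_date, event = 1L)
}

#' Read the clinical and event tables
#'
#' `clinical.csv` columns: patient_id, sex, age, diagnosis, n_fractions,
#' rt_end_date, last_date, death (0/1). `events.csv` columns: patient_id,
#' date, icd10. Dates are ISO-8601 or plain day numbers.
#'
#' @param clinical_path,events_path CSV paths; `events_path` may be
#'   `NULL` for an event-free cohort.
#' @return named list of [clinical_record()] objects.
#' @export
read_clinical <- function(clinical_path, events_path = NULL) {
  cl <- read.csv(clinical_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "rt_end_date", "last_date", "death")
  if (!all(need %in% names(cl)))
    stop_pericor("clinical table must have columns: ",
                 paste(need, collapse = ", "), class = "pericor_format_error")
  ev <- if (!is.null(events_path) && file.exists(events_path))
    read.csv(events_path, stringsAsFactors = FALSE)
  else data.frame(patient_id = character(), date = numeric(),
                  icd10 = character())
  recs <- lapply(seq_len(nrow(cl)), function(i) {
    pid <- as.character(cl$patient_id[i])
    e <- ev[as.character(ev$patient_id) == pid, c("date", "icd10"),
            drop = FALSE]
    clinical_record(pid, cl$rt_end_date[i], cl$last_date[i],
                    cl$death[i] != 0, events = e)
  })
  names(recs) <- as.character(cl$patient_id)
  recs
}
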