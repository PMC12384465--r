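#' Pipeline configuration
#'
#' One flat list of every knob the end-to-end run uses. Unknown keys are
#' rejected so config-file typos fail loudly instead of silently running
#' defaults.
#'
#' @param ... key = value overrides of the defaults.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    shell_thickness_mm = 4,
    ring_width_mm = 50,
    ring_dose_max_gy = 1,
    histogram_metric = "l1",
    alpha_beta_gy = 3,
    label_timepoint = "followup",
    smoothing_window = 11L,
    dose_bin_edges = dose_bin_edges(),
    batch_scheme = "four_batch",
    harmonize_target = "biomarkers",
    empirical_bayes = TRUE,
    dedup_window_days = 28,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop_pericor("unknown config key(s): ", paste(bad, collapse = ", "),
                 class = "pericor_validation_error")
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order: input validation, shell and reference-ring construction,
#' follow-up selection (HU-histogram distance in the ring), the three
#' biomarkers on the selected pair, contrast-batch harmonization of the
#' biomarker features, dose-correlation statistics, and survival/event
#' analyses. Writes tidy CSVs, a JSON run manifest and a structured log
#' under `out_dir`; a rerun with identical inputs and config reproduces
#' every CSV bit-identically.
#'
#' Patients failing validation or any per-patient stage are skipped with
#' a logged reason; more than 50% failures aborts the run.
#'
#' @param cohort list with `studies` (list of [patient_study()]) and
#'   `records` (named list of [clinical_record()]), e.g. from
#'   [generate_cohort()] or [read_cohort_dir()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param subset optional character predicate over the metadata columns
#'   (`patient_id`, `diagnosis`, `n_fractions`, `sex`, `age`), e.g.
#'   `"diagnosis == 'NSCLC'"`; see [filter_cohort()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir, subset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  logit <- function(stage, pid, msg, level = "INFO") {
    log_lines <<- c(log_lines,
                    sprintf("%s\t%s\t%s\t%s", level, stage, pid, msg))
  }

  studies <- cohort$studies
  records <- cohort$records
  if (!is.null(subset)) {
    ids <- filter_cohort(cohort_metadata(studies), subset)
    studies <- studies[vapply(studies, function(s)
      s$patient_id %in% ids, logical(1))]
    logit("subset", "-", sprintf("%d patients match '%s'",
                                 length(studies), subset))
  }
  n_in <- length(studies)
  if (!n_in)
    stop_pericor("no patients to process", class = "pericor_validation_error")

  rspec <- region_spec(config$shell_thickness_mm, config$ring_width_mm,
                       config$ring_dose_max_gy)
  per <- list()
  skipped <- character()
  for (s in studies) {
    res <- tryCatch(
      process_patient(s, rspec, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, s$patient_id)
      logit("patient", s$patient_id, conditionMessage(res), "WARN")
    } else {
      per[[s$patient_id]] <- res
      logit("patient", s$patient_id, "biomarkers computed")
    }
  }
  if (length(per) < n_in / 2)
    stop_pericor("more than 50% of patients failed validation (",
                 length(skipped), "/", n_in, ")",
                 class = "pericor_validation_error")
  ids <- names(per)

  # --- cohort tables ------------------------------------------------
  scheme <- tissue_scheme()
  summary_df <- do.call(rbind, lapply(per, function(p) p$summary))
  rownames(summary_df) <- NULL

  feat <- do.call(rbind, lapply(per, function(p) p$features))
  batch <- vapply(ids, function(id) per[[id]]$batch, character(1))
  harmonized <- feat
  nb <- table(batch)
  if (length(nb) >= 2L && all(nb >= 2L)) {
    fm <- combat_fit_transform(
      feature_matrix(feat, batch),
      empirical_bayes = isTRUE(config$empirical_bayes))
    harmonized <- fm$values
    logit("harmonization", "-", sprintf(
      "%s over %d batches (EB %s)", config$harmonize_target,
      length(nb), if (isTRUE(config$empirical_bayes)) "on" else "off"))
  } else {
    logit("harmonization", "-",
          "skipped: need >= 2 batches with >= 2 samples each", "WARN")
  }

  # --- dose statistics ----------------------------------------------
  mean_peri <- summary_df$mean_pericardium_dose_gy
  dose_rows <- list()
  add_dose_row <- function(name, values) {
    r <- tryCatch(spearman_test(mean_peri, values), error = function(e) NULL)
    if (!is.null(r))
      dose_rows[[length(dose_rows) + 1L]] <<- data.frame(
        biomarker = name, rho = r$effect, p = r$p_value, n = r$n)
  }
  add_dose_row("upward_shift", harmonized[, "upward_shift"])
  for (lab in scheme$label)
    add_dose_row(paste0("delta_v_", lab),
                 harmonized[, paste0("delta_v_", lab)])
  results_dose <- do.call(rbind, dose_rows)

  # --- per-dose-bin mean HU-change curves ---------------------------
  curves <- lapply(per, function(p) p$curve)
  agg <- aggregate_delta_huv(curves, mean_peri, config$dose_bin_edges)
  agg_df <- do.call(rbind, lapply(names(agg), function(b) {
    cu <- agg[[b]]
    sm <- smooth_curve(cu$pct, config$smoothing_window)
    keep <- cu$pct > 0 | sm > 1e-12
    data.frame(dose_bin = b, delta_hu = cu$delta_hu[keep],
               pct_volume = cu$pct[keep], pct_volume_smoothed = sm[keep])
  }))

  # --- survival -----------------------------------------------------
  surv_rows <- list()
  recs <- records[ids]
  have_rec <- !vapply(recs, is.null, logical(1))
  if (any(have_rec)) {
    rids <- ids[have_rec]
    os_time <- vapply(recs[rids], function(r)
      r$last_date - r$rt_end_date, numeric(1))
    os_event <- vapply(recs[rids], function(r)
      as.integer(r$death), integer(1))
    cvd <- lapply(recs[rids], first_post_rt_cvd,
                  window_days = config$dedup_window_days)
    cvd_time <- vapply(cvd, `[[`, numeric(1), "time")
    cvd_event <- vapply(cvd, `[[`, integer(1), "event")

    covariates <- c("mean_pericardium_dose_gy" =
                      list(mean_peri[match(rids, ids)]),
                    setNames(lapply(colnames(harmonized), function(cn)
                      harmonized[match(rids, ids), cn]),
                      colnames(harmonized)))
    for (cn in names(covariates)) {
      g <- tryCatch(dichotomize_at_mean(covariates[[cn]]),
                    error = function(e) NULL)
      if (is.null(g)) next
      for (ep in c("death", "cvd")) {
        tt <- if (ep == "death") os_time else cvd_time
        ee <- if (ep == "death") os_event else cvd_event
        lr <- tryCatch(logrank_test(tt, ee, g), error = function(e) NULL)
        hr <- tryCatch(hazard_ratio(tt, ee, g), error = function(e) NULL)
        surv_rows[[length(surv_rows) + 1L]] <- data.frame(
          covariate = cn, endpoint = ep,
          logrank_p = if (is.null(lr)) NA_real_ else lr$p_value,
          hr = if (is.null(hr) || !hr$estimable) NA_real_ else hr$effect,
          ci_low = if (is.null(hr) || !hr$estimable) NA_real_
                   else hr$ci_low,
          ci_high = if (is.null(hr) || !hr$estimable) NA_real_
                    else hr$ci_high,
          n_events = sum(ee),
          estimable = !is.null(hr) && hr$estimable)
      }
    }
  }
  results_survival <- if (length(surv_rows)) do.call(rbind, surv_rows)
    else data.frame()

  # --- write outputs ------------------------------------------------
  wr <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(summary_df, "patient_summary.csv")
  wr(do.call(rbind, lapply(ids, function(id) {
    cu <- per[[id]]$curve
    keep <- cu$pct > 0
    data.frame(patient_id = id, delta_hu = cu$delta_hu[keep],
               pct_volume = cu$pct[keep])
  })), "delta_huv.csv")
  wr(do.call(rbind, lapply(ids, function(id) {
    v <- per[[id]]$vmc
    data.frame(patient_id = id,
               tissue = rep(rownames(v), times = ncol(v)),
               dose_bin = rep(colnames(v), each = nrow(v)),
               pct_mass_change = as.vector(v))
  })), "vmc.csv")
  wr(do.call(rbind, lapply(ids, function(id) {
    dv <- per[[id]]$delta_v
    data.frame(patient_id = id, tissue = names(dv),
               pct_volume_change = as.numeric(dv))
  })), "delta_v.csv")
  wr(agg_df, "cohort_delta_huv.csv")
  harm_df <- data.frame(patient_id = ids, batch = batch,
                        as.data.frame(harmonized))
  wr(harm_df, "biomarker_features.csv")
  wr(results_dose, "results_dose.csv")
  wr(results_survival, "results_survival.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("pericor")),
    seed = config$seed,
    config = config[setdiff(names(config), "dose_bin_edges")],
    dose_bin_edges = config$dose_bin_edges,
    config_hash = hash_object(unclass(config)),
    n_input = n_in,
    n_processed = length(per),
    n_skipped = length(skipped),
    skipped = skipped,
    stages = c("validate", "geometry", "followup_selection", "biomarkers",
               "harmonization", "dose_statistics", "survival"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(manifest)
}

process_patient <- function(s, rspec, config) {
  shell <- pericardial_shell(s$heart_mask, rspec$shell_thickness_mm)
  if (!any(shell$voxels))
    stop_pericor("empty pericardial shell", class = "pericor_validation_error")
  ring <- reference_ring(s$heart_mask, s$dose, rspec)
  sel <- if (length(s$followup_candidates) == 1L || !any(ring$voxels))
    list(index = 1L)
  else select_followup(s$baseline, s$followup_candidates, ring,
                       metric = config$histogram_metric)
  fu <- s$followup_candidates[[sel$index]]

  deqd2 <- eqd2_grid(s$dose, config$alpha_beta_gy)
  curve <- delta_huv(s$baseline, fu, shell)
  vtab <- vmc(s$baseline, fu, shell, deqd2,
              edges = config$dose_bin_edges,
              label_timepoint = config$label_timepoint)
  dv <- delta_v(s$baseline, fu, shell)
  cs <- curve_summary(curve)

  features <- c(upward_shift = cs$upward_shift,
                setNames(as.numeric(dv), paste0("delta_v_", names(dv))),
                setNames(rowSums(vtab),
                         paste0("vmc_", rownames(vtab))))
  batch <- if (identical(config$batch_scheme, "two_batch")) {
    if (s$baseline$contrast_enhanced) "CE" else "nonCE"
  } else {
    assign_batches(list(s), "four_batch", followup_index = sel$index)
  }
  summary <- data.frame(
    patient_id = s$patient_id,
    selected_followup = sel$index,
    mean_heart_dose_gy = mean_region_dose(deqd2, s$heart_mask),
    mean_pericardium_dose_gy = mean_region_dose(deqd2, shell),
    mean_delta_hu = cs$mean_delta_hu,
    upward_shift = cs$upward_shift,
    batch = batch,
    stringsAsFactors = FALSE)
  list(summary = summary, curve = curve, vmc = vtab, delta_v = dv,
       features = features, batch = batch)
}

cohort_metadata <- function(studies) {
  do.call(rbind, lapply(studies, function(s) data.frame(
    patient_id = s$patient_id,
    diagnosis = s$metadata$diagnosis %||% NA_character_,
    n_fractions = s$metadata$n_fractions %||% NA_integer_,
    sex = s$metadata$sex %||% NA_character_,
    age = s$metadata$age %||% NA_real_,
    stringsAsFactors = FALSE)))
}

#' Select a patient subset by metadata predicate
#'
#' @param metadata data.frame with one row per patient (columns
#'   `patient_id`, `diagnosis`, `n_fractions`, `sex`, `age`).
#' @param predicate character R expression over those columns, e.g.
#'   `"diagnosis == 'NSCLC' & n_fractions <= 8"`.
#' @return character vector of matching patient ids.
#' @export
filter_cohort <- function(metadata, predicate) {
  keep <- eval(parse(text = predicate), envir = metadata,
               enclos = baseenv())
  if (!is.logical(keep))
    stop_pericor("predicate must evaluate to logical",
                 class = "pericor_validation_error")
  ids <- metadata$patient_id[keep & !is.na(keep)]
  if (!length(ids))
    stop_pericor("predicate matches no patients",
                 class = "pericor_validation_error")
  as.character(ids)
}

hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Write a cohort to disk
#'
#' Lays out a cohort directory: NRRD volumes under `volumes/`, the
#' clinical and event CSVs, an image-metadata table, and (when present)
#' the generator truth table.
#'
#' @param cohort as returned by [generate_cohort()].
#' @param dir destination directory.
#' @export
write_cohort <- function(cohort, dir) {
  vdir <- file.path(dir, "volumes")
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  img_rows <- list()
  cl_rows <- list()
  ev_rows <- list()
  for (s in cohort$studies) {
    pid <- s$patient_id
    paths <- c(baseline = file.path(vdir, paste0(pid, "_baseline.nrrd")),
               mask = file.path(vdir, paste0(pid, "_mask.nrrd")),
               dose = file.path(vdir, paste0(pid, "_dose.nrrd")))
    write_volume(s$baseline, paths["baseline"])
    write_volume(s$heart_mask, paths["mask"])
    write_volume(s$dose, paths["dose"])
    img_rows[[length(img_rows) + 1L]] <- data.frame(
      patient_id = pid, role = "baseline",
      path = file.path("volumes", basename(paths["baseline"])),
      contrast_enhanced = s$baseline$contrast_enhanced,
      scanner_tag = s$baseline$scanner_tag)
    for (j in seq_along(s$followup_candidates)) {
      fp <- file.path(vdir, sprintf("%s_followup%d.nrrd", pid, j))
      write_volume(s$followup_candidates[[j]], fp)
      img_rows[[length(img_rows) + 1L]] <- data.frame(
        patient_id = pid, role = sprintf("followup%d", j),
        path = file.path("volumes", basename(fp)),
        contrast_enhanced = s$followup_candidates[[j]]$contrast_enhanced,
        scanner_tag = s$followup_candidates[[j]]$scanner_tag)
    }
    rec <- cohort$records[[pid]]
    cl_rows[[length(cl_rows) + 1L]] <- data.frame(
      patient_id = pid, sex = s$metadata$sex, age = s$metadata$age,
      diagnosis = s$metadata$diagnosis,
      n_fractions = s$metadata$n_fractions,
      rt_end_date = if (is.null(rec)) 0 else rec$rt_end_date,
      last_date = if (is.null(rec)) 0 else rec$last_date,
      death = if (is.null(rec)) 0L else as.integer(rec$death))
    if (!is.null(rec) && nrow(rec$events))
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        patient_id = pid, date = rec$events$date,
        icd10 = rec$events$icd10)
  }
  write.csv(do.call(rbind, img_rows), file.path(dir, "images.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, cl_rows), file.path(dir, "clinical.csv"),
            row.names = FALSE)
  ev <- if (length(ev_rows)) do.call(rbind, ev_rows)
    else data.frame(patient_id = character(), date = numeric(),
                    icd10 = character())
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  if (!is.null(cohort$truth))
    write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `studies` and `records`, as [generate_cohort()]
#'   returns.
#' @export
read_cohort_dir <- function(dir) {
  images <- read.csv(file.path(dir, "images.csv"),
                     stringsAsFactors = FALSE)
  clin <- read.csv(file.path(dir, "clinical.csv"),
                   stringsAsFactors = FALSE)
  records <- read_clinical(file.path(dir, "clinical.csv"),
                           file.path(dir, "events.csv"))
  studies <- lapply(seq_len(nrow(clin)), function(i) {
    pid <- as.character(clin$patient_id[i])
    rows <- images[as.character(images$patient_id) == pid, , drop = FALSE]
    brow <- rows[rows$role == "baseline", ]
    baseline <- read_volume(file.path(dir, brow$path), clip = TRUE,
                            contrast_enhanced = brow$contrast_enhanced,
                            scanner_tag = brow$scanner_tag)
    furows <- rows[grepl("^followup", rows$role), , drop = FALSE]
    furows <- furows[order(furows$role), , drop = FALSE]
    cands <- lapply(seq_len(nrow(furows)), function(j)
      read_volume(file.path(dir, furows$path[j]), clip = TRUE,
                  contrast_enhanced = furows$contrast_enhanced[j],
                  scanner_tag = furows$scanner_tag[j]))
    mask <- read_mask(file.path(dir, "volumes",
                                paste0(pid, "_mask.nrrd")))
    dose <- read_dose(file.path(dir, "volumes", paste0(pid, "_dose.nrrd")),
                      n_fractions = clin$n_fractions[i])
    patient_study(pid, baseline, cands, mask, dose,
                  metadata = list(sex = clin$sex[i], age = clin$age[i],
                                  diagnosis = clin$diagnosis[i],
                                  n_fractions = clin$n_fractions[i]))
  })
  names(studies) <- as.character(clin$patient_id)
  list(studies = studies, records = records)
}
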