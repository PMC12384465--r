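#' Synthetic-cohort configuration
#'
#' Parameters of the phantom-cohort generator. The phantom emulates the
#' statistical structure the analysis relies on — not anatomy: an
#' ellipsoidal heart on a coarse CT grid, an exponential dose falloff
#' from a tumor seed placed at a patient-specific distance (producing the
#' full spread of mean-dose bins), shell voxels drawn from the five
#' composition classes, a dose-dependent probability of a voxel moving
#' one class up the density ladder at follow-up, additive/multiplicative
#' contrast batch effects, per-candidate reconstruction-kernel noise, and
#' exponential survival whose log-hazard carries the planted biomarker
#' group.
#'
#' @param n_patients cohort size.
#' @param seed master seed; the whole cohort is a deterministic function
#'   of it.
#' @param grid_dim,spacing_mm grid shape and voxel size (default 48^3 at
#'   2 mm).
#' @param heart_semiaxes_mm ellipsoid semi-axes of the heart.
#' @param shell_thickness_mm pericardial shell depth.
#' @param falloff_mm exponential dose falloff length from the tumor seed.
#' @param tumor_distance_mm range (min, max) of tumor-seed distance from
#'   the heart center, mm; drawn uniformly per patient.
#' @param fraction_schedules list of `c(n_fractions, dose_per_fraction)`
#'   pairs sampled per patient (conventional, SBRT and hypofractionated
#'   lung schedules).
#' @param composition_prior named fractions of shell voxels per
#'   composition class (sums to 1).
#' @param beta dose-effect slope: a shell voxel shifts one class upward
#'   at follow-up with probability `min(1, beta * EQD2 / 100)`.
#' @param ce_offset_hu,ce_scale additive/multiplicative contrast effect
#'   applied to contrast-enhanced images.
#' @param kernel_sigmas_hu per-candidate Gaussian kernel-noise sigma; one
#'   follow-up candidate per entry, the smallest being the
#'   "matched-kernel" scan.
#' @param texture_sigma_hu within-class HU texture noise.
#' @param p_baseline_ce,p_followup_ce contrast-enhancement probabilities.
#' @param prop_nsclc fraction of NSCLC diagnoses.
#' @param alpha_beta_gy EQD2 conversion parameter used for the planted
#'   effect.
#' @param base_hazard baseline death hazard per day.
#' @param theta log hazard-ratio of the planted high-biomarker group.
#' @param cvd_rate baseline CVD diagnosis rate per day.
#' @param cvd_mult rate multiplier for the high group.
#' @param admin_censor_days administrative censoring horizon.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20L, seed = 1L,
                          grid_dim = c(48L, 48L, 48L),
                          spacing_mm = c(2, 2, 2),
                          heart_semiaxes_mm = c(28, 24, 22),
                          shell_thickness_mm = 4,
                          falloff_mm = 25,
                          tumor_distance_mm = c(30, 220),
                          fraction_schedules = list(c(33, 2), c(3, 22.3),
                                                    c(5, 10), c(8, 7),
                                                    c(30, 1.5)),
                          composition_prior = c(Fat = 0.35, Fluid = 0.20,
                                                Heme = 0.25, Fibrous = 0.18,
                                                Calcification = 0.02),
                          beta = 0.5,
                          ce_offset_hu = 25, ce_scale = 1,
                          kernel_sigmas_hu = c(5, 20, 40),
                          texture_sigma_hu = 3,
                          p_baseline_ce = 0.5, p_followup_ce = 0.5,
                          prop_nsclc = 0.8,
                          alpha_beta_gy = 3,
                          base_hazard = log(2) / 600,
                          theta = log(2),
                          cvd_rate = 0.2 / 365,
                          cvd_mult = 2,
                          admin_censor_days = 1825) {
  if (abs(sum(composition_prior) - 1) > 1e-9)
    stop_pericor("composition fractions must sum to 1",
                 class = "pericor_validation_error")
  if (!setequal(names(composition_prior), tissue_scheme()$label))
    stop_pericor("composition prior must name the five tissue classes",
                 class = "pericor_validation_error")
  if (beta < 0 || any(kernel_sigmas_hu < 0) || texture_sigma_hu < 0 ||
      base_hazard <= 0 || cvd_rate < 0)
    stop_pericor("rates and sigmas must be non-negative",
                 class = "pericor_validation_error")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Builds `n_patients` phantom studies plus matching clinical records and
#' a truth table recording what was planted (per-patient mean pericardial
#' EQD2, per-class shift counts, contrast batch, matched-kernel candidate
#' index, outcome group). Deterministic under the config seed.
#'
#' @param config a [cohort_config()].
#' @return list with `studies` (list of [patient_study()]), `records`
#'   (list of [clinical_record()]), `truth` (data.frame), and the shared
#'   `heart_mask`, `shell`, `ring` masks.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  scheme <- tissue_scheme()
  geom <- phantom_geometry(config)
  shell_idx <- which(geom$shell$voxels)
  heart_only <- geom$heart$voxels & !geom$shell$voxels

  studies <- vector("list", config$n_patients)
  records <- vector("list", config$n_patients)
  truth <- vector("list", config$n_patients)

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", i)
    p <- generate_patient(pid, config, geom, shell_idx, heart_only, scheme)
    studies[[i]] <- p$study
    truth[[i]] <- p$truth
  }
  truth <- do.call(rbind, truth)

  # planted outcome group: upper half of the dose-driven shift biomarker
  grp <- as.integer(truth$shifted_fraction >
                      median(truth$shifted_fraction))
  truth$outcome_group <- grp
  for (i in seq_len(config$n_patients)) {
    rec <- generate_outcome(truth$patient_id[i], grp[i], config)
    records[[i]] <- rec$record
    truth$surv_time[i] <- rec$time
    truth$death[i] <- rec$death
  }
  names(records) <- truth$patient_id
  names(studies) <- truth$patient_id
  list(studies = studies, records = records, truth = truth,
       heart_mask = geom$heart, shell = geom$shell, ring = geom$ring)
}

# shared masks: all phantoms use the same heart; computed once per cohort
phantom_geometry <- function(config) {
  d <- config$grid_dim
  sp <- config$spacing_mm
  ctr <- (d + 1) / 2
  ax <- expand_grid_coords(d, sp, ctr)
  r2 <- (ax$x / config$heart_semiaxes_mm[1])^2 +
    (ax$y / config$heart_semiaxes_mm[2])^2 +
    (ax$z / config$heart_semiaxes_mm[3])^2
  heart <- binary_mask(array(r2 <= 1, dim = d), sp)
  shell <- pericardial_shell(heart, config$shell_thickness_mm)
  # the selection ring ignores dose here (phantom dose is added per
  # patient); geometric annulus only
  ring <- reference_ring(heart,
                         dose_grid(array(0, dim = d), sp),
                         region_spec(config$shell_thickness_mm))
  list(heart = heart, shell = shell, ring = ring,
       coords = ax, center = ctr)
}

expand_grid_coords <- function(d, sp, ctr) {
  x <- (seq_len(d[1]) - ctr[1]) * sp[1]
  y <- (seq_len(d[2]) - ctr[2]) * sp[2]
  z <- (seq_len(d[3]) - ctr[3]) * sp[3]
  list(x = array(rep(x, times = d[2] * d[3]), dim = d),
       y = array(rep(rep(y, each = d[1]), times = d[3]), dim = d),
       z = array(rep(z, each = d[1] * d[2]), dim = d))
}

generate_patient <- function(pid, config, geom, shell_idx, heart_only,
                             scheme) {
  d <- config$grid_dim
  sp <- config$spacing_mm
  nvox <- prod(d)
  nshell <- length(shell_idx)

  # dose: exponential falloff from a tumor seed outside the heart
  sched <- config$fraction_schedules[[
    sample.int(length(config$fraction_schedules), 1L)]]
  n_fx <- as.integer(sched[1])
  total_dose <- sched[1] * sched[2]
  u <- stats::runif(3, -1, 1)
  u <- u / sqrt(sum(u^2))
  tdist <- stats::runif(1, config$tumor_distance_mm[1],
                        config$tumor_distance_mm[2])
  tpos <- u * tdist
  dist_t <- sqrt((geom$coords$x - tpos[1])^2 +
                 (geom$coords$y - tpos[2])^2 +
                 (geom$coords$z - tpos[3])^2)
  phys <- total_dose * exp(-dist_t / config$falloff_mm)
  dose <- dose_grid(phys, sp, n_fractions = n_fx)
  deqd2 <- eqd2_grid(dose, config$alpha_beta_gy)

  # baseline composition and HU
  classes <- scheme$label
  cls_b <- sample(classes, nshell, replace = TRUE,
                  prob = config$composition_prior[classes])
  hu_b_shell <- sample_class_hu(cls_b, scheme) +
    stats::rnorm(nshell, 0, config$texture_sigma_hu)

  # dose-driven upward shift at follow-up (Fluid -> Heme -> Fibrous ->
  # Calcification; Fat and Calcification stay put)
  ladder <- c(Fluid = "Heme", Heme = "Fibrous", Fibrous = "Calcification")
  p_shift <- pmin(1, config$beta * deqd2[shell_idx] / 100)
  eligible <- cls_b %in% names(ladder)
  shifted <- eligible & stats::runif(nshell) < p_shift
  cls_f <- cls_b
  cls_f[shifted] <- ladder[cls_b[shifted]]
  hu_f_shell <- ifelse(shifted,
                       sample_class_hu(cls_f, scheme),
                       hu_b_shell + stats::rnorm(nshell, 0,
                                                 config$texture_sigma_hu))

  # background: blood pool / myocardium inside, mediastinal mix outside
  bg_b <- stats::rnorm(nvox, -120, 30)
  bg_b[heart_only] <- stats::rnorm(sum(heart_only), 40, 10)
  base_true <- array(bg_b, dim = d)
  base_true[shell_idx] <- hu_b_shell
  fu_true <- base_true + stats::rnorm(nvox, 0, config$texture_sigma_hu)
  fu_true[shell_idx] <- hu_f_shell

  base_ce <- stats::runif(1) < config$p_baseline_ce
  fu_ce <- stats::runif(1) < config$p_followup_ce
  base_img <- finalize_hu(apply_ce(base_true, base_ce, config))
  baseline <- image_volume(base_img, sp, contrast_enhanced = base_ce,
                           scanner_tag = "kernel-B")

  k <- length(config$kernel_sigmas_hu)
  order_idx <- sample.int(k)          # shuffle candidate order
  cands <- vector("list", k)
  for (j in seq_len(k)) {
    sig <- config$kernel_sigmas_hu[order_idx[j]]
    img <- fu_true + stats::rnorm(nvox, 0, sig)
    img <- finalize_hu(apply_ce(img, fu_ce, config))
    cands[[j]] <- image_volume(img, sp, contrast_enhanced = fu_ce,
                               scanner_tag = sprintf("kernel-s%g", sig))
  }
  matched <- which(order_idx == which.min(config$kernel_sigmas_hu))

  diagnosis <- if (stats::runif(1) < config$prop_nsclc) "NSCLC" else "SCLC"
  sex <- sample(c("F", "M"), 1L)
  age <- round(stats::runif(1, 45, 85))
  study <- patient_study(pid, baseline, cands, geom$heart, dose,
                         metadata = list(sex = sex, age = age,
                                         diagnosis = diagnosis,
                                         n_fractions = n_fx))

  shift_counts <- table(factor(cls_b[shifted], levels = scheme$label))
  truth <- data.frame(
    patient_id = pid,
    mean_shell_eqd2 = mean(deqd2[shell_idx]),
    mean_heart_eqd2 = mean(deqd2[geom$heart$voxels]),
    n_shifted = sum(shifted),
    shifted_fraction = mean(shifted),
    shift_from_Fluid = as.integer(shift_counts[["Fluid"]]),
    shift_from_Heme = as.integer(shift_counts[["Heme"]]),
    shift_from_Fibrous = as.integer(shift_counts[["Fibrous"]]),
    baseline_ce = base_ce, followup_ce = fu_ce,
    matched_candidate = matched,
    diagnosis = diagnosis, n_fractions = n_fx,
    surv_time = NA_real_, death = NA,
    stringsAsFactors = FALSE)
  list(study = study, truth = truth)
}

sample_class_hu <- function(cls, scheme) {
  lo <- scheme$lo[match(cls, scheme$label)]
  hi <- scheme$hi[match(cls, scheme$label)]
  stats::runif(length(cls), lo, hi)
}

apply_ce <- function(x, ce, config) {
  if (!ce) return(x)
  (x + config$ce_offset_hu) * config$ce_scale
}

finalize_hu <- function(x) {
  out <- clip_hu(round_half_away(x))
  storage.mode(out) <- "integer"
  out
}

generate_outcome <- function(pid, group, config) {
  rate <- config$base_hazard * exp(config$theta * group)
  t_death <- stats::rexp(1, rate)
  death <- t_death <= config$admin_censor_days
  time <- min(t_death, config$admin_censor_days)

  # CVD diagnosis stream: homogeneous Poisson over follow-up, higher rate
  # in the planted group; occasional pre-RT events and registry
  # duplicates exercise the event rules downstream
  cvd_rate <- config$cvd_rate * (1 + config$cvd_mult * group)
  n_ev <- stats::rpois(1, cvd_rate * time)
  dates <- sort(round(stats::runif(n_ev, 1, time)))
  codes <- sample(c("I21", "I25.1", "I50.9", "I20.0"), n_ev,
                  replace = TRUE)
  if (stats::runif(1) < 0.3) {   # pre-RT cardiac history
    dates <- c(round(stats::runif(1, -1000, -30)), dates)
    codes <- c("I25.9", codes)
  }
  dup <- which(stats::runif(length(dates)) < 0.3 & dates > 0)
  if (length(dup)) {
    dates <- c(dates, dates[dup] + 7)
    codes <- c(codes, codes[dup])
  }
  if (stats::runif(1) < 0.5) {   # non-CVD noise diagnosis
    dates <- c(dates, round(stats::runif(1, 1, max(time, 2))))
    codes <- c(codes, sample(c("J18.9", "E11.9", "I10"), 1))
  }
  ord <- order(dates)
  rec <- clinical_record(pid, rt_end_date = 0, last_date = time,
                         death = death,
                         events = data.frame(date = dates[ord],
                                             icd10 = codes[ord]))
  list(record = rec, time = time, death = death)
}

#' Minimal single-shell toy study
#'
#' Wraps explicit per-voxel (baseline HU, follow-up HU, dose) triples as
#' a flat n x 1 x 1 study with unit voxel volume — the fixture for
#' biomarker-equation oracle tests. The heart mask covers all voxels and
#' doubles as the shell.
#'
#' @param hu_baseline,hu_followup per-voxel HU vectors of equal length.
#' @param dose_gy per-voxel physical dose (recycled).
#' @param n_fractions fraction count for the dose grid.
#' @return A [patient_study()] with a single follow-up candidate.
#' @export
generate_toy_patient <- function(hu_baseline, hu_followup, dose_gy = 0,
                                 n_fractions = 1L) {
  stopifnot(length(hu_baseline) == length(hu_followup))
  n <- length(hu_baseline)
  d <- c(n, 1L, 1L)
  sp <- c(1, 1, 1)
  base <- image_volume(array(hu_baseline, dim = d), sp, clip = TRUE)
  fu <- image_volume(array(hu_followup, dim = d), sp, clip = TRUE)
  mask <- binary_mask(array(TRUE, dim = d), sp)
  dg <- dose_grid(array(rep_len(dose_gy, n), dim = d), sp,
                  n_fractions = n_fractions)
  patient_study("toy", base, list(fu), mask, dg,
                metadata = list(sex = "F", age = 65, diagnosis = "NSCLC",
                                n_fractions = n_fractions))
}
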