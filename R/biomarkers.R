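#' Tissue-composition HU scheme
#'
#' Partition of the CT number line into the five composition classes used
#' throughout the analysis. Integer HU intervals, pairwise disjoint,
#' covering \[-1000, 1000\] exactly:
#' Calcification \[130, 1000\], Fibrous \[65, 129\], Heme \[13, 64\],
#' Fluid \[-5, 12\], Fat \[-1000, -6\]. Labels are composition-range
#' names, not diagnoses: each range holds both normal and abnormal tissue
#' (e.g. Fibrous includes adjacent myocardium; Heme includes normal
#' pericardium).
#'
#' @return data.frame with columns `label`, `lo`, `hi` (class
#'   `tissue_scheme`), ordered from densest to least dense.
#' @export
tissue_scheme <- function() {
  structure(data.frame(
    label = c("Calcification", "Fibrous", "Heme", "Fluid", "Fat"),
    lo = c(130, 65, 13, -5, -1000),
    hi = c(1000, 129, 64, 12, -6),
    stringsAsFactors = FALSE), class = c("tissue_scheme", "data.frame"))
}

#' Label HU values with their tissue-composition class
#'
#' @param hu numeric vector of HU in \[-1000, 1000\] (integerized
#'   half-away-from-zero before lookup).
#' @param scheme a [tissue_scheme()].
#' @return factor with the scheme's labels as levels.
#' @export
label_tissue <- function(hu, scheme = tissue_scheme()) {
  hu <- round_half_away(hu)
  if (any(hu < -1000 | hu > 1000))
    stop_pericor("HU outside [-1000, 1000]",
                 class = "pericor_validation_error")
  # breaks at the lower edges of Fluid/Heme/Fibrous/Calcification
  idx <- findInterval(hu, c(-5, 13, 65, 130)) + 1L
  factor(c("Fat", "Fluid", "Heme", "Fibrous", "Calcification")[idx],
         levels = scheme$label)
}

#' Equivalent dose in 2 Gy fractions (EQD2)
#'
#' Linear-quadratic fractionation correction:
#' `EQD2 = D * (d + a/b) / (2 + a/b)` with total dose `D`, dose per
#' fraction `d`, and tissue repair ratio `a/b` (Gy). The default
#' `alpha_beta_gy = 3` is the late-responding cardiac tissue convention.
#' Vectorized; applied voxelwise to dose grids before any binning.
#'
#' @param total_dose_gy total physical dose, Gy.
#' @param dose_per_fraction_gy dose per fraction, Gy.
#' @param alpha_beta_gy alpha/beta ratio, Gy (> 0).
#' @return EQD2 in Gy, same shape as `total_dose_gy`.
#' @export
eqd2 <- function(total_dose_gy, dose_per_fraction_gy, alpha_beta_gy = 3) {
  if (any(total_dose_gy < 0) || any(dose_per_fraction_gy < 0) ||
      alpha_beta_gy <= 0)
    stop_pericor("doses must be >= 0 and alpha/beta > 0",
                 class = "pericor_validation_error")
  total_dose_gy * (dose_per_fraction_gy + alpha_beta_gy) /
    (2 + alpha_beta_gy)
}

#' Voxelwise EQD2 grid for a patient's dose
#'
#' @param dose a [dose_grid()].
#' @param alpha_beta_gy see [eqd2()].
#' @return 3-D numeric array of EQD2, Gy.
#' @export
eqd2_grid <- function(dose, alpha_beta_gy = 3) {
  stopifnot(inherits(dose, "dose_grid"))
  eqd2(dose$physical_dose, dose$dose_per_fraction_map, alpha_beta_gy)
}

#' Mean-dose bin edges
#'
#' The EQD2 dose groups used for cohort stratification:
#' \[0, 0.2), \[0.2, 2), \[2, 5), \[5, 12.5), \[12.5, 20), \[20, Inf) Gy;
#' left-closed, right-open.
#'
#' @return numeric vector of edges including 0 and `Inf`.
#' @export
dose_bin_edges <- function() c(0, 0.2, 2, 5, 12.5, 20, Inf)

#' Assign doses to dose bins
#'
#' @param dose_gy numeric vector (EQD2, Gy), non-negative.
#' @param edges increasing edges as from [dose_bin_edges()].
#' @return factor of interval labels such as `"[0,0.2)"`.
#' @export
bin_dose <- function(dose_gy, edges = dose_bin_edges()) {
  if (any(dose_gy < 0))
    stop_pericor("dose must be non-negative",
                 class = "pericor_validation_error")
  labs <- dose_bin_labels(edges)
  idx <- findInterval(dose_gy, edges, left.open = FALSE)
  factor(labs[idx], levels = labs)
}

dose_bin_labels <- function(edges = dose_bin_edges()) {
  n <- length(edges) - 1L
  vapply(seq_len(n), function(i) {
    if (is.infinite(edges[i + 1])) sprintf(">=%g", edges[i])
    else sprintf("[%g,%g)", edges[i], edges[i + 1])
  }, character(1))
}

#' Volume-weighted mean dose over a region
#'
#' @param dose_values 3-D array (e.g. from [eqd2_grid()]).
#' @param region a non-empty [binary_mask()].
#' @return mean dose in Gy.
#' @export
mean_region_dose <- function(dose_values, region) {
  stopifnot(inherits(region, "binary_mask"))
  if (!any(region$voxels))
    stop_pericor("region is empty", class = "pericor_validation_error")
  mean(dose_values[region$voxels])
}

#' Per-HU-change volume curve (biomarker 1)
#'
#' For each integer HU difference `dHU = HU_baseline - HU_followup`, the
#' percent of pericardial (shell) volume whose voxels changed by exactly
#' that amount. The curve sums to 100 per patient by construction (the
#' per-patient normalization by total shell volume).
#'
#' @param baseline,followup congruent [image_volume()] objects.
#' @param shell non-empty [binary_mask()] (the pericardial shell).
#' @return object of class `delta_huv_curve`: fields `delta_hu`
#'   (-2000:2000) and `pct` (percent volume, sums to 100).
#' @export
delta_huv <- function(baseline, followup, shell) {
  v <- shell_delta(baseline, followup, shell)
  counts <- tabulate(as.integer(v$dhu) + 2001L, nbins = 4001L)
  structure(list(delta_hu = -2000:2000,
                 pct = 100 * counts / length(v$dhu)),
            class = "delta_huv_curve")
}

# shared voxel extraction for the longitudinal biomarkers
shell_delta <- function(baseline, followup, shell) {
  stopifnot(inherits(baseline, "image_volume"),
            inherits(followup, "image_volume"),
            inherits(shell, "binary_mask"))
  if (!grids_congruent(baseline, followup) ||
      !grids_congruent(baseline, shell))
    stop_pericor("baseline, follow-up and shell grids are incongruent",
                 class = "pericor_validation_error")
  if (!any(shell$voxels))
    stop_pericor("shell is empty", class = "pericor_validation_error")
  hb <- round_half_away(clip_hu(baseline$voxels[shell$voxels]))
  hf <- round_half_away(clip_hu(followup$voxels[shell$voxels]))
  list(hb = hb, hf = hf, dhu = hb - hf, voxvol = prod(baseline$spacing))
}

#' Cohort mean HU-change curves per dose bin
#'
#' Unweighted mean of per-patient curves within each mean-pericardium-dose
#' bin. Bins with no patients are absent from the result, not zero.
#'
#' @param curves list of `delta_huv_curve` objects.
#' @param mean_doses numeric, one mean pericardial EQD2 per curve, Gy.
#' @param edges dose-bin edges, see [dose_bin_edges()].
#' @return named list (one element per non-empty bin) of
#'   `delta_huv_curve` objects.
#' @export
aggregate_delta_huv <- function(curves, mean_doses,
                                edges = dose_bin_edges()) {
  stopifnot(length(curves) == length(mean_doses))
  bins <- bin_dose(mean_doses, edges)
  out <- list()
  for (b in levels(bins)) {
    in_bin <- which(bins == b)
    if (!length(in_bin)) next
    m <- vapply(curves[in_bin], function(cu) cu$pct, numeric(4001L))
    out[[b]] <- structure(list(delta_hu = -2000:2000,
                               pct = rowMeans(as.matrix(m))),
                          class = "delta_huv_curve")
  }
  out
}

#' Per-tissue, per-dose voxel mass change (biomarker 2)
#'
#' Percent pericardial mass change between baseline and follow-up,
#' resolved by tissue-composition class and voxel-dose bin. Mass is
#' proxied linearly by `(HU + 1000) * voxel volume`. For each cell
#' (tissue `T`, dose bin `D`):
#' `VMC = 100 * sum(dHU * V over shell voxels with EQD2 in D and tissue T)
#'        / sum((HU_baseline + 1000) * V over all shell voxels)`
#' with `dHU = HU_baseline - HU_followup`; positive values mean mass
#' *decrease* from baseline to follow-up. Tissue class is read at
#' follow-up by default (where the voxel ended up), switchable to
#' baseline.
#'
#' @param baseline,followup congruent [image_volume()] objects.
#' @param shell non-empty [binary_mask()].
#' @param dose_eqd2 3-D array of voxel EQD2 (see [eqd2_grid()]).
#' @param scheme a [tissue_scheme()].
#' @param edges voxel-dose bin edges (the cohort mean-dose edges applied
#'   per voxel).
#' @param label_timepoint `"followup"` (default) or `"baseline"`.
#' @return object of class `vmc_table`: matrix of percent mass change,
#'   rows = tissue labels, columns = dose bins.
#' @export
vmc <- function(baseline, followup, shell, dose_eqd2,
                scheme = tissue_scheme(), edges = dose_bin_edges(),
                label_timepoint = c("followup", "baseline")) {
  label_timepoint <- match.arg(label_timepoint)
  v <- shell_delta(baseline, followup, shell)
  denom <- sum((v$hb + 1000) * v$voxvol)
  if (denom <= 0)
    stop_pericor("degenerate shell: total baseline mass proxy is zero",
                 class = "pericor_degenerate_error")
  hu_lab <- if (label_timepoint == "followup") v$hf else v$hb
  tissue <- label_tissue(hu_lab, scheme)
  dbin <- bin_dose(dose_eqd2[shell$voxels], edges)
  num <- tapply(v$dhu * v$voxvol, list(tissue, dbin), sum, default = 0)
  tab <- 100 * num / denom
  structure(tab, class = c("vmc_table", class(tab)),
            label_timepoint = label_timepoint)
}

#' Per-tissue volume change (biomarker 3)
#'
#' Percent of pericardial volume that left (positive) or entered
#' (negative) each tissue-composition HU range between baseline and
#' follow-up:
#' `dV_T = 100 * (V_T(baseline) - V_T(followup)) / V_total`.
#' Because every voxel has exactly one label at each timepoint and the
#' shell is fixed, the changes sum to zero across tissues.
#'
#' @inheritParams vmc
#' @return object of class `delta_v_table`: named numeric vector of
#'   percent volume change per tissue label.
#' @export
delta_v <- function(baseline, followup, shell, scheme = tissue_scheme()) {
  v <- shell_delta(baseline, followup, shell)
  tb <- table(label_tissue(v$hb, scheme))
  tf <- table(label_tissue(v$hf, scheme))
  out <- 100 * (as.numeric(tb) - as.numeric(tf)) / length(v$hb)
  structure(setNames(out, scheme$label), class = "delta_v_table")
}

#' Centered moving average with shrinking edges
#'
#' Fixed odd window; near the edges the window shrinks to the available
#' neighbors, so output length equals input length and a constant series
#' is unchanged.
#'
#' @param values numeric vector.
#' @param window odd positive integer, at most `length(values)`.
#' @return numeric vector of the same length.
#' @export
smooth_curve <- function(values, window = 11L) {
  n <- length(values)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L || window > n)
    stop_pericor("window must be odd, >= 1 and <= series length",
                 class = "pericor_validation_error")
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Summary statistics of an HU-change curve
#'
#' The center of mass of the curve (mean dHU weighted by percent volume)
#' and the "upward shift" biomarker `-mean(dHU)`, positive when voxel HU
#' increased from baseline to follow-up (composition moving toward denser
#' classes).
#'
#' @param curve a `delta_huv_curve`.
#' @return list with `mean_delta_hu` and `upward_shift`.
#' @export
curve_summary <- function(curve) {
  w <- curve$pct / sum(curve$pct)
  m <- sum(curve$delta_hu * w)
  list(mean_delta_hu = m, upward_shift = -m)
}
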