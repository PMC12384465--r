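#' Region-construction parameters
#'
#' Defaults follow the study design: a 4 mm pericardial shell (the
#' outermost layer of the heart mask) and, for follow-up selection, a
#' 5 cm out-of-field ring around the heart restricted to voxels that
#' received at most 1 Gy physical dose.
#'
#' @param shell_thickness_mm shell depth measured inward from the heart
#'   surface, mm.
#' @param ring_width_mm ring extent outward from the heart surface, mm.
#' @param ring_dose_max_gy maximum physical dose inside the ring, Gy.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(shell_thickness_mm = 4, ring_width_mm = 50,
                        ring_dose_max_gy = 1) {
  if (shell_thickness_mm < 0 || ring_width_mm <= 0 || ring_dose_max_gy <= 0)
    stop_pericor("region parameters must be positive",
                 class = "pericor_validation_error")
  structure(list(shell_thickness_mm = shell_thickness_mm,
                 ring_width_mm = ring_width_mm,
                 ring_dose_max_gy = ring_dose_max_gy),
            class = "region_spec")
}

#' Euclidean distance map to a voxel set
#'
#' Distance (mm) from every voxel center to the nearest `TRUE` voxel
#' center, anisotropic spacing respected. Exact separable transform in
#' compiled code.
#'
#' @param feature 3-D logical array.
#' @param spacing per-axis voxel size, mm.
#' @return numeric array of distances; `Inf` where no feature exists.
#' @export
distance_map <- function(feature, spacing) {
  stopifnot(length(dim(feature)) == 3L, length(spacing) == 3L)
  .edt_cpp(as.logical(feature), as.integer(dim(feature)),
           as.numeric(spacing))
}

# Voxels whose center lies within `threshold` mm of the mask's digital
# boundary: the set of face-connected mask/complement transitions, each
# represented by its face midpoint. This midpoint convention is the
# least-biased simple surface model on a voxel grid — the
# center-to-center EDT overshoots boundary distances by up to half a
# step, while treating whole faces (or the complement solid) as the
# surface lets cube corners jut inward and undershoots.
#
# The center-to-center EDT to the opposite side brackets the midpoint
# distance (any segment to the nearest opposite center crosses a
# transition face, and every midpoint lies within half a step of its
# adjacent centers), so only a thin band of voxels needs exact
# point-to-midpoint checks.
interface_within <- function(mask, spacing, threshold) {
  d_in <- distance_map(!mask, spacing)    # for mask-side queries
  d_out <- distance_map(mask, spacing)    # for complement-side queries
  d0 <- ifelse(mask, d_in, d_out)
  halfdiag <- 0.5 * sqrt(sum(spacing^2))
  smax <- max(spacing)
  within <- d0 + halfdiag <= threshold    # certainly within
  band <- which(!within & d0 - smax / 2 <= threshold)
  if (length(band)) {
    qc <- sweep(arrayInd(band, dim(mask)), 2, spacing, "*")
    fc <- interface_face_midpoints(mask, spacing)
    if (nrow(fc)) {
      within[band] <- .cube_dist_leq_cpp(qc, fc, c(0, 0, 0), threshold)
    }
  }
  within
}

# midpoints (mm) of all faces separating a mask voxel from a
# face-adjacent complement voxel; the grid border is not a boundary
interface_face_midpoints <- function(mask, spacing) {
  fc <- NULL
  for (axis in 1:3) {
    s <- c(0L, 0L, 0L)
    s[axis] <- 1L
    # complement neighbor at +axis / -axis (out-of-grid is not a face)
    for (dir in c(1L, -1L)) {
      w <- which(mask & translate_array(!mask, -dir * s, pad = FALSE),
                 arr.ind = TRUE)
      if (nrow(w)) {
        m <- sweep(w, 2, spacing, "*")
        m[, axis] <- m[, axis] + dir * spacing[axis] / 2
        fc <- rbind(fc, m)
      }
    }
  }
  if (is.null(fc)) matrix(numeric(), ncol = 3) else fc
}

#' Pericardial shell of a heart mask
#'
#' The shell is taken *inside* the heart mask: voxels whose center lies
#' within `thickness_mm` of the mask's outer boundary, modeled as the
#' midpoints of the faces where mask and complement meet. A zero
#' thickness yields an empty shell — interior centers sit at least half
#' a voxel from the boundary — and the shell is always a subset of the
#' heart.
#'
#' @param heart a non-empty [binary_mask()].
#' @param thickness_mm shell depth in mm (default 4).
#' @return A [binary_mask()] with `shell` a subset of `heart`.
#' @export
pericardial_shell <- function(heart, thickness_mm = 4) {
  stopifnot(inherits(heart, "binary_mask"))
  if (!any(heart$voxels))
    stop_pericor("heart mask is empty", class = "pericor_validation_error")
  if (thickness_mm < 0)
    stop_pericor("thickness must be non-negative",
                 class = "pericor_validation_error")
  if (all(heart$voxels))
    return(binary_mask(array(FALSE, dim(heart$voxels)), heart$spacing,
                       heart$origin))
  w <- interface_within(heart$voxels, heart$spacing, thickness_mm)
  binary_mask(heart$voxels & w, heart$spacing, heart$origin)
}

#' Out-of-field reference ring around the heart
#'
#' Voxels outside the heart, within `ring_width_mm` of the heart surface,
#' that received at most `ring_dose_max_gy` physical dose. Used to compare
#' baseline and candidate follow-up HU distributions where radiotherapy
#' cannot have changed the tissue.
#'
#' @param heart a non-empty [binary_mask()].
#' @param dose a [dose_grid()] congruent with the mask.
#' @param spec a [region_spec()].
#' @return A [binary_mask()], disjoint from `heart` by construction.
#' @export
reference_ring <- function(heart, dose, spec = region_spec()) {
  stopifnot(inherits(heart, "binary_mask"), inherits(dose, "dose_grid"))
  if (!grids_congruent(heart, dose))
    stop_pericor("heart mask and dose grids are incongruent",
                 class = "pericor_validation_error")
  if (!any(heart$voxels))
    stop_pericor("heart mask is empty", class = "pericor_validation_error")
  w <- interface_within(heart$voxels, heart$spacing, spec$ring_width_mm)
  keep <- !heart$voxels & w &
    dose$physical_dose <= spec$ring_dose_max_gy
  binary_mask(keep, heart$spacing, heart$origin)
}

#' HU histogram of a region
#'
#' Integer-centered unit bins spanning -1000..1000 (2001 bins), weighted
#' by voxel volume. Values are integerized half-away-from-zero before
#' binning.
#'
#' @param volume an [image_volume()].
#' @param region a non-empty [binary_mask()] congruent with the volume.
#' @param normalize scale bin values to sum to one.
#' @return An object of class `hu_histogram` with fields `mids`
#'   (-1000:1000) and `values` (volume in mm^3, or fractions if
#'   normalized).
#' @export
hu_histogram <- function(volume, region, normalize = TRUE) {
  stopifnot(inherits(volume, "image_volume"), inherits(region, "binary_mask"))
  if (!grids_congruent(volume, region))
    stop_pericor("volume and region grids are incongruent",
                 class = "pericor_validation_error")
  if (!any(region$voxels))
    stop_pericor("region is empty", class = "pericor_validation_error")
  hu <- round_half_away(clip_hu(volume$voxels[region$voxels]))
  counts <- tabulate(as.integer(hu) + 1001L, nbins = 2001L)
  values <- counts * prod(volume$spacing)
  if (normalize) values <- values / sum(values)
  structure(list(mids = -1000:1000, values = values,
                 normalized = normalize),
            class = "hu_histogram")
}

#' Distance between two HU histograms
#'
#' @param a,b `hu_histogram` objects on the same bins.
#' @param metric `"l1"` (sum of absolute bin differences), `"l2"`
#'   (Euclidean), or `"mean_hu"` (absolute difference of the histogram
#'   means).
#' @return non-negative scalar.
#' @export
histogram_distance <- function(a, b, metric = c("l1", "l2", "mean_hu")) {
  metric <- match.arg(metric)
  pa <- a$values / sum(a$values)
  pb <- b$values / sum(b$values)
  switch(metric,
         l1 = sum(abs(pa - pb)),
         l2 = sqrt(sum((pa - pb)^2)),
         mean_hu = abs(sum(a$mids * pa) - sum(b$mids * pb)))
}

#' Select the follow-up scan best matching the baseline
#'
#' Among pre-registered candidate follow-ups, picks the one whose HU
#' distribution in the out-of-field reference ring is closest to the
#' baseline's: kernel and scanner differences show up in this region,
#' radiotherapy effects do not. Ties break to the lowest index.
#'
#' @param baseline an [image_volume()].
#' @param candidates non-empty list of [image_volume()] on the same grid.
#' @param ring a non-empty [binary_mask()] (see [reference_ring()]).
#' @param metric histogram metric, see [histogram_distance()].
#' @return list with `index` of the selected candidate and `distances`
#'   for all candidates.
#' @export
select_followup <- function(baseline, candidates, ring,
                            metric = c("l1", "l2", "mean_hu")) {
  metric <- match.arg(metric)
  if (!is.list(candidates) || length(candidates) < 1L)
    stop_pericor("candidate list is empty",
                 class = "pericor_validation_error")
  hb <- hu_histogram(baseline, ring, normalize = TRUE)
  dists <- vapply(candidates, function(cand) {
    histogram_distance(hb, hu_histogram(cand, ring, normalize = TRUE),
                       metric = metric)
  }, numeric(1))
  list(index = which.min(dists), distances = dists)
}

#' Dice overlap coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for
#' disjoint ones. Two empty masks have no defined overlap and raise an
#' error.
#'
#' @param a,b congruent [binary_mask()] objects.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!grids_congruent(a, b))
    stop_pericor("masks are on incongruent grids",
                 class = "pericor_validation_error")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L)
    stop_pericor("both masks are empty; Dice undefined",
                 class = "pericor_validation_error")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Center-of-mass alignment of a moving volume
#'
#' Integer-voxel translation bringing the moving heart mask's center of
#' mass onto the fixed one's (the initialization step of a registration
#' chain; deformable registration itself is assumed done upstream).
#' Voxels shifted in from outside the field read -1000 (air).
#'
#' @param moving an [image_volume()] to translate.
#' @param moving_heart,fixed_heart non-empty [binary_mask()] objects.
#' @return list with `volume` (translated [image_volume()]) and
#'   `shift_voxels` (integer length-3).
#' @export
com_align <- function(moving, moving_heart, fixed_heart) {
  if (!any(moving_heart$voxels) || !any(fixed_heart$voxels))
    stop_pericor("heart mask is empty", class = "pericor_validation_error")
  shift <- round(mask_com(fixed_heart) - mask_com(moving_heart))
  out <- translate_array(moving$voxels, as.integer(shift), pad = -1000)
  vol <- image_volume(out, moving$spacing, moving$origin,
                      contrast_enhanced = moving$contrast_enhanced,
                      scanner_tag = moving$scanner_tag)
  list(volume = vol, shift_voxels = as.integer(shift))
}

mask_com <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  colMeans(idx)
}

translate_array <- function(x, shift, pad = -1000) {
  d <- dim(x)
  out <- array(pad, dim = d)
  src_lo <- pmax(1L, 1L - shift)
  src_hi <- pmin(d, d - shift)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo + shift
  dst_hi <- src_hi + shift
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    x[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}
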