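# shared fixtures, all built in code

# digital sphere mask of given radius (mm) on an isotropic grid
sphere_mask <- function(radius_mm = 20, n = 50, spacing = c(1, 1, 1)) {
  ctr <- (n + 1) / 2
  x <- (seq_len(n) - ctr) * spacing[1]
  y <- (seq_len(n) - ctr) * spacing[2]
  z <- (seq_len(n) - ctr) * spacing[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  binary_mask(array(r2 <= radius_mm^2, c(n, n, n)), spacing)
}

# a small random image volume
random_volume <- function(dim3 = c(8, 8, 8), spacing = c(1, 1, 1),
                          lo = -1000, hi = 1000) {
  image_volume(array(runif(prod(dim3), lo, hi), dim3), spacing)
}

# random toy patient: n voxels with random HU and dose
random_toy <- function(n, dose_max = 40) {
  generate_toy_patient(runif(n, -1000, 1000), runif(n, -1000, 1000),
                       runif(n, 0, dose_max), n_fractions = 10L)
}

# brute-force, loop-based evaluation of the three biomarkers on a toy
# study (the independent oracle: no vectorization, no shared code paths)
oracle_biomarkers <- function(hu_base, hu_fu, dose_eqd2_vals,
                              edges = dose_bin_edges(),
                              label_timepoint = "followup") {
  sch <- tissue_scheme()
  rha <- function(x) sign(x) * floor(abs(x) + 0.5)
  hb <- rha(pmin(pmax(hu_base, -1000), 1000))
  hf <- rha(pmin(pmax(hu_fu, -1000), 1000))
  n <- length(hb)
  lab1 <- function(h) {
    for (i in seq_len(nrow(sch)))
      if (h >= sch$lo[i] && h <= sch$hi[i]) return(sch$label[i])
    stop("unlabelable")
  }
  bin1 <- function(d) {
    for (b in seq_len(length(edges) - 1))
      if (d >= edges[b] && d < edges[b + 1]) return(b)
    stop("unbinnable")
  }
  # biomarker 1
  curve <- setNames(numeric(4001), as.character(-2000:2000))
  for (v in seq_len(n)) {
    k <- as.character(hb[v] - hf[v])
    curve[k] <- curve[k] + 1
  }
  curve <- 100 * curve / n
  # biomarker 2
  vmc_tab <- matrix(0, nrow(sch), length(edges) - 1,
                    dimnames = list(sch$label, NULL))
  denom <- 0
  for (v in seq_len(n)) denom <- denom + (hb[v] + 1000)
  for (v in seq_len(n)) {
    lab <- lab1(if (label_timepoint == "followup") hf[v] else hb[v])
    b <- bin1(dose_eqd2_vals[v])
    vmc_tab[lab, b] <- vmc_tab[lab, b] + (hb[v] - hf[v])
  }
  vmc_tab <- 100 * vmc_tab / denom
  # biomarker 3
  dv <- setNames(numeric(nrow(sch)), sch$label)
  for (v in seq_len(n)) {
    dv[lab1(hb[v])] <- dv[lab1(hb[v])] + 1
    dv[lab1(hf[v])] <- dv[lab1(hf[v])] - 1
  }
  dv <- 100 * dv / n
  list(curve = curve, vmc = vmc_tab, delta_v = dv)
}

# a tiny aligned study pair on a 3-D grid for histogram/selection tests
flat_volume <- function(values, dim3, spacing = c(1, 1, 1), ...) {
  image_volume(array(values, dim3), spacing, ...)
}
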