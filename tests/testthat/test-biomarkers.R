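test_that("tissue labels follow the composition HU ranges", {
  expect_equal(as.character(label_tissue(130)), "Calcification")
  expect_equal(as.character(label_tissue(1000)), "Calcification")
  expect_equal(as.character(label_tissue(129)), "Fibrous")
  expect_equal(as.character(label_tissue(65)), "Fibrous")
  expect_equal(as.character(label_tissue(64)), "Heme")
  expect_equal(as.character(label_tissue(13)), "Heme")
  expect_equal(as.character(label_tissue(12)), "Fluid")
  expect_equal(as.character(label_tissue(-5)), "Fluid")
  expect_equal(as.character(label_tissue(-6)), "Fat")
  expect_equal(as.character(label_tissue(-1000)), "Fat")
  expect_error(label_tissue(1001), class = "pericor_validation_error")
  # every integer HU maps to exactly one label (partition)
  hu <- -1000:1000
  expect_false(any(is.na(label_tissue(hu))))
})

test_that("EQD2 conversion matches the linear-quadratic closed form", {
  expect_equal(eqd2(50, 2, 3), 50)          # 2 Gy/fx fixed point
  expect_equal(eqd2(45, 1.5, 3), 40.5)
  expect_equal(eqd2(0, 0, 3), 0)
  # linear in total dose at fixed d/fx
  expect_equal(eqd2(2 * 45, 1.5, 3), 2 * eqd2(45, 1.5, 3))
  expect_error(eqd2(-1, 2, 3), class = "pericor_validation_error")
  expect_error(eqd2(10, 2, 0), class = "pericor_validation_error")
})

test_that("dose bins are left-closed right-open with the cohort edges", {
  b <- bin_dose(c(0, 0.19, 0.2, 1.99, 2, 5, 12.49, 12.5, 19.9, 20, 80))
  expect_equal(as.character(b),
               c("[0,0.2)", "[0,0.2)", "[0.2,2)", "[0.2,2)", "[2,5)",
                 "[5,12.5)", "[5,12.5)", "[12.5,20)", "[12.5,20)",
                 ">=20", ">=20"))
})

test_that("mean region dose equals the brute-force average", {
  set.seed(8)
  d <- c(6, 6, 6)
  vals <- array(runif(216, 0, 50), d)
  reg <- binary_mask(array(runif(216) < 0.4, d), c(1, 1, 1))
  reg$voxels[1] <- TRUE
  expect_equal(mean_region_dose(vals, reg),
               sum(vals[reg$voxels]) / sum(reg$voxels))
  expect_equal(mean_region_dose(array(5, d), reg), 5)
  expect_error(mean_region_dose(vals, binary_mask(array(FALSE, d),
                                                  c(1, 1, 1))),
               class = "pericor_validation_error")
})

test_that("the HU-change curve is a conserved per-patient distribution", {
  toy <- generate_toy_patient(c(0, 7), c(-5, 7), c(1, 1))
  shell <- toy$heart_mask
  cu <- delta_huv(toy$baseline, toy$followup_candidates[[1]], shell)
  expect_equal(sum(cu$pct), 100, tolerance = 1e-9)
  expect_equal(cu$pct[cu$delta_hu == 5], 50)
  expect_equal(cu$pct[cu$delta_hu == 0], 50)
  # identity pair concentrates at zero
  cu0 <- delta_huv(toy$baseline, toy$baseline, shell)
  expect_equal(cu0$pct[cu0$delta_hu == 0], 100)
})

test_that("per-dose-bin aggregation is the unweighted patient mean", {
  set.seed(13)
  toys <- lapply(1:3, function(i) random_toy(60))
  curves <- lapply(toys, function(t)
    delta_huv(t$baseline, t$followup_candidates[[1]], t$heart_mask))
  # all three in one bin: plain mean
  agg <- aggregate_delta_huv(curves, c(3, 4, 4.5))
  expect_length(agg, 1)
  expect_equal(agg[["[2,5)"]]$pct,
               (curves[[1]]$pct + curves[[2]]$pct + curves[[3]]$pct) / 3)
  # one patient per bin: identity; empty bins absent
  agg2 <- aggregate_delta_huv(curves, c(0.1, 3, 25))
  expect_setequal(names(agg2), c("[0,0.2)", "[2,5)", ">=20"))
  expect_equal(agg2[[">=20"]]$pct, curves[[3]]$pct)
})

test_that("single-voxel mass-change worked example is exact", {
  toy <- generate_toy_patient(0, 10, 5)
  v <- vmc(toy$baseline, toy$followup_candidates[[1]], toy$heart_mask,
           eqd2_grid(toy$dose))
  # 100 * (0 - 10) / (0 + 1000) = -1.0, in the Fluid row (HU 10 at
  # follow-up) and the voxel-dose bin of EQD2(5 Gy at 5 Gy/fx) = 8 Gy
  expect_equal(v["Fluid", "[5,12.5)"], -1)
  expect_equal(sum(v != 0), 1)
  # identity pair: all cells zero
  v0 <- vmc(toy$baseline, toy$baseline, toy$heart_mask,
            eqd2_grid(toy$dose))
  expect_true(all(v0 == 0))
})

test_that("mass-change sign convention: HU increase at follow-up is negative", {
  toy <- generate_toy_patient(c(20, 20), c(90, 20), c(1, 1))
  v <- vmc(toy$baseline, toy$followup_candidates[[1]], toy$heart_mask,
           eqd2_grid(toy$dose))
  expect_lt(sum(v), 0)
})

test_that("two-voxel volume-change worked example is exact and conserved", {
  toy <- generate_toy_patient(c(-100, -100), c(-100, 0), c(0, 0))
  dv <- delta_v(toy$baseline, toy$followup_candidates[[1]], toy$heart_mask)
  expect_equal(unname(dv["Fat"]), 50)
  expect_equal(unname(dv["Fluid"]), -50)
  expect_equal(unname(dv[c("Calcification", "Fibrous", "Heme")]),
               c(0, 0, 0))
  expect_equal(sum(dv), 0, tolerance = 1e-9)
})

test_that("biomarkers match the brute-force voxel-loop oracle", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(100:500, 1)
    hb <- runif(n, -1000, 1000)
    hf <- runif(n, -1000, 1000)
    dose <- runif(n, 0, 40)
    toy <- generate_toy_patient(hb, hf, dose, n_fractions = 10L)
    de <- eqd2_grid(toy$dose)
    orc <- oracle_biomarkers(hb, hf, as.vector(de))
    cu <- delta_huv(toy$baseline, toy$followup_candidates[[1]],
                    toy$heart_mask)
    expect_equal(cu$pct, unname(orc$curve), tolerance = 1e-9)
    v <- vmc(toy$baseline, toy$followup_candidates[[1]], toy$heart_mask, de)
    expect_equal(unname(unclass(v)), unname(orc$vmc), tolerance = 1e-9,
                 ignore_attr = TRUE)
    dv <- delta_v(toy$baseline, toy$followup_candidates[[1]],
                  toy$heart_mask)
    expect_equal(as.numeric(dv), unname(orc$delta_v), tolerance = 1e-9)
    expect_equal(sum(cu$pct), 100, tolerance = 1e-6)
    expect_equal(sum(dv), 0, tolerance = 1e-6)
  }
})

test_that("uniform follow-up HU increase makes total mass change more negative", {
  set.seed(19)
  n <- 300
  hb <- runif(n, -500, 500)
  hf <- runif(n, -500, 500)
  toy1 <- generate_toy_patient(hb, hf, 5)
  toy2 <- generate_toy_patient(hb, hf + 25, 5)
  de <- eqd2_grid(toy1$dose)
  s1 <- sum(vmc(toy1$baseline, toy1$followup_candidates[[1]],
                toy1$heart_mask, de))
  s2 <- sum(vmc(toy2$baseline, toy2$followup_candidates[[1]],
                toy2$heart_mask, de))
  expect_lt(s2, s1)
})

test_that("tissue volumes partition the shell at each timepoint", {
  set.seed(23)
  toy <- random_toy(400)
  for (img in list(toy$baseline, toy$followup_candidates[[1]])) {
    labs <- label_tissue(pericor:::round_half_away(
      clip_hu(img$voxels[toy$heart_mask$voxels])))
    expect_equal(sum(table(labs)), 400)
  }
})

test_that("moving average smoothing shrinks at the edges", {
  expect_equal(smooth_curve(c(4, 8, 15), 1), c(4, 8, 15))
  expect_equal(smooth_curve(rep(7, 10), 5), rep(7, 10))
  expect_equal(smooth_curve(c(0, 3, 0), 3), c(1.5, 1, 1.5))
  x <- c(1, 2, 3, 4, 5)
  expect_equal(smooth_curve(x, 3), c(1.5, 2, 3, 4, 4.5))
  expect_error(smooth_curve(x, 2), class = "pericor_validation_error")
  expect_error(smooth_curve(x, 7), class = "pericor_validation_error")
})
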