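test_that("distance map equals brute force on anisotropic grids", {
  set.seed(42)
  d <- c(9, 7, 6)
  sp <- c(1.5, 2, 0.8)
  m <- array(runif(prod(d)) < 0.15, d)
  m[3, 3, 3] <- TRUE
  dm <- distance_map(m, sp)
  idx <- which(m, arr.ind = TRUE)
  for (v in sample(prod(d), 40)) {
    ijk <- arrayInd(v, d)
    bf <- min(sqrt(((idx[, 1] - ijk[1]) * sp[1])^2 +
                   ((idx[, 2] - ijk[2]) * sp[2])^2 +
                   ((idx[, 3] - ijk[3]) * sp[3])^2))
    expect_equal(dm[v], bf, tolerance = 1e-10)
  }
})

test_that("4 mm shell of a 20 mm sphere matches the analytic volume", {
  heart <- sphere_mask(20, n = 50)
  shell <- pericardial_shell(heart, 4)
  analytic <- 4 / 3 * pi * (20^3 - 16^3)
  expect_lt(abs(sum(shell$voxels) * 1 - analytic) / analytic, 0.05)
  expect_true(all(!(shell$voxels & !heart$voxels)))  # shell inside heart
})

test_that("shell limits: zero thickness empty, full thickness whole mask", {
  heart <- sphere_mask(20, n = 50)
  expect_false(any(pericardial_shell(heart, 0)$voxels))
  expect_identical(pericardial_shell(heart, 25)$voxels, heart$voxels)
  expect_error(pericardial_shell(binary_mask(array(FALSE, c(3, 3, 3)),
                                             c(1, 1, 1))),
               class = "pericor_validation_error")
})

test_that("shell is monotone in thickness", {
  heart <- sphere_mask(12, n = 32, spacing = c(1, 1.5, 2))
  prev <- pericardial_shell(heart, 0)$voxels
  for (t in c(2, 4, 8)) {
    cur <- pericardial_shell(heart, t)$voxels
    expect_true(all(!(prev & !cur)))
    prev <- cur
  }
})

test_that("reference ring is the dose-filtered annulus, disjoint from heart", {
  heart <- sphere_mask(10, n = 40, spacing = c(2, 2, 2))
  d0 <- dose_grid(array(0, c(40, 40, 40)), c(2, 2, 2))
  ring <- reference_ring(heart, d0)
  expect_true(any(ring$voxels))
  expect_false(any(ring$voxels & heart$voxels))
  # all-10 Gy dose removes everything
  d10 <- dose_grid(array(10, c(40, 40, 40)), c(2, 2, 2))
  expect_false(any(reference_ring(heart, d10)$voxels))
  # half-space dose restricts the ring to the 0 Gy half exactly
  half <- array(rep(c(0, 2), each = 20), c(40, 40, 40))
  rh <- reference_ring(heart, dose_grid(half, c(2, 2, 2)))
  full <- reference_ring(heart, d0)
  expect_identical(rh$voxels, full$voxels & half <= 1)
  # incongruent grids rejected
  d_bad <- dose_grid(array(0, c(40, 40, 40)), c(1, 1, 1))
  expect_error(reference_ring(heart, d_bad),
               class = "pericor_validation_error")
})

test_that("HU histograms match a brute-force tally and normalize exactly", {
  set.seed(5)
  d <- c(10, 10, 10)
  vol <- image_volume(array(round(runif(1000, -200, 300)), d), c(1, 2, 1))
  reg <- binary_mask(array(runif(1000) < 0.5, d), c(1, 2, 1))
  reg$voxels[1] <- TRUE
  h <- hu_histogram(vol, reg, normalize = FALSE)
  tally <- table(factor(vol$voxels[reg$voxels], levels = -1000:1000)) * 2
  expect_equal(unname(h$values), as.vector(unname(tally)))
  hn <- hu_histogram(vol, reg, normalize = TRUE)
  expect_equal(sum(hn$values), 1, tolerance = 1e-9)
  # degenerate cases
  one <- image_volume(array(0, c(4, 1, 1)), c(1, 1, 1))
  m <- binary_mask(array(TRUE, c(4, 1, 1)), c(1, 1, 1))
  h1 <- hu_histogram(one, m)
  expect_equal(h1$values[h1$mids == 0], 1)
  two <- image_volume(array(c(-5, 12), c(2, 1, 1)), c(1, 1, 1))
  m2 <- binary_mask(array(TRUE, c(2, 1, 1)), c(1, 1, 1))
  h2 <- hu_histogram(two, m2)
  expect_equal(unname(h2$values[h2$mids %in% c(-5, 12)]), c(0.5, 0.5))
  expect_error(hu_histogram(one, binary_mask(array(FALSE, c(4, 1, 1)),
                                             c(1, 1, 1))),
               class = "pericor_validation_error")
})

test_that("follow-up selection picks the least-noise candidate", {
  set.seed(9)
  d <- c(20, 20, 20)
  base <- image_volume(array(round(rnorm(prod(d), -100, 30)), d), c(2, 2, 2))
  ring <- binary_mask(array(runif(prod(d)) < 0.4, d), c(2, 2, 2))
  # exact copy beats an offset copy
  cand_a <- base
  cand_b <- image_volume(base$voxels + 50, c(2, 2, 2))
  sel <- select_followup(base, list(cand_b, cand_a), ring)
  expect_identical(sel$index, 2L)
  expect_equal(sel$distances[2], 0)
  # single candidate: trivially index 1
  expect_identical(select_followup(base, list(cand_b), ring)$index, 1L)
  # kernel-noise ladder: sigma 5 wins nearly always
  wins <- 0L
  for (rep in 1:25) {
    cands <- lapply(c(20, 5, 40), function(s)
      image_volume(base$voxels + round(rnorm(prod(d), 0, s)), c(2, 2, 2)))
    if (select_followup(base, cands, ring)$index == 2L) wins <- wins + 1L
  }
  expect_gte(wins, 24L)
  # order invariance up to tie-breaking: permuting candidates permutes pick
  cands <- lapply(c(5, 20, 40), function(s)
    image_volume(base$voxels + round(rnorm(prod(d), 0, s)), c(2, 2, 2)))
  s1 <- select_followup(base, cands, ring)
  s2 <- select_followup(base, rev(cands), ring)
  expect_identical(s1$index, 1L)
  expect_identical(s2$index, 3L)
})

test_that("Dice coefficient handles identity, disjoint and partial overlap", {
  sp <- c(1, 1, 1)
  a <- binary_mask(array(rep(c(TRUE, FALSE), c(8, 19)), c(3, 3, 3)), sp)
  expect_equal(dice(a, a), 1)
  b <- binary_mask(array(rep(c(FALSE, TRUE, FALSE), c(8, 4, 15)),
                         c(3, 3, 3)), sp)
  expect_equal(dice(a, b), 0)
  half <- a
  half$voxels[1:4] <- FALSE   # 4 of the 8 remain
  expect_equal(dice(a, half), 2 * 4 / (8 + 4))
  expect_equal(dice(a, half), dice(half, a))
  empty <- binary_mask(array(FALSE, c(3, 3, 3)), sp)
  expect_error(dice(empty, empty), class = "pericor_validation_error")
})

test_that("center-of-mass alignment recovers integer shifts and pads air", {
  set.seed(3)
  d <- c(16, 16, 16)
  fixed <- sphere_mask(4, n = 16, spacing = c(1, 1, 1))
  vol <- image_volume(array(round(runif(prod(d), -100, 100)), d), c(1, 1, 1))
  # identical masks: identity
  al0 <- com_align(vol, fixed, fixed)
  expect_identical(al0$shift_voxels, c(0L, 0L, 0L))
  expect_identical(al0$volume$voxels, vol$voxels)
  # constructed (3, 0, 0) translation is recovered
  moved <- binary_mask(pericor:::translate_array(fixed$voxels, c(3L, 0L, 0L),
                                                 pad = FALSE), c(1, 1, 1))
  al <- com_align(vol, moved, fixed)
  expect_identical(al$shift_voxels, c(-3L, 0L, 0L))
  expect_true(all(al$volume$voxels[14:16, , ] == -1000))
})
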