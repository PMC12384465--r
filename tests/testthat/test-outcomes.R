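# independent permutation enumeration for the small-n Spearman oracle:
# iterative Heap's algorithm, distinct from the package's recursive one
heap_perms <- function(n) {
  out <- matrix(0L, 0L, n)
  a <- seq_len(n)
  c_ <- integer(n)
  out <- rbind(out, a)
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) a[c(1L, i)] <- a[c(i, 1L)]
      else { j <- c_[i] + 1L; a[c(j, i)] <- a[c(i, j)] }
      out <- rbind(out, a)
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

test_that("Spearman handles monotone, antitone and degenerate inputs", {
  x <- c(1, 3, 9, 12, 20, 33, 40, 41, 50, 60)
  expect_equal(spearman_test(x, x^3)$effect, 1)
  expect_equal(spearman_test(x, rev(x))$effect, -1)
  expect_error(spearman_test(x, rep(1, 10)),
               class = "pericor_validation_error")
  expect_error(spearman_test(1:2, 2:1), class = "pericor_validation_error")
})

test_that("small-n Spearman p equals the exhaustive permutation oracle", {
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4)
  res <- spearman_test(x, y)
  rx <- rank(x); ry <- rank(y)
  perms <- heap_perms(6)
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  p_oracle <- mean(abs(rhos) >= abs(cor(rx, ry)) - 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(res$effect, cor(rx, ry), tolerance = 1e-12)
  # tie-free case agrees with the classical exact test
  x2 <- c(3, 1, 4, 1.5, 9, 2.6)
  y2 <- c(2, 7, 1.8, 2.8, 1, 8)
  ct <- suppressWarnings(cor.test(x2, y2, method = "spearman",
                                  exact = TRUE))
  expect_equal(spearman_test(x2, y2)$p_value, unname(ct$p.value),
               tolerance = 1e-12)
})

test_that("large-n Spearman p uses the t approximation", {
  set.seed(31)
  x <- rnorm(40); y <- x + rnorm(40, 0, 2)
  res <- spearman_test(x, y)
  r <- cor(x, y, method = "spearman")
  tt <- r * sqrt(38 / (1 - r^2))
  expect_equal(res$p_value, 2 * pt(-abs(tt), 38), tolerance = 1e-12)
})

test_that("Pearson correlation matches affine and orthogonal constructions", {
  x <- c(0.4, 1.1, 2.2, 3.9, 4.1, 6)
  expect_equal(pearson_test(x, 2 * x + 1)$effect, 1)
  expect_equal(pearson_test(x, -x)$effect, -1)
  # residualized y is exactly uncorrelated with x
  set.seed(33)
  y <- rnorm(6)
  y_orth <- residuals(lm(y ~ x))
  expect_lt(abs(pearson_test(x, y_orth)$effect), 1e-12)
  ct <- cor.test(x, c(1, 3, 2, 5, 4, 5.5))
  res <- pearson_test(x, c(1, 3, 2, 5, 4, 5.5))
  expect_equal(res$p_value, unname(ct$p.value), tolerance = 1e-10)
})

test_that("Kaplan-Meier matches hand product-limit tables", {
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km_surv_at(km, c(0.5, 1.5, 2.5)), c(1, 0.5, 0))
  # n = 5 mixed censoring: deaths at 1, 3, 5; censored at 2, 4
  # S(1) = 4/5; S(3) = 4/5 * 2/3; S(5) = 0
  km2 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  expect_equal(km_surv_at(km2, c(1, 3, 5)), c(4 / 5, 8 / 15, 0))
  # all censored: survival stays 1
  km3 <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_equal(km_surv_at(km3, c(1, 5, 100)), c(1, 1, 1))
  # monotone non-increasing within [0, 1]
  set.seed(35)
  km4 <- km_estimate(rexp(50, 0.1), rbinom(50, 1, 0.7))
  expect_true(all(diff(km4$surv) <= 1e-12))
  expect_true(all(km4$surv >= 0 & km4$surv <= 1))
  # no censoring: equals the empirical survival function
  tt <- c(2, 4, 4, 7, 9)
  km5 <- km_estimate(tt, rep(1, 5))
  expect_equal(km_surv_at(km5, c(2, 4, 7, 9)),
               c(4 / 5, 2 / 5, 1 / 5, 0))
})

test_that("log-rank is null on duplicated groups and detects planted hazards", {
  tt <- c(5, 8, 12, 20, 33)
  ev <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
  # label swap leaves the statistic unchanged
  set.seed(11)
  t1 <- rexp(200, 0.001); t2 <- rexp(200, 0.003)
  time <- c(t1, t2); event <- rep(1L, 400)
  g <- rep(c("a", "b"), each = 200)
  lr1 <- logrank_test(time, event, g)
  lr2 <- logrank_test(time, event, ifelse(g == "a", "b", "a"))
  expect_equal(lr1$statistic, lr2$statistic, tolerance = 1e-9)
  expect_lt(lr1$p_value, 0.05)
  # degenerate: no events at all is an error
  expect_error(logrank_test(tt, rep(0, 5), c("a", "a", "b", "b", "b")),
               class = "pericor_validation_error")
})

test_that("hazard ratio recovers a planted effect and flags zero-event groups", {
  set.seed(3)
  n <- 500
  t1 <- rexp(n, 0.001); t2 <- rexp(n, 0.002)
  cens <- 2000
  time <- c(pmin(t1, cens), pmin(t2, cens))
  event <- c(as.integer(t1 <= cens), as.integer(t2 <= cens))
  g <- factor(rep(c("low", "high"), each = n), levels = c("low", "high"))
  hr <- hazard_ratio(time, event, g)
  expect_gt(hr$effect, 1.6)
  expect_lt(hr$effect, 2.5)
  expect_true(hr$ci_low < 2 && hr$ci_high > 2)
  # duplicated groups: HR exactly 1 under Breslow ties
  tt <- c(5, 8, 12, 20, 33); ev <- c(1, 0, 1, 1, 0)
  hr1 <- hazard_ratio(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(hr1$effect, 1, tolerance = 1e-8)
  # zero events in one group: flagged, not infinite
  hr2 <- hazard_ratio(c(tt, tt), c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                      rep(c("a", "b"), each = 5))
  expect_false(hr2$estimable)
  expect_true(is.na(hr2$effect))
  expect_error(hazard_ratio(tt, rep(0, 5), c("a", "a", "b", "b", "b")),
               class = "pericor_validation_error")
})

test_that("permuted group labels give a null hazard ratio most of the time", {
  set.seed(41)
  n <- 100
  tt <- rexp(2 * n, 0.001)
  ev <- rep(1L, 2 * n)
  cover <- 0L
  for (s in 1:20) {
    g <- sample(rep(c("a", "b"), n))
    hr <- hazard_ratio(tt, ev, g)
    if (hr$ci_low <= 1 && hr$ci_high >= 1) cover <- cover + 1L
  }
  expect_gte(cover, 18L)
})

test_that("mean split puts boundary values in the low group", {
  g <- dichotomize_at_mean(c(0, 10))
  expect_identical(as.character(g), c("low", "high"))
  g2 <- dichotomize_at_mean(c(1, 2, 3, 4))   # mean 2.5: balanced
  expect_equal(sum(g2 == "high"), 2)
  g3 <- dichotomize_at_mean(c(1, 2, 3))      # 2 == mean goes low
  expect_identical(as.character(g3), c("low", "low", "high"))
  expect_error(dichotomize_at_mean(c(2, 2, 2)),
               class = "pericor_validation_error")
})
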