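#' Statistical test result container
#'
#' @param statistic test statistic.
#' @param p_value two-sided p value.
#' @param effect effect size (rho, r, or hazard ratio).
#' @param ci_low,ci_high 95% confidence bounds for `effect` (may be NA).
#' @param n sample size.
#' @param method short description.
#' @param estimable `FALSE` flags a non-estimable effect (e.g. a hazard
#'   ratio when one group has no events).
#' @return object of class `pericor_test`.
#' @export
test_result <- function(statistic, p_value, effect, ci_low = NA_real_,
                        ci_high = NA_real_, n = NA_integer_,
                        method = "", estimable = TRUE) {
  structure(list(statistic = statistic, p_value = p_value, effect = effect,
                 ci_low = ci_low, ci_high = ci_high, n = n,
                 method = method, estimable = estimable),
            class = "pericor_test")
}

#' @export
print.pericor_test <- function(x, ...) {
  cat(sprintf("<%s> effect = %s, p = %.4g, n = %d%s\n",
              x$method, format(x$effect, digits = 4), x$p_value, x$n,
              if (!is.na(x$ci_low))
                sprintf(" [95%% CI %.3g-%.3g]", x$ci_low, x$ci_high)
              else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Average ranks for ties. The p value uses the t approximation for
#' n >= 10 and an exhaustive permutation distribution for n < 10 (where
#' the approximation is poor and ties rule out the classical exact
#' tables).
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return a [test_result()] with `effect` = rho.
#' @export
spearman_test <- function(x, y) {
  check_corr_input(x, y)
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n >= 10) {
    p <- t_corr_p(rho, n)
  } else {
    perms <- all_perms(n)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- colSums(rxc * matrix(ryc[perms], nrow = n)) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  test_result(statistic = rho, p_value = p, effect = rho, n = n,
              method = "Spearman rank correlation")
}

#' Pearson correlation
#'
#' Product-moment correlation with two-sided p from the t distribution
#' with n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return a [test_result()] with `effect` = r.
#' @export
pearson_test <- function(x, y) {
  check_corr_input(x, y)
  n <- length(x)
  r <- cor(x, y)
  test_result(statistic = r, p_value = t_corr_p(r, n), effect = r, n = n,
              method = "Pearson correlation")
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y))
    stop_pericor("x and y must have equal length",
                 class = "pericor_validation_error")
  if (length(x) < 3)
    stop_pericor("need at least 3 observations",
                 class = "pericor_validation_error")
  if (sd(x) == 0 || sd(y) == 0)
    stop_pericor("correlation undefined for a constant vector",
                 class = "pericor_validation_error")
}

t_corr_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tt), df = n - 2)
}

# all permutations of 1..n as an n x n! integer matrix (n <= 9)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  blocks <- lapply(seq_len(n), function(pos) {
    top <- if (pos > 1L) sub[seq_len(pos - 1L), , drop = FALSE] else NULL
    bot <- if (pos < n) sub[pos:(n - 1L), , drop = FALSE] else NULL
    rbind(top, matrix(n, 1L, ncol(sub)), bot)
  })
  do.call(cbind, blocks)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with right censoring; survival is 1 at time
#' zero and steps down at event times.
#'
#' @param time positive event/censoring times (days).
#' @param event 1 = event observed, 0 = censored.
#' @return object of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `surv`, plus the underlying `survival::survfit` fit.
#' @export
km_estimate <- function(time, event) {
  if (!length(time))
    stop_pericor("empty survival sample", class = "pericor_validation_error")
  if (any(time <= 0))
    stop_pericor("times must be positive", class = "pericor_validation_error")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv, fit = fit),
            class = "km_curve")
}

#' Survival probability at given times
#'
#' @param km a `km_curve`.
#' @param t times at which to evaluate (S(t) = 1 for t before the first
#'   event).
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt & km$n_event > 0)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Two-sample log-rank test
#'
#' @param time,event as in [km_estimate()].
#' @param group binary group labels (both levels present).
#' @return a [test_result()] with the chi-square statistic (1 df).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop_pericor("log-rank needs exactly two non-empty groups",
                 class = "pericor_validation_error")
  if (sum(event) == 0)
    stop_pericor("no events in either group; log-rank undefined",
                 class = "pericor_validation_error")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  test_result(statistic = sd_$chisq, p_value = p, effect = NA_real_,
              n = length(time), method = "log-rank")
}

#' Univariable hazard ratio between two groups
#'
#' Proportional-hazards fit on the binary group indicator (Breslow tie
#' handling), reporting the hazard of the second factor level relative to
#' the first with a Wald 95% CI on the log scale. When one group has no
#' events the ratio is not estimable and is returned flagged rather than
#' as an infinity.
#'
#' @inheritParams logrank_test
#' @return a [test_result()] with `effect` = HR; `estimable = FALSE` and
#'   `effect = NA` when a group has zero events.
#' @export
hazard_ratio <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop_pericor("hazard ratio needs exactly two non-empty groups",
                 class = "pericor_validation_error")
  if (sum(event) == 0)
    stop_pericor("no events in the data", class = "pericor_validation_error")
  ev_by_g <- tapply(event, group, sum)
  if (any(ev_by_g == 0))
    return(test_result(NA_real_, NA_real_, NA_real_, n = length(time),
                       method = "hazard ratio (non-estimable)",
                       estimable = FALSE))
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  # monotone likelihood (complete separation of event orderings): the
  # estimate diverges; report non-estimable instead of a huge number
  if (!is.finite(beta) || abs(beta) > 15)
    return(test_result(NA_real_, NA_real_, NA_real_, n = length(time),
                       method = "hazard ratio (non-estimable)",
                       estimable = FALSE))
  z <- beta / se
  test_result(statistic = z,
              p_value = 2 * pnorm(-abs(z)),
              effect = exp(beta),
              ci_low = exp(beta - 1.96 * se),
              ci_high = exp(beta + 1.96 * se),
              n = length(time), method = "hazard ratio (Breslow)")
}

#' Split a cohort at the covariate mean
#'
#' Group `"high"` holds values strictly above the cohort mean, `"low"`
#' holds values at or below it (values exactly at the mean go low,
#' deterministically).
#'
#' @param values numeric covariate, n >= 2, non-constant.
#' @return factor with levels `low`, `high`.
#' @export
dichotomize_at_mean <- function(values) {
  if (length(values) < 2L || sd(values) == 0)
    stop_pericor("cannot dichotomize a constant covariate",
                 class = "pericor_validation_error")
  factor(ifelse(values > mean(values), "high", "low"),
         levels = c("low", "high"))
}
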