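#' Feature matrix for batch harmonization
#'
#' @param values numeric matrix, rows = samples (images or image pairs),
#'   columns = features (histogram bins or biomarker values).
#' @param batch per-row batch label (contrast-enhancement batch).
#' @param feature_ids optional column names.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, batch, feature_ids = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop_pericor("feature matrix contains missing or non-finite values",
                 class = "pericor_validation_error")
  if (ncol(values) < 1L)
    stop_pericor("feature matrix needs at least one feature",
                 class = "pericor_validation_error")
  batch <- as.character(batch)
  if (length(batch) != nrow(values))
    stop_pericor("one batch label per sample row is required",
                 class = "pericor_validation_error")
  if (!is.null(feature_ids)) colnames(values) <- feature_ids
  structure(list(values = values, batch = batch,
                 feature_ids = colnames(values)),
            class = "feature_matrix")
}

#' Contrast-enhancement batch labels for a cohort
#'
#' Two schemes: `two_batch` labels each image by its own contrast flag
#' (`CE` / `nonCE`), for analyses of baseline images alone; `four_batch`
#' labels each baseline/follow-up *pair* by the flag combination, for
#' longitudinal biomarkers:
#' Batch1 = both non-enhanced, Batch2 = both enhanced,
#' Batch3 = baseline enhanced only, Batch4 = follow-up enhanced only.
#'
#' @param studies list of [patient_study()] objects.
#' @param mode `"two_batch"` or `"four_batch"`.
#' @param followup_index index of the selected follow-up candidate per
#'   study (recycled).
#' @return character vector of batch labels, one per study.
#' @export
assign_batches <- function(studies, mode = c("two_batch", "four_batch"),
                           followup_index = 1L) {
  mode <- match.arg(mode)
  followup_index <- rep_len(as.integer(followup_index), length(studies))
  vapply(seq_along(studies), function(i) {
    s <- studies[[i]]
    bce <- s$baseline$contrast_enhanced
    if (is.na(bce))
      stop_pericor("missing contrast flag on baseline of ", s$patient_id,
                   class = "pericor_validation_error")
    if (mode == "two_batch") return(if (bce) "CE" else "nonCE")
    fu <- s$followup_candidates[[followup_index[i]]]
    fce <- fu$contrast_enhanced
    if (is.na(fce))
      stop_pericor("missing contrast flag on follow-up of ", s$patient_id,
                   class = "pericor_validation_error")
    if (!bce && !fce) "Batch1"
    else if (bce && fce) "Batch2"
    else if (bce && !fce) "Batch3"
    else "Batch4"
  }, character(1))
}

#' Location/scale batch-effect harmonization (ComBat)
#'
#' Removes per-batch additive and multiplicative effects from a feature
#' matrix. Each feature is standardized to its pooled mean and variance;
#' per-batch location (gamma) and scale (delta^2) effects are estimated
#' and, with `empirical_bayes = TRUE`, shrunk across features toward a
#' per-batch normal prior (location) and inverse-gamma prior (scale) with
#' method-of-moments hyperparameters, solved by the standard iterative
#' conditional update; the batch effects are then subtracted/rescaled and
#' the pooled location/scale restored. With `empirical_bayes = FALSE` the
#' raw batch estimates are used, which removes planted location offsets
#' exactly and makes the transform idempotent.
#'
#' Features with pooled variance below `var_tol` (e.g. structurally empty
#' histogram bins) are passed through untouched. A single batch is an
#' identity transform. The per-feature grand mean of the output is
#' re-anchored to the input grand mean.
#'
#' @param m a [feature_matrix()].
#' @param empirical_bayes shrink batch effects across features (default
#'   `TRUE`; the standard choice when features are many and batches
#'   small).
#' @param var_tol pooled-variance floor below which a feature bypasses
#'   harmonization.
#' @param conv_tol,max_iter convergence control for the EB iterative
#'   update.
#' @return a `feature_matrix` of the same shape, with attribute
#'   `"estimates"` carrying the per-batch raw and shrunk effects.
#' @export
combat_fit_transform <- function(m, empirical_bayes = TRUE,
                                 var_tol = 1e-12, conv_tol = 1e-6,
                                 max_iter = 500L) {
  stopifnot(inherits(m, "feature_matrix"))
  x <- m$values
  batch <- m$batch
  batches <- unique(batch)
  if (length(batches) < 2L) return(m)  # nothing to harmonize
  nb <- table(batch)
  if (any(nb < 2L))
    stop_pericor("batch(es) with fewer than 2 samples: ",
                 paste(names(nb)[nb < 2L], collapse = ", "),
                 class = "pericor_validation_error")
  n <- nrow(x)
  p <- ncol(x)

  batch_idx <- lapply(batches, function(b) which(batch == b))
  names(batch_idx) <- batches
  n_b <- vapply(batch_idx, length, integer(1))

  # per-feature batch means and the design-adjusted grand mean/variance
  bmeans <- t(vapply(batch_idx, function(ii)
    colMeans(x[ii, , drop = FALSE]), numeric(p)))
  if (p == 1L) bmeans <- matrix(bmeans, ncol = 1L)
  alpha <- as.numeric(crossprod(n_b / n, bmeans))          # grand mean
  fit <- bmeans[match(batch, batches), , drop = FALSE]
  var_pooled <- colSums((x - fit)^2) / n                   # residual var

  active <- var_pooled > var_tol
  out <- x
  est <- NULL
  if (any(active)) {
    xa <- x[, active, drop = FALSE]
    al <- alpha[active]
    vp <- var_pooled[active]
    z <- sweep(sweep(xa, 2, al, "-"), 2, sqrt(vp), "/")

    gamma_hat <- t(vapply(batch_idx, function(ii)
      colMeans(z[ii, , drop = FALSE]), numeric(sum(active))))
    # per-batch scale by maximum likelihood (denominator n_b), consistent
    # with the pooled variance: this makes the non-EB transform exactly
    # idempotent
    delta2_hat <- t(vapply(batch_idx, function(ii) {
      zb <- z[ii, , drop = FALSE]
      colSums(sweep(zb, 2, colMeans(zb), "-")^2) / length(ii)
    }, numeric(sum(active))))
    if (sum(active) == 1L) {
      gamma_hat <- matrix(gamma_hat, ncol = 1L)
      delta2_hat <- matrix(delta2_hat, ncol = 1L)
    }

    if (empirical_bayes && sum(active) >= 2L) {
      eb <- eb_shrink(z, batch_idx, gamma_hat, delta2_hat,
                      conv_tol, max_iter)
      gamma_star <- eb$gamma_star
      delta2_star <- eb$delta2_star
      priors <- eb$priors
    } else {
      gamma_star <- gamma_hat
      delta2_star <- delta2_hat
      priors <- NULL
    }

    zadj <- z
    for (bi in seq_along(batches)) {
      ii <- batch_idx[[bi]]
      zadj[ii, ] <- sweep(sweep(z[ii, , drop = FALSE], 2,
                                gamma_star[bi, ], "-"),
                          2, sqrt(delta2_star[bi, ]), "/")
    }
    xadj <- sweep(sweep(zadj, 2, sqrt(vp), "*"), 2, al, "+")
    # re-anchor per-feature grand mean to the input's
    xadj <- sweep(xadj, 2, colMeans(xa) - colMeans(xadj), "+")
    out[, active] <- xadj
    est <- list(batches = batches, gamma_hat = gamma_hat,
                delta2_hat = delta2_hat, gamma_star = gamma_star,
                delta2_star = delta2_star, priors = priors,
                active = active)
  }
  res <- feature_matrix(out, batch, m$feature_ids)
  attr(res, "estimates") <- est
  res
}

# parametric empirical-Bayes shrinkage of batch location/scale effects:
# normal prior on gamma, inverse-gamma prior on delta^2, hyperparameters
# by method of moments, iterated conditional posterior means
eb_shrink <- function(z, batch_idx, gamma_hat, delta2_hat,
                      conv_tol, max_iter) {
  nb <- length(batch_idx)
  p <- ncol(gamma_hat)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  priors <- vector("list", nb)
  for (bi in seq_len(nb)) {
    ii <- batch_idx[[bi]]
    nbi <- length(ii)
    g_bar <- mean(gamma_hat[bi, ])
    t2 <- var(gamma_hat[bi, ])
    m_d <- mean(delta2_hat[bi, ])
    s2_d <- var(delta2_hat[bi, ])
    # inverse-gamma moments: a from mean/var, b from mean
    a_prior <- (2 * s2_d + m_d^2) / s2_d
    b_prior <- (m_d * s2_d + m_d^3) / s2_d
    g_new <- gamma_hat[bi, ]
    d_new <- delta2_hat[bi, ]
    zb <- z[ii, , drop = FALSE]
    if (!is.finite(t2) || t2 <= 0 || !is.finite(s2_d) || s2_d <= 0) {
      # degenerate prior (e.g. single active feature): no shrinkage
      gamma_star[bi, ] <- gamma_hat[bi, ]
      delta2_star[bi, ] <- delta2_hat[bi, ]
      priors[[bi]] <- list(gamma_bar = g_bar, tau2 = t2,
                           a = NA_real_, b = NA_real_, iterations = 0L)
      next
    }
    it <- 0L
    repeat {
      it <- it + 1L
      g_old <- g_new
      d_old <- d_new
      g_new <- (t2 * nbi * gamma_hat[bi, ] + d_new * g_bar) /
        (t2 * nbi + d_new)
      sum2 <- colSums(sweep(zb, 2, g_new, "-")^2)
      d_new <- (0.5 * sum2 + b_prior) / (nbi / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      if (change < conv_tol || it >= max_iter) break
    }
    gamma_star[bi, ] <- g_new
    delta2_star[bi, ] <- d_new
    priors[[bi]] <- list(gamma_bar = g_bar, tau2 = t2,
                         a = a_prior, b = b_prior, iterations = it)
  }
  list(gamma_star = gamma_star, delta2_star = delta2_star, priors = priors)
}
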