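.match_followup_to_baseline <- function(coh) {
  idx <- match(coh$followup_items$item_id, coh$baseline_items$item_id)
  if (anyNA(idx))
    stop("follow-up item(s) without a matching baseline item: ",
         paste(coh$followup_items$item_id[is.na(idx)], collapse = ", "))
  idx
}

#' Clinical-stability baseline prediction
#'
#' The benchmark predictor that assumes no change: predicted follow-up
#' severity equals observed baseline severity on matched items, in z units
#' so it is comparable with the diffusion pipeline. Its mean squared error
#' is exactly the mean squared change in symptom severity across time
#' points.
#'
#' @param x a `tmsn_cohort`; standardized in place (cohort statistics) when
#'   it is not already.
#' @return n x q matrix of predicted follow-up z-scores.
#' @export
stability_baseline <- function(x) {
  stopifnot(inherits(x, "tmsn_cohort"))
  if (!"standardized" %in% x$preprocessing) x <- standardize_items(x)
  idx <- .match_followup_to_baseline(x)
  pred <- x$baseline[, idx, drop = FALSE]
  colnames(pred) <- x$followup_items$item_id
  pred
}

#' Pooled regression-to-the-mean correlation
#'
#' Correlation, pooled over all subjects and matched items, between
#' baseline severity and baseline-to-follow-up change (both in per-item
#' z units). Under a stationary cross-lagged process with autocorrelation
#' rho this equals -sqrt((1 - rho)/2): imperfect autocorrelation alone
#' produces a strong negative association.
#'
#' @param x a `tmsn_cohort`.
#' @return list with `r`, `p` and `n_obs`.
#' @export
regression_to_mean <- function(x) {
  stopifnot(inherits(x, "tmsn_cohort"))
  if (!"standardized" %in% x$preprocessing) x <- standardize_items(x)
  idx <- .match_followup_to_baseline(x)
  zb <- as.numeric(x$baseline[, idx, drop = FALSE])
  ch <- as.numeric(x$followup) - zb
  ct <- cor.test(zb, ch)
  list(r = unname(ct$estimate), p = ct$p.value, n_obs = length(zb))
}

#' Subset a cohort's layers by instrument
#'
#' Used for instrument augmentation: extra instruments (e.g. BPRS, CBCL)
#' enter the baseline layer only while the follow-up layer keeps just the
#' target instrument's items.
#'
#' @param x a `tmsn_cohort`.
#' @param baseline_instruments,followup_instruments instrument names to
#'   keep (`NULL` keeps all).
#' @return the subset cohort.
#' @export
subset_instruments <- function(x, baseline_instruments = NULL,
                               followup_instruments = NULL) {
  stopifnot(inherits(x, "tmsn_cohort"))
  for (wave in c("baseline", "followup")) {
    keep_ins <- if (wave == "baseline") baseline_instruments else
      followup_instruments
    if (is.null(keep_ins)) next
    pan <- x[[paste0(wave, "_items")]]
    keep <- pan$instrument %in% keep_ins
    if (!any(keep)) stop("no ", wave, " item from instrument(s): ",
                         paste(keep_ins, collapse = ", "))
    x[[wave]] <- x[[wave]][, keep, drop = FALSE]
    x[[paste0(wave, "_items")]] <- pan[keep, , drop = FALSE]
  }
  validate_cohort(x)
}

#' Leave-one-out graph-diffusion prediction of follow-up severity
#'
#' For every subject s, the entire pipeline is re-fit on the remaining
#' n - 1 subjects: age/sex residualization, per-item z-scoring,
#' correlations, BY-FDR thresholding, positive-edge network, Laplacian.
#' Subject s's residualized, training-standardized baseline severities are
#' then clamped on the baseline-layer nodes, the follow-up-layer nodes
#' start at 0, and the signal diffuses to its steady state; the follow-up
#' node values are the prediction. The default solver computes the exact
#' clamped-diffusion equilibrium by the harmonic linear solve; `solver =
#' "iterative"` runs the explicit finite-difference iteration to the 1e-9
#' convergence threshold (same steady state, slower). `target_instrument`
#' restricts the follow-up layer (and, together with `augment`, the
#' baseline layer) for instrument-augmentation experiments.
#'
#' Training-fold constant items are excluded from that fold's network and
#' predicted 0 (flagged); free follow-up components disconnected from the
#' baseline layer also get 0 (the training-mean prediction in z units).
#'
#' @param x a raw `tmsn_cohort` (n >= 10).
#' @param alpha,method,sign_mode edge selection, as in [tmsn()];
#'   `sign_mode` defaults to `"positive_only"` for diffusion.
#' @param target_instrument instrument whose follow-up items are predicted
#'   (`NULL`: all items).
#' @param augment extra baseline-layer instruments.
#' @param solver `"harmonic"` (exact equilibrium, default) or
#'   `"iterative"`.
#' @param config a [diffusion_config()] (used by the iterative solver; its
#'   `laplacian_kind` applies to both solvers).
#' @param residualize regress age and sex out of every item, with
#'   coefficients fit on the training fold and applied to the held-out
#'   subject.
#' @return an object of class `tmsn_prediction` with n x q matrices
#'   `predicted_z`, `observed_z`, `stability_z`, `predicted_raw`,
#'   per-subject `iterations` / `converged`, per-fold surviving-edge counts
#'   and exclusion flags.
#' @export
loocv_predict <- function(x, alpha = 0.05,
                          method = c("pearson", "spearman"),
                          sign_mode = c("positive_only", "signed"),
                          target_instrument = NULL, augment = NULL,
                          solver = c("harmonic", "iterative"),
                          config = diffusion_config(), residualize = TRUE) {
  stopifnot(inherits(x, "tmsn_cohort"))
  method <- match.arg(method)
  sign_mode <- match.arg(sign_mode)
  solver <- match.arg(solver)
  if (!is.null(target_instrument))
    x <- subset_instruments(x,
                            baseline_instruments = c(target_instrument,
                                                     augment),
                            followup_instruments = target_instrument)
  n <- length(x$subject_id)
  if (n < 10) stop("leave-one-out prediction needs at least 10 subjects")
  bl <- x$baseline
  fu <- x$followup
  p <- ncol(bl); q <- ncol(fu)
  stab_idx <- .match_followup_to_baseline(x)
  cov <- x$covariates
  Xb <- cbind(intercept = 1, age = cov$age_baseline, sex = cov$sex)
  Xf <- cbind(intercept = 1, age = cov$age_followup, sex = cov$sex)
  predicted_z <- observed_z <- stability_z <- predicted_raw <-
    matrix(NA_real_, n, q, dimnames = list(x$subject_id,
                                           x$followup_items$item_id))
  iterations <- integer(n)
  converged <- logical(n)
  fold_edges <- integer(n)
  flags <- vector("list", n)
  for (s in seq_len(n)) {
    tr <- setdiff(seq_len(n), s)
    if (residualize) {
      keep_reg <- c(TRUE, apply(Xb[tr, -1, drop = FALSE], 2,
                                function(v) sd(v) > 0))
      Bb <- solve(crossprod(Xb[tr, keep_reg, drop = FALSE]),
                  crossprod(Xb[tr, keep_reg, drop = FALSE], bl[tr, ]))
      Bf <- solve(crossprod(Xf[tr, keep_reg, drop = FALSE]),
                  crossprod(Xf[tr, keep_reg, drop = FALSE], fu[tr, ]))
      rb <- bl - Xb[, keep_reg, drop = FALSE] %*% Bb
      rf <- fu - Xf[, keep_reg, drop = FALSE] %*% Bf
      covfit_f <- (Xf[, keep_reg, drop = FALSE] %*% Bf)[s, ]
    } else {
      rb <- bl; rf <- fu
      covfit_f <- rep(0, q)
    }
    mb <- colMeans(rb[tr, , drop = FALSE])
    mf <- colMeans(rf[tr, , drop = FALSE])
    sb <- apply(rb[tr, , drop = FALSE], 2, sd)
    sf <- apply(rf[tr, , drop = FALSE], 2, sd)
    # numerically constant training items (e.g. exactly fitted by the
    # covariate model) are excluded from the fold's network
    excl_b <- sb < 1e-10; excl_f <- sf < 1e-10
    if (any(excl_b) || any(excl_f))
      flags[[s]] <- c(colnames(bl)[excl_b], colnames(fu)[excl_f])
    sb[excl_b] <- 1; sf[excl_f] <- 1
    zb <- sweep(sweep(rb, 2, mb), 2, sb, "/")
    zf <- sweep(sweep(rf, 2, mf), 2, sf, "/")
    kb <- which(!excl_b); kf <- which(!excl_f)
    if (length(kb) == 0 || length(kf) == 0) {
      # a degenerate fold (a whole layer constant) predicts the training
      # mean, i.e. 0 in z units, for every target item
      predicted_z[s, ] <- 0
      observed_z[s, ] <- zf[s, ]
      stability_z[s, ] <- zb[s, stab_idx]
      predicted_raw[s, ] <- mf + covfit_f
      converged[s] <- TRUE
      next
    }
    cs <- suppressWarnings(
      pairwise_correlations(zb[tr, kb, drop = FALSE],
                            zf[tr, kf, drop = FALSE], method = method))
    net <- suppressWarnings(assemble_tmsn(cs, alpha = alpha,
                                          sign_mode = sign_mode))
    fold_edges[s] <- sum(net$W[upper.tri(net$W)] != 0)
    L <- build_laplacian(net, kind = config$laplacian_kind)
    clamped <- net$nodes$layer == "baseline"
    x0 <- c(zb[s, kb], rep(0, length(kf)))
    if (solver == "harmonic") {
      xs <- harmonic_steady_state(L, x0, clamped, lenient = TRUE)
      iterations[s] <- NA_integer_
      converged[s] <- TRUE
      pred <- xs[!clamped]
    } else {
      sig <- clamped_diffusion(L, x0, clamped, config)
      iterations[s] <- sig$iterations
      converged[s] <- sig$converged
      pred <- sig$x[!clamped]
    }
    pz <- rep(0, q)               # excluded items predicted 0 in z units
    pz[kf] <- pred
    predicted_z[s, ] <- pz
    observed_z[s, ] <- zf[s, ]
    stability_z[s, ] <- zb[s, stab_idx]
    predicted_raw[s, ] <- pz * sf + mf + covfit_f
  }
  structure(list(predicted_z = predicted_z, observed_z = observed_z,
                 stability_z = stability_z, predicted_raw = predicted_raw,
                 observed_raw = fu, iterations = iterations,
                 converged = converged, fold_edges = fold_edges,
                 flags = flags, solver = solver, alpha = alpha,
                 method = method, sign_mode = sign_mode,
                 subjects = x$subject_id,
                 items = x$followup_items$item_id),
            class = "tmsn_prediction")
}

#' @export
print.tmsn_prediction <- function(x, ...) {
  cat(sprintf("Leave-one-out diffusion prediction: %d subjects x %d follow-up items\n",
              nrow(x$predicted_z), ncol(x$predicted_z)))
  cat(sprintf("  solver: %s; surviving edges per fold: median %d\n",
              x$solver, as.integer(stats::median(x$fold_edges))))
  if (!all(x$converged)) cat("  WARNING:", sum(!x$converged),
                             "subject(s) did not converge\n")
  invisible(x)
}

#' Compare two per-observation squared-error vectors
#'
#' Paired two-sided test (paired t by default, Wilcoxon signed-rank by
#' flag) on the squared errors of two predictors over the same
#' observations, reporting each predictor's MSE as mean +/- sd of its
#' squared errors.
#'
#' @param errors_a,errors_b equal-length squared-error vectors.
#' @param test `"paired_t"` or `"wilcoxon"`.
#' @return list with `p`, `direction` (`"a"`, `"b"` or `"tie"`: which has
#'   the smaller mean), `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
compare_mse <- function(errors_a, errors_b,
                        test = c("paired_t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(errors_a) != length(errors_b))
    stop("error vectors must have equal length")
  d <- errors_a - errors_b
  if (all(d == 0)) {
    p <- 1
  } else if (sd(d) == 0) {
    warning("constant nonzero error difference; p-value degenerate")
    p <- NA_real_
  } else {
    p <- if (test == "paired_t")
      t.test(errors_a, errors_b, paired = TRUE)$p.value
    else
      wilcox.test(errors_a, errors_b, paired = TRUE, exact = FALSE)$p.value
  }
  ma <- mean(errors_a); mb <- mean(errors_b)
  list(p = p,
       direction = if (ma < mb) "a" else if (mb < ma) "b" else "tie",
       mean_a = ma, sd_a = sd(errors_a), mean_b = mb, sd_b = sd(errors_b),
       test = test)
}

#' Evaluate diffusion predictions against the stability baseline
#'
#' Computes, over the identical set of n x q held-out observations (all in
#' fold-wise z units): mean squared error of the diffusion prediction and
#' of the clinical-stability baseline with a paired comparison test; the
#' pooled correlation between real and predicted severity; the pooled
#' correlation between real and predicted change (follow-up minus
#' baseline); and the per-subject correlations of mean severity and mean
#' change. A zero-variance vector makes the corresponding correlation
#' undefined (NA, flagged).
#'
#' @param pred a `tmsn_prediction`.
#' @param test see [compare_mse()].
#' @return an object of class `tmsn_evaluation`.
#' @export
evaluate_predictions <- function(pred, test = c("paired_t", "wilcoxon")) {
  stopifnot(inherits(pred, "tmsn_prediction"))
  test <- match.arg(test)
  obs <- as.numeric(pred$observed_z)
  est <- as.numeric(pred$predicted_z)
  stab <- as.numeric(pred$stability_z)
  err_diffusion <- (est - obs)^2
  err_stability <- (stab - obs)^2
  safe_cor <- function(a, b) {
    if (length(a) < 3 || sd(a) == 0 || sd(b) == 0)
      return(list(r = NA_real_, p = NA_real_, flagged = TRUE))
    ct <- cor.test(a, b)
    list(r = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
  }
  cmp <- compare_mse(err_stability, err_diffusion, test = test)
  out <- list(
    mse_stability = mean(err_stability), sd_stability = sd(err_stability),
    mse_diffusion = mean(err_diffusion), sd_diffusion = sd(err_diffusion),
    comparison = cmp,
    r_severity_pooled = safe_cor(obs, est),
    r_change_pooled = safe_cor(obs - stab, est - stab),
    r_mean_severity_subjects = safe_cor(rowMeans(pred$observed_z),
                                        rowMeans(pred$predicted_z)),
    r_mean_change_subjects = safe_cor(
      rowMeans(pred$observed_z - pred$stability_z),
      rowMeans(pred$predicted_z - pred$stability_z)),
    errors = list(diffusion = err_diffusion, stability = err_stability),
    n_obs = length(obs), n_subjects = nrow(pred$observed_z))
  class(out) <- "tmsn_evaluation"
  out
}

.fmt_p <- function(p) {
  if (is.na(p)) "NA" else if (p < 1e-5) "p<0.00001" else
    sprintf("p=%.4g", p)
}

#' @export
print.tmsn_evaluation <- function(x, ...) {
  cat("Prediction evaluation (z units, pooled over",
      x$n_obs, "observations)\n")
  cat(sprintf("  MSE of clinical stability=%.3g%s%.2g, MSE of graph diffusion=%.3g%s%.2g, %s\n",
              x$mse_stability, "±", x$sd_stability,
              x$mse_diffusion, "±", x$sd_diffusion,
              .fmt_p(x$comparison$p)))
  cat(sprintf("  real vs predicted severity:  R=%.3g, %s\n",
              x$r_severity_pooled$r, .fmt_p(x$r_severity_pooled$p)))
  cat(sprintf("  real vs predicted change:    R=%.3g, %s\n",
              x$r_change_pooled$r, .fmt_p(x$r_change_pooled$p)))
  cat(sprintf("  per-subject mean severity:   R=%.3g, %s\n",
              x$r_mean_severity_subjects$r,
              .fmt_p(x$r_mean_severity_subjects$p)))
  cat(sprintf("  per-subject mean change:     R=%.3g, %s\n",
              x$r_mean_change_subjects$r,
              .fmt_p(x$r_mean_change_subjects$p)))
  invisible(x)
}
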