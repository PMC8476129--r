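#' Cross-sectional and longitudinal pairwise correlations
#'
#' Computes the full 2p x 2p correlation structure underlying a temporal
#' multilayer symptom network: within-baseline and within-follow-up
#' (cross-sectional) blocks and the baseline x follow-up (longitudinal)
#' block, in a single matrix, together with two-sided p-values from the
#' t transform with n - 2 degrees of freedom. Spearman mode rank-transforms
#' the scores and applies the same estimator. Constant columns yield r = 0
#' and p = 1 for their pairs, with a warning, so degenerate inputs still run.
#'
#' @param baseline a `tmsn_cohort` or an n x p numeric matrix.
#' @param followup n x q matrix (ignored when `baseline` is a cohort).
#' @param method `"pearson"` or `"spearman"`.
#' @return an object of class `tmsn_correlations`: list with `r`, `pval`
#'   (2p x 2p symmetric matrices), `method`, `n`, and a `nodes` data frame
#'   (node id, item id, instrument, layer).
#' @export
pairwise_correlations <- function(baseline, followup = NULL,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(baseline, "tmsn_cohort")) {
    coh <- baseline
    baseline <- coh$baseline
    followup <- coh$followup
    nodes <- rbind(
      data.frame(item_id = coh$baseline_items$item_id,
                 instrument = coh$baseline_items$instrument,
                 layer = "baseline", stringsAsFactors = FALSE),
      data.frame(item_id = coh$followup_items$item_id,
                 instrument = coh$followup_items$instrument,
                 layer = "followup", stringsAsFactors = FALSE))
  } else {
    followup <- as.matrix(followup)
    baseline <- as.matrix(baseline)
    nodes <- data.frame(
      item_id = c(colnames(baseline) %||% paste0("b", seq_len(ncol(baseline))),
                  colnames(followup) %||% paste0("f", seq_len(ncol(followup)))),
      instrument = "GEN",
      layer = rep(c("baseline", "followup"),
                  c(ncol(baseline), ncol(followup))),
      stringsAsFactors = FALSE)
  }
  if (nrow(baseline) != nrow(followup))
    stop("baseline and followup must cover the same subjects")
  n <- nrow(baseline)
  if (n < 4) stop("at least 4 subjects are needed for edge p-values")
  nodes$node <- paste0(nodes$item_id,
                       ifelse(nodes$layer == "baseline", "@bl", "@fu"))
  X <- cbind(baseline, followup)
  if (method == "spearman") X <- apply(X, 2, rank)
  const <- apply(X, 2, sd) == 0
  if (any(const)) {
    warning("constant column(s): ",
            paste(nodes$node[const], collapse = ", "),
            " -- their correlations are set to 0 with p = 1")
  }
  suppressWarnings(r <- cor(X))
  r[!is.finite(r)] <- 0
  pval <- matrix(.cor_pval(r, n), nrow(r), ncol(r))
  diag(r) <- 1
  diag(pval) <- 0
  if (any(const)) {
    r[const, ] <- 0; r[, const] <- 0
    pval[const, ] <- 1; pval[, const] <- 1
    diag(r)[const] <- 1
  }
  dimnames(r) <- dimnames(pval) <- list(nodes$node, nodes$node)
  structure(list(r = r, pval = pval, method = method, n = n,
                 nodes = nodes[c("node", "item_id", "instrument", "layer")]),
            class = "tmsn_correlations")
}

#' @export
print.tmsn_correlations <- function(x, ...) {
  cat(sprintf("Pairwise %s correlations: %d nodes, n = %d subjects\n",
              x$method, nrow(x$r), x$n))
  invisible(x)
}

#' Benjamini-Yekutieli FDR rejection mask
#'
#' Applies the Benjamini-Yekutieli step-up procedure (valid under arbitrary
#' dependence, with harmonic correction c(m) = sum(1/i)): the k smallest
#' p-values are rejected for the largest k with p_(k) <= k * alpha / (m c(m)).
#' For a symmetric p-value matrix the family is the set of unique
#' upper-triangular pairs and the returned mask is symmetric with a `FALSE`
#' diagonal.
#'
#' @param pvals numeric vector, or symmetric matrix of pairwise p-values.
#' @param alpha FDR level in (0, 1).
#' @return logical rejection mask with the shape of `pvals`.
#' @export
fdr_threshold_by <- function(pvals, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)")
  if (is.matrix(pvals)) {
    .assert_symmetric(pvals, "p-value matrix")
    ut <- upper.tri(pvals)
    rej <- fdr_threshold_by(pvals[ut], alpha)
    mask <- matrix(FALSE, nrow(pvals), ncol(pvals), dimnames = dimnames(pvals))
    mask[ut] <- rej
    return(mask | t(mask))
  }
  if (length(pvals) < 1) stop("need at least one p-value")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BY") <= alpha
}
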