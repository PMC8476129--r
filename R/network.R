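# internal constructor shared by assemble_tmsn() and planted_block_network()
.new_tmsn <- function(W, nodes, mask, r = W, pval = NULL, qval = NULL,
                      alpha = NA_real_, method = "pearson", n = NA_integer_,
                      sign_mode = "signed") {
  blocks <- list(baseline = which(nodes$layer == "baseline"),
                 followup = which(nodes$layer == "followup"))
  structure(list(W = W, nodes = nodes, mask = mask, r = r, pval = pval,
                 qval = qval, alpha = alpha, method = method, n = n,
                 sign_mode = sign_mode, blocks = blocks),
            class = "tmsn")
}

#' Fit a temporal multilayer symptom network
#'
#' The central model-fitting step: from a two-wave cohort, estimate all
#' cross-sectional and longitudinal pairwise correlations (after optional
#' age/sex residualization and per-item z-scoring), correct the whole
#' multilayer family of unique pairs with the Benjamini-Yekutieli procedure
#' at level `alpha`, and keep only the surviving correlations as edge
#' weights of a single 2p x 2p symmetric adjacency matrix. The diagonal
#' blocks are the two cross-sectional layers; the off-diagonal block holds
#' the longitudinal edges.
#'
#' @param x a `tmsn_cohort`.
#' @param alpha FDR level for edge selection (default 0.05).
#' @param method correlation estimator, `"pearson"` (default) or
#'   `"spearman"` (confirmatory).
#' @param sign_mode `"signed"` keeps positive and negative surviving edges;
#'   `"positive_only"` (display and diffusion convention) zeroes surviving
#'   negative edges; `"negative_only"` the converse.
#' @param residualize regress age (wave-specific) and sex out of every item
#'   first.
#' @param standardize z-score items before correlating (leaves Pearson
#'   edges unchanged; matters only for downstream signal units).
#' @return an object of class `tmsn`; see [assemble_tmsn()] for its fields.
#' @seealso [assemble_tmsn()], [tmsn_embedding()], [centrality_null_test()],
#'   [loocv_predict()]
#' @examples
#' sim <- sample_cohort(generative_spec(n_subjects = 120, p_items = 10,
#'                                      seed = 7))
#' net <- tmsn(sim$cohort)
#' summary(net)
#' @export
tmsn <- function(x, alpha = 0.05, method = c("pearson", "spearman"),
                 sign_mode = c("signed", "positive_only", "negative_only"),
                 residualize = TRUE, standardize = TRUE) {
  stopifnot(inherits(x, "tmsn_cohort"))
  method <- match.arg(method)
  sign_mode <- match.arg(sign_mode)
  if (residualize && !"residualized" %in% x$preprocessing)
    x <- residualize_covariates(x)
  if (standardize && !"standardized" %in% x$preprocessing)
    x <- standardize_items(x)
  cs <- pairwise_correlations(x, method = method)
  net <- assemble_tmsn(cs, alpha = alpha, sign_mode = sign_mode)
  attr(net, "call") <- match.call()
  net
}

#' Threshold a correlation set into a multilayer adjacency
#'
#' Applies the Benjamini-Yekutieli rejection mask to the full correlation
#' matrix and returns the thresholded, signed, zero-diagonal adjacency of
#' the temporal multilayer symptom network. Sub-threshold correlations get
#' weight zero (mask-based thresholding, no shrinkage).
#'
#' @param cs a `tmsn_correlations` object from [pairwise_correlations()].
#' @param alpha FDR level in (0, 1).
#' @param sign_mode see [tmsn()].
#' @return an object of class `tmsn`: list with `W` (weights), `nodes`,
#'   `mask` (FDR survival), `r`, `pval`, `qval` (BY-adjusted p), `alpha`,
#'   `method`, `n`, `sign_mode` and `blocks` (per-layer node indices).
#' @export
assemble_tmsn <- function(cs, alpha = 0.05,
                          sign_mode = c("signed", "positive_only",
                                        "negative_only")) {
  stopifnot(inherits(cs, "tmsn_correlations"))
  sign_mode <- match.arg(sign_mode)
  mask <- fdr_threshold_by(cs$pval, alpha)
  qval <- cs$pval
  ut <- upper.tri(qval)
  qval[ut] <- p.adjust(cs$pval[ut], method = "BY")
  qval[lower.tri(qval)] <- t(qval)[lower.tri(qval)]
  W <- cs$r * mask
  diag(W) <- 0
  if (sign_mode == "positive_only") W[W < 0] <- 0
  if (sign_mode == "negative_only") W[W > 0] <- 0
  if (!any(W != 0)) warning("no edge survived FDR thresholding")
  .new_tmsn(W, cs$nodes, mask, r = cs$r, pval = cs$pval, qval = qval,
            alpha = alpha, method = cs$method, n = cs$n,
            sign_mode = sign_mode)
}

.quadrant <- function(net) {
  lay <- net$nodes$layer
  outer(lay, lay, function(a, b)
    ifelse(a == "baseline" & b == "baseline", "baseline",
           ifelse(a == "followup" & b == "followup", "followup",
                  "longitudinal")))
}

#' Node strength
#'
#' Sum of absolute thresholded edge weights incident to each node, across
#' all quadrants -- the overall cross-sectional plus longitudinal
#' connectivity used to scale nodes in network displays.
#'
#' @param net a `tmsn`.
#' @param nodes node ids (default: all nodes).
#' @return named numeric vector of strengths.
#' @export
node_strength <- function(net, nodes = NULL) {
  stopifnot(inherits(net, "tmsn"))
  s <- rowSums(abs(net$W))
  names(s) <- net$nodes$node
  if (is.null(nodes)) return(s)
  bad <- setdiff(nodes, names(s))
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  s[nodes]
}

#' @export
print.tmsn <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] != 0)
  cat(sprintf("Temporal multilayer symptom network (%d nodes, %d edges)\n",
              nrow(x$W), ne))
  cat(sprintf("  layers: %d baseline + %d follow-up items\n",
              length(x$blocks$baseline), length(x$blocks$followup)))
  cat(sprintf("  edges: %s correlations, BY-FDR alpha = %s, sign mode: %s\n",
              x$method, format(x$alpha), x$sign_mode))
  invisible(x)
}

#' @export
summary.tmsn <- function(object, ...) {
  ut <- upper.tri(object$W)
  quad <- .quadrant(object)
  surv <- object$W != 0
  tab <- t(vapply(c("baseline", "followup", "longitudinal"), function(qd) {
    sel <- ut & quad == qd
    c(tested = sum(sel), surviving = sum(surv[sel]),
      positive = sum(object$W[sel] > 0))
  }, numeric(3)))
  neg <- sum(object$mask[ut] & object$r[ut] < 0)
  out <- list(nodes = nrow(object$W), quadrants = tab,
              n_negative_surviving = neg, alpha = object$alpha,
              method = object$method, n = object$n,
              sign_mode = object$sign_mode,
              mean_strength = mean(node_strength(object)))
  class(out) <- "summary.tmsn"
  out
}

#' @export
print.summary.tmsn <- function(x, ...) {
  cat(sprintf("TMSN summary: %d nodes, %s edges at BY alpha = %s (n = %d)\n",
              x$nodes, x$method, format(x$alpha), x$n))
  print(x$quadrants)
  cat(sprintf("negative surviving correlations: %d\n",
              x$n_negative_surviving))
  cat(sprintf("mean node strength: %.3f\n", x$mean_strength))
  invisible(x)
}

#' Export the surviving edges as a long table
#'
#' @param net a `tmsn`.
#' @return data frame with one row per surviving edge: node ids, layers,
#'   thresholded weight, raw correlation, p and BY-adjusted q.
#' @export
as_edge_list <- function(net) {
  stopifnot(inherits(net, "tmsn"))
  ut <- which(upper.tri(net$W) & net$W != 0, arr.ind = TRUE)
  data.frame(node_a = net$nodes$node[ut[, 1]],
             node_b = net$nodes$node[ut[, 2]],
             layer_a = net$nodes$layer[ut[, 1]],
             layer_b = net$nodes$layer[ut[, 2]],
             weight = net$W[ut],
             r = net$r[ut],
             p = if (is.null(net$pval)) NA_real_ else net$pval[ut],
             q = if (is.null(net$qval)) NA_real_ else net$qval[ut],
             stringsAsFactors = FALSE)
}

#' Write a network to disk
#'
#' `write_edge_list()` writes the long edge table, `write_adjacency()` the
#' dense thresholded weight matrix, and `write_graphml()` a GraphML file
#' (requires igraph) with layer and item annotations.
#'
#' @param net a `tmsn`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  write.csv(as_edge_list(net), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_adjacency <- function(net, path) {
  write.csv(data.frame(node = net$nodes$node, net$W, check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export requires the 'igraph' package")
  g <- igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$layer <- net$nodes$layer
  igraph::V(g)$item_id <- net$nodes$item_id
  igraph::V(g)$instrument <- net$nodes$instrument
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
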