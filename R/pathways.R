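#' Convert edge weights to path lengths
#'
#' Shortest-path analysis needs lengths, not affinities: strongly correlated
#' symptoms should be "close". The default rule is the connectivity-toolbox
#' convention length = 1/weight; `"neg_log"` uses -log(weight) for weights
#' in (0, 1). Path analysis runs on the positive-edge network only --
#' negative correlations have no meaningful path length -- so a network
#' carrying negative edges must be rebuilt with `sign_mode =
#' "positive_only"` first.
#'
#' @param net a `tmsn` with non-negative weights.
#' @param rule `"inverse"` (default) or `"neg_log"`.
#' @return an object of class `tmsn_lengths`: `L` (2p x 2p lengths, `Inf`
#'   for absent edges, 0 diagonal), `rule`, `nodes`, `blocks`.
#' @export
weights_to_lengths <- function(net, rule = c("inverse", "neg_log")) {
  stopifnot(inherits(net, "tmsn"))
  rule <- match.arg(rule)
  W <- net$W
  if (any(W < 0))
    stop("network has negative edges; rebuild with sign_mode = ",
         "'positive_only' before path analysis")
  L <- matrix(Inf, nrow(W), ncol(W), dimnames = dimnames(W))
  e <- W > 0
  if (rule == "inverse") {
    L[e] <- 1 / W[e]
  } else {
    if (any(W[e] >= 1))
      stop("neg_log rule is degenerate for weights >= 1 ",
           "(zero- or negative-length edge)")
    L[e] <- -log(W[e])
  }
  diag(L) <- 0
  structure(list(L = L, rule = rule, nodes = net$nodes, blocks = net$blocks),
            class = "tmsn_lengths")
}

#' All-pairs shortest paths (Floyd-Warshall)
#'
#' Dense Floyd-Warshall over the length graph, returning the distance
#' matrix and a predecessor matrix sufficient to reconstruct one shortest
#' path per pair. Ties are broken deterministically (strict improvement,
#' intermediates scanned in node-index order); with continuous correlation
#' weights exact ties have measure zero.
#'
#' @param lg a `tmsn_lengths`.
#' @return an object of class `tmsn_paths`: `d` (distances, `Inf` when
#'   unreachable), `pred` (1-based predecessor indices, `NA` when none),
#'   `nodes`, `blocks`.
#' @export
shortest_paths_fw <- function(lg) {
  stopifnot(inherits(lg, "tmsn_lengths"))
  if (any(lg$L[upper.tri(lg$L)] < 0)) stop("edge lengths must be positive")
  res <- cpp_floyd_warshall(lg$L)
  pred <- res$pred + 1L
  pred[pred == 0L] <- NA_integer_
  dimnames(res$d) <- dimnames(lg$L)
  structure(list(d = res$d, pred = pred, nodes = lg$nodes,
                 blocks = lg$blocks),
            class = "tmsn_paths")
}

#' Reconstruct one shortest path between two nodes
#'
#' @param paths a `tmsn_paths`.
#' @param from,to node ids or indices.
#' @return integer vector of node indices from `from` to `to`, or `NULL`
#'   when unreachable.
#' @export
reconstruct_path <- function(paths, from, to) {
  stopifnot(inherits(paths, "tmsn_paths"))
  ids <- paths$nodes$node
  i <- if (is.character(from)) match(from, ids) else as.integer(from)
  j <- if (is.character(to)) match(to, ids) else as.integer(to)
  if (is.na(i) || is.na(j)) stop("unknown node")
  if (!is.finite(paths$d[i, j])) return(NULL)
  seq <- j
  while (seq[1] != i) seq <- c(paths$pred[i, seq[1]], seq)
  seq
}

#' Longitudinal betweenness
#'
#' Counts, for every node, the number of baseline-to-follow-up shortest
#' clinical paths on which it is strictly interior (endpoints excluded):
#' one shortest path is reconstructed for every ordered (baseline item,
#' follow-up item) pair with finite distance. High counts mark symptoms
#' that mediate the flow of psychopathology across time.
#'
#' @param lg a `tmsn_lengths` (or a `tmsn`, converted with the default
#'   inverse rule).
#' @param paths optional precomputed [shortest_paths_fw()] result.
#' @return named numeric vector of per-node path counts.
#' @export
longitudinal_betweenness <- function(lg, paths = NULL) {
  if (inherits(lg, "tmsn")) lg <- weights_to_lengths(lg)
  stopifnot(inherits(lg, "tmsn_lengths"))
  paths <- paths %||% shortest_paths_fw(lg)
  bi <- lg$blocks$baseline
  fi <- lg$blocks$followup
  if (!length(bi) || !length(fi)) stop("both layers must be non-empty")
  if (!any(is.finite(paths$d[bi, fi, drop = FALSE])))
    warning("no finite baseline-to-follow-up path; all counts are zero")
  counts <- cpp_longitudinal_betweenness(paths$d,
                                         ifelse(is.na(paths$pred), 0L,
                                                paths$pred) - 1L,
                                         bi - 1L, fi - 1L)
  names(counts) <- lg$nodes$node
  counts
}

#' Permutation test of longitudinal betweenness; gateways and funnels
#'
#' Tests each node's longitudinal betweenness against an edge-reshuffling
#' null: each of `n_null` random networks keeps the observed weight
#' multiset and edge count but re-assigns edges to uniformly random node
#' pairs (layer labels stay on the nodes, so the baseline-to-follow-up pair
#' set is unchanged). Per-node empirical p-values use the add-one rule
#' p = (1 + #null >= observed) / (1 + N) against the null betweenness
#' distribution pooled across nodes within the node's layer (nodes are
#' exchangeable after reshuffling; `pool = "node"` keeps a per-node null).
#' P-values are then BY-adjusted with the same FDR operation used for
#' edges, and significant baseline-layer nodes are labelled gateways,
#' significant follow-up-layer nodes funnels.
#'
#' @param net a `tmsn` with non-negative weights (positive-only network).
#' @param n_null number of reshuffled networks (>= 100; the reference
#'   analysis uses 10000).
#' @param seed optional integer seed.
#' @param alpha FDR level for the gateway/funnel call.
#' @param rule length rule, see [weights_to_lengths()].
#' @param pool `"layer"` (default) or `"node"` null pooling.
#' @return an object of class `tmsn_centrality`: a `table` data frame
#'   (node, item_id, layer, strength, betweenness, p, q, class), the null
#'   draw matrix, `n_null`, `seed`, `alpha`, `pool`.
#' @export
centrality_null_test <- function(net, n_null = 10000, seed = NULL,
                                 alpha = 0.05,
                                 rule = c("inverse", "neg_log"),
                                 pool = c("layer", "node")) {
  stopifnot(inherits(net, "tmsn"))
  if (n_null < 100) stop("n_null must be at least 100")
  pool <- match.arg(pool)
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  lg <- weights_to_lengths(net, rule = rule)
  obs <- longitudinal_betweenness(lg)
  nn <- nrow(net$W)
  lengths <- lg$L[upper.tri(lg$L)]
  lengths <- lengths[is.finite(lengths)]
  if (length(lengths) == 0) {
    null_mat <- matrix(0, 0, nn)
    p <- rep(1, nn)
  } else {
    null_mat <- cpp_null_betweenness(nn, lengths,
                                     net$blocks$baseline - 1L,
                                     net$blocks$followup - 1L,
                                     as.integer(n_null))
    p <- numeric(nn)
    for (l in c("baseline", "followup")) {
      sel <- net$nodes$layer == l
      ref <- if (pool == "layer") as.numeric(null_mat[, sel]) else NULL
      for (i in which(sel)) {
        r <- ref %||% null_mat[, i]
        p[i] <- (1 + sum(r >= obs[i])) / (1 + length(r))
      }
    }
  }
  q <- p.adjust(p, method = "BY")
  cls <- ifelse(q < alpha,
                ifelse(net$nodes$layer == "baseline", "gateway", "funnel"),
                "none")
  tab <- data.frame(node = net$nodes$node, item_id = net$nodes$item_id,
                    layer = net$nodes$layer,
                    strength = unname(node_strength(net)),
                    betweenness = unname(obs), p = p, q = q, class = cls,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, null_distribution = null_mat, n_null = n_null,
                 seed = seed, alpha = alpha, pool = pool, rule = rule),
            class = "tmsn_centrality")
}

#' @export
print.tmsn_centrality <- function(x, ...) {
  cat(sprintf(paste0("Longitudinal betweenness permutation test ",
                     "(%d reshuffled networks, BY alpha = %s)\n"),
              x$n_null, format(x$alpha)))
  sig <- x$table[x$table$class != "none", , drop = FALSE]
  if (nrow(sig)) {
    cat(sprintf("  %d gateway(s), %d funnel(s):\n",
                sum(sig$class == "gateway"), sum(sig$class == "funnel")))
    print(sig[c("node", "layer", "betweenness", "p", "q", "class")],
          row.names = FALSE)
  } else cat("  no node exceeds the null\n")
  invisible(x)
}

#' Extract gateway and funnel symptom lists
#'
#' @param cr a `tmsn_centrality`.
#' @param alpha FDR level (defaults to the level used in the test).
#' @return list with character vectors `gateways` (significant
#'   baseline-layer nodes) and `funnels` (significant follow-up-layer
#'   nodes).
#' @export
classify_gateways_funnels <- function(cr, alpha = cr$alpha) {
  stopifnot(inherits(cr, "tmsn_centrality"))
  sig <- cr$table$q < alpha
  list(gateways = cr$table$node[sig & cr$table$layer == "baseline"],
       funnels = cr$table$node[sig & cr$table$layer == "followup"])
}

#' Per-node predictability
#'
#' Proportion of variance of each node explained by ordinary least squares
#' on its surviving-edge neighbors in the multilayer network (both layers,
#' so a follow-up item may be predicted by baseline and follow-up
#' neighbors). Isolated nodes get 0. With `folds > 1` an out-of-sample
#' cross-validated R^2 (1 - PRESS/TSS) is reported instead. A
#' rank-deficient neighbor design falls back to ridge with a fixed small
#' penalty and is flagged.
#'
#' @param x a `tmsn_cohort` (preprocessed the way the network was built;
#'   raw cohorts are residualized and standardized with the defaults).
#' @param net the `tmsn` fitted on that cohort.
#' @param folds `NULL`/1 for in-sample R^2, or a fold count for
#'   cross-validation.
#' @param seed seed for the fold assignment.
#' @return data frame (node, layer, r2, n_neighbors, ridge) of class
#'   `tmsn_predictability`.
#' @export
nodewise_predictability <- function(x, net, folds = NULL, seed = NULL) {
  stopifnot(inherits(x, "tmsn_cohort"), inherits(net, "tmsn"))
  if (!"residualized" %in% x$preprocessing) x <- residualize_covariates(x)
  if (!"standardized" %in% x$preprocessing) x <- standardize_items(x)
  X <- cbind(x$baseline, x$followup)
  stopifnot(ncol(X) == nrow(net$W))
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  fold_id <- if (!is.null(folds) && folds > 1)
    sample(rep_len(seq_len(folds), n)) else rep(1L, n)
  out <- data.frame(node = net$nodes$node, layer = net$nodes$layer,
                    r2 = 0, n_neighbors = 0L, ridge = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(X))) {
    nb <- which(net$W[, i] != 0)
    out$n_neighbors[i] <- length(nb)
    if (!length(nb)) next
    y <- X[, i]
    Z <- cbind(1, X[, nb, drop = FALSE])
    fit_beta <- function(Zt, yt) {
      qrz <- qr(Zt)
      if (qrz$rank < ncol(Zt)) {
        out$ridge[i] <<- TRUE
        solve(crossprod(Zt) + diag(1e-6, ncol(Zt)), crossprod(Zt, yt))
      } else qr.coef(qrz, yt)
    }
    if (is.null(folds) || folds <= 1) {
      beta <- fit_beta(Z, y)
      res <- y - Z %*% beta
    } else {
      res <- numeric(n)
      for (f in unique(fold_id)) {
        tr <- fold_id != f
        beta <- fit_beta(Z[tr, , drop = FALSE], y[tr])
        res[!tr] <- y[!tr] - Z[!tr, , drop = FALSE] %*% beta
      }
    }
    out$r2[i] <- max(0, 1 - sum(res^2) / sum((y - mean(y))^2))
  }
  class(out) <- c("tmsn_predictability", "data.frame")
  out
}
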