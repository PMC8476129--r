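#' Spectral embedding of the multilayer adjacency
#'
#' Eigendecomposes the thresholded adjacency matrix of a temporal multilayer
#' symptom network. Components are ranked by algebraic eigenvalue
#' (descending); because a signed adjacency has negative eigenvalues, the
#' "variance explained" by component k is reported as
#' lambda_k / sum(max(lambda_j, 0)) for positive lambda_k (a PCA-like
#' reading over the positive part of the spectrum), with the
#' absolute-eigenvalue normalization also stored as `var_explained_abs`.
#'
#' @param net a `tmsn` (or any symmetric weight matrix).
#' @return an object of class `tmsn_embedding`: `loadings` (orthonormal
#'   eigenvectors, one column per component), `eigenvalues`,
#'   `var_explained`, `var_explained_abs`, `k_retained` (NA until
#'   [select_components()] is run), `orientation` and the node table.
#' @export
tmsn_embedding <- function(net) {
  W <- if (inherits(net, "tmsn")) net$W else as.matrix(net)
  .assert_symmetric(W, "adjacency")
  nodes <- if (inherits(net, "tmsn")) net$nodes else
    data.frame(node = rownames(W) %||% paste0("n", seq_len(nrow(W))),
               item_id = rownames(W) %||% paste0("n", seq_len(nrow(W))),
               instrument = "GEN", layer = NA_character_,
               stringsAsFactors = FALSE)
  e <- eigen(W, symmetric = TRUE)       # eigenvalues already descending
  pos <- pmax(e$values, 0)
  ve <- if (sum(pos) > 0) pos / sum(pos) else rep(0, length(pos))
  ve_abs <- if (sum(abs(e$values)) > 0) abs(e$values) / sum(abs(e$values))
            else rep(0, length(pos))
  rownames(e$vectors) <- nodes$node
  structure(list(loadings = e$vectors, eigenvalues = e$values,
                 var_explained = ve, var_explained_abs = ve_abs,
                 k_retained = NA_integer_, orientation = list(),
                 nodes = nodes),
            class = "tmsn_embedding")
}

#' @rdname tmsn_embedding
#' @export
eigendecompose_adjacency <- tmsn_embedding

#' @export
print.tmsn_embedding <- function(x, ...) {
  cat(sprintf("Spectral embedding: %d nodes\n", nrow(x$loadings)))
  k <- min(5, length(x$eigenvalues))
  cat("  leading eigenvalues:",
      paste(sprintf("%.3f", x$eigenvalues[seq_len(k)]), collapse = ", "),
      "\n")
  cat("  variance explained :",
      paste(sprintf("%.3f", x$var_explained[seq_len(k)]), collapse = ", "),
      "\n")
  if (!is.na(x$k_retained))
    cat(sprintf("  components retained against reshuffled null: %d\n",
                x$k_retained))
  invisible(x)
}

#' Reshuffle edge positions, preserving the weight multiset
#'
#' The permutation null shared by component selection and longitudinal
#' betweenness testing: the multiset of surviving edge weights (and hence
#' edge count and total connectivity) is kept, and edges are re-assigned to
#' uniformly sampled distinct node pairs (no self-loops, symmetric).
#'
#' @param W symmetric weight matrix (or a `tmsn`).
#' @return a reshuffled symmetric matrix of the same dimension.
#' @export
reshuffle_edges <- function(W) {
  if (inherits(W, "tmsn")) W <- W$W
  n <- nrow(W)
  ut <- upper.tri(W)
  w <- W[ut][W[ut] != 0]
  out <- matrix(0, n, n, dimnames = dimnames(W))
  if (length(w)) {
    pos <- sample.int(sum(ut), length(w))
    slot <- which(ut)[pos]
    out[slot] <- w
    out <- out + t(out)
  }
  out
}

#' Choose how many spectral components to keep
#'
#' Retains leading components for as long as the observed variance
#' proportion of the k-th component exceeds the chosen percentile (default
#' 95th) of that component's variance proportion across edge-reshuffled
#' null networks; retention stops at the first failure. An empty network
#' retains zero components.
#'
#' @param net a `tmsn`.
#' @param n_null number of reshuffled networks (>= 100; default 1000).
#' @param percentile selection percentile in (0, 1).
#' @param seed optional integer seed for the reshuffling RNG.
#' @param emb optionally, a precomputed [tmsn_embedding()] of `net`.
#' @return the embedding with `k_retained` set and a `tmsn_spectrum_null`
#'   object (fields `n_null`, `null_var_explained`, `percentile`, `seed`)
#'   attached as `$null`.
#' @export
select_components <- function(net, n_null = 1000, percentile = 0.95,
                              seed = NULL, emb = NULL) {
  stopifnot(inherits(net, "tmsn"))
  if (n_null < 100) stop("n_null must be at least 100")
  emb <- emb %||% tmsn_embedding(net)
  if (!is.null(seed)) set.seed(seed)
  if (all(net$W == 0)) {
    emb$k_retained <- 0L
    emb$null <- structure(list(n_null = 0L, null_var_explained = NULL,
                               percentile = percentile, seed = seed),
                          class = "tmsn_spectrum_null")
    return(emb)
  }
  nv <- matrix(NA_real_, n_null, nrow(net$W))
  for (b in seq_len(n_null)) {
    Wb <- reshuffle_edges(net$W)
    lam <- eigen(Wb, symmetric = TRUE, only.values = TRUE)$values
    pos <- pmax(lam, 0)
    nv[b, ] <- if (sum(pos) > 0) pos / sum(pos) else 0
  }
  crit <- apply(nv, 2, quantile, probs = percentile, names = FALSE)
  k <- 0L
  while (k < length(emb$var_explained) &&
         emb$var_explained[k + 1L] > crit[k + 1L]) k <- k + 1L
  emb$k_retained <- k
  emb$null <- structure(list(n_null = n_null, null_var_explained = nv,
                             percentile = percentile, seed = seed),
                        class = "tmsn_spectrum_null")
  emb
}

#' Two-dimensional node coordinates with a fixed orientation
#'
#' Places every node at its loading on the two leading retained components
#' (component 1 on x, component 2 on y). Eigenvectors are sign-ambiguous, so
#' a convention is applied and recorded: the y component is oriented so that
#' the mean loading of follow-up-layer nodes exceeds that of baseline-layer
#' nodes (baseline at the bottom); the x component is oriented to make a
#' named anchor node's loading positive, or failing that to make the loading
#' skewness non-negative.
#'
#' @param emb a `tmsn_embedding` whose node table carries layer labels.
#' @param dims which components to use (default `c(1, 2)`); must lie within
#'   the retained range when [select_components()] has been run.
#' @param anchor optional node id fixing the sign of the first dimension.
#' @return data frame (`node`, `item_id`, `layer`, `x`, `y`) with the sign
#'   convention recorded in the `"orientation"` attribute.
#' @export
embed_nodes <- function(emb, dims = c(1, 2), anchor = NULL) {
  stopifnot(inherits(emb, "tmsn_embedding"), length(dims) == 2)
  if (!is.na(emb$k_retained)) {
    if (emb$k_retained < 2)
      stop("fewer than 2 components retained; cannot embed in 2-D")
    if (max(dims) > emb$k_retained)
      stop("requested dimension exceeds the retained components")
  }
  x <- emb$loadings[, dims[1]]
  y <- emb$loadings[, dims[2]]
  orientation <- list(dims = dims)
  lay <- emb$nodes$layer
  if (all(c("baseline", "followup") %in% lay)) {
    flip_y <- mean(y[lay == "followup"]) < mean(y[lay == "baseline"])
    if (flip_y) y <- -y
    orientation$y_rule <- "followup mean above baseline mean"
    orientation$y_flipped <- flip_y
  }
  if (!is.null(anchor)) {
    i <- match(anchor, emb$nodes$node)
    if (is.na(i)) stop("anchor node not found: ", anchor)
    flip_x <- x[i] < 0
    orientation$x_rule <- paste("anchor", anchor, "positive")
  } else {
    flip_x <- .skewness(x) < 0
    orientation$x_rule <- "non-negative loading skewness"
  }
  if (flip_x) x <- -x
  orientation$x_flipped <- flip_x
  out <- data.frame(node = emb$nodes$node, item_id = emb$nodes$item_id,
                    layer = emb$nodes$layer, x = x, y = y,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "orientation") <- orientation
  out
}

.pair_subset <- function(net, subset) {
  ut <- upper.tri(net$W)
  edge <- ut & net$W != 0
  quad <- .quadrant(net)
  switch(subset,
         all = edge,
         baseline = edge & quad == "baseline",
         followup = edge & quad == "followup",
         longitudinal = edge & quad == "longitudinal",
         positive_only = edge & net$r > 0)
}

#' Does Euclidean distance in the embedding track correlation strength?
#'
#' The embedding-validation statistic: over surviving edges (optionally
#' restricted to one quadrant, or to positive correlations to check against
#' restricted-range artifacts), correlates the Euclidean distance between
#' the two nodes in the 2-D embedding with the raw correlation strength of
#' the edge. A faithful embedding puts strongly correlated symptoms close
#' together, so r should be clearly negative.
#'
#' @param net a `tmsn`.
#' @param coords coordinates from [embed_nodes()].
#' @param subset `"all"`, `"baseline"`, `"followup"`, `"longitudinal"` or
#'   `"positive_only"`.
#' @return list with `r`, `p` and `n_pairs`.
#' @export
distance_correlation_check <- function(net, coords,
                                       subset = c("all", "baseline",
                                                  "followup", "longitudinal",
                                                  "positive_only")) {
  stopifnot(inherits(net, "tmsn"))
  subset <- match.arg(subset)
  idx <- which(.pair_subset(net, subset), arr.ind = TRUE)
  if (nrow(idx) < 3)
    stop("fewer than 3 pairs in subset '", subset, "'")
  stopifnot(identical(coords$node, net$nodes$node))
  d <- sqrt((coords$x[idx[, 1]] - coords$x[idx[, 2]])^2 +
            (coords$y[idx[, 1]] - coords$y[idx[, 2]])^2)
  strength <- net$r[idx]
  ct <- cor.test(d, strength)
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(idx))
}

#' Layer-wise association between the time dimension and longitudinal
#' connectivity
#'
#' For each node, takes the mean raw correlation of its surviving
#' longitudinal (cross-layer) edges, then correlates that mean strength
#' with the component-2 loading separately within the baseline and
#' follow-up layers. Under the orientation convention, baseline symptoms
#' that predict follow-up psychopathology sit higher (positive r at
#' baseline) while follow-up symptoms that are broadly influenced sit lower
#' (negative r at follow-up); the difference of the two correlations is
#' tested by Fisher's r-to-z for independent samples.
#'
#' @param net a `tmsn`.
#' @param coords coordinates from [embed_nodes()].
#' @return list with `r_baseline`, `r_followup`, `p_baseline`,
#'   `p_followup`, `p_difference`, and `no_longitudinal_edge` (node ids
#'   whose mean was zero by convention, flagged).
#' @export
dim2_longitudinal_association <- function(net, coords) {
  stopifnot(inherits(net, "tmsn"))
  quad <- .quadrant(net)
  Wl <- net$W * (quad == "longitudinal")
  if (all(Wl == 0)) stop("no surviving longitudinal edge")
  deg <- rowSums(Wl != 0)
  msl <- ifelse(deg > 0, rowSums(net$r * (Wl != 0)) / pmax(deg, 1), 0)
  flagged <- net$nodes$node[deg == 0]
  res <- lapply(c("baseline", "followup"), function(l) {
    sel <- net$nodes$layer == l
    if (sd(msl[sel]) == 0 || sd(coords$y[sel]) == 0)
      stop("degenerate layer '", l, "': zero variance in loading or strength")
    cor.test(coords$y[sel], msl[sel])
  })
  n_b <- sum(net$nodes$layer == "baseline")
  n_f <- sum(net$nodes$layer == "followup")
  list(r_baseline = unname(res[[1]]$estimate),
       r_followup = unname(res[[2]]$estimate),
       p_baseline = res[[1]]$p.value, p_followup = res[[2]]$p.value,
       p_difference = .fisher_r_diff_p(res[[1]]$estimate, n_b,
                                       res[[2]]$estimate, n_f),
       no_longitudinal_edge = flagged)
}

#' Correlate component loadings across embeddings
#'
#' Compares the topological embedding of shared items across two networks
#' (two cohorts, or the two temporal layers of one network). Because
#' eigenvector signs are arbitrary, the sign of the second embedding's
#' component is chosen to maximize the absolute correlation, and the choice
#' is reported.
#'
#' @param emb_a,emb_b `tmsn_embedding` objects.
#' @param mapping `NULL` (match on shared node ids) or a two-column data
#'   frame of (`a`, `b`) node ids.
#' @param dim component index to compare.
#' @return list with `r`, `p`, `flipped` and `n`.
#' @export
compare_loadings <- function(emb_a, emb_b, mapping = NULL, dim = 1) {
  stopifnot(inherits(emb_a, "tmsn_embedding"),
            inherits(emb_b, "tmsn_embedding"))
  if (is.null(mapping)) {
    shared <- intersect(emb_a$nodes$node, emb_b$nodes$node)
    mapping <- data.frame(a = shared, b = shared, stringsAsFactors = FALSE)
  } else {
    mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
    names(mapping) <- c("a", "b")
  }
  ia <- match(mapping$a, emb_a$nodes$node)
  ib <- match(mapping$b, emb_b$nodes$node)
  if (anyNA(ia) || anyNA(ib))
    stop("mapping references node(s) absent from an embedding")
  if (nrow(mapping) < 3) stop("need at least 3 mapped items")
  la <- emb_a$loadings[ia, dim]
  lb <- emb_b$loadings[ib, dim]
  ct <- cor.test(la, lb)
  flipped <- unname(ct$estimate) < 0
  if (flipped) ct <- cor.test(la, -lb)
  list(r = unname(ct$estimate), p = ct$p.value, flipped = flipped,
       n = nrow(mapping))
}

#' Plot a fitted network in its spectral embedding
#'
#' Scatter of nodes at their 2-D spectral coordinates, baseline layer in
#' green and follow-up in orange, node size scaled by strength, surviving
#' edges drawn as light segments.
#'
#' @param x a `tmsn`.
#' @param coords optional precomputed [embed_nodes()] coordinates.
#' @param labels draw item labels.
#' @param ... passed to [graphics::plot()].
#' @return the coordinates, invisibly.
#' @export
plot.tmsn <- function(x, coords = NULL, labels = FALSE, ...) {
  coords <- coords %||% embed_nodes(tmsn_embedding(x))
  s <- node_strength(x)
  cex <- 0.8 + 1.6 * if (max(s) > 0) s / max(s) else s
  col <- ifelse(coords$layer == "followup", "darkorange3", "forestgreen")
  graphics::plot(coords$x, coords$y, type = "n",
                 xlab = "network dimension 1", ylab = "network dimension 2",
                 ...)
  idx <- which(upper.tri(x$W) & x$W != 0, arr.ind = TRUE)
  if (nrow(idx))
    graphics::segments(coords$x[idx[, 1]], coords$y[idx[, 1]],
                       coords$x[idx[, 2]], coords$y[idx[, 2]],
                       col = grDevices::adjustcolor("grey60", 0.4))
  graphics::points(coords$x, coords$y, pch = 21, bg = col, cex = cex)
  if (labels)
    graphics::text(coords$x, coords$y, coords$item_id, pos = 3, cex = 0.6)
  invisible(coords)
}
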