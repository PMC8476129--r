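# Independent brute-force oracles, deliberately written from the definitions
# rather than reusing any package code path.

# Benjamini-Yekutieli step-up, evaluated literally at every k
oracle_by_stepup <- function(p, alpha) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * alpha / (m * cm))
  reject <- logical(m)
  if (length(ks)) reject[o[seq_len(max(ks))]] <- TRUE
  reject
}

# Benjamini-Hochberg step-up for the conservativeness comparison
oracle_bh_stepup <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(ks)) reject[o[seq_len(max(ks))]] <- TRUE
  reject
}

# exhaustive simple-path enumeration: distance matrix and, for a given
# ordered pair, the minimising path (unique a.s. with continuous lengths)
oracle_all_paths <- function(len) {
  n <- nrow(len)
  best_d <- matrix(Inf, n, n)
  diag(best_d) <- 0
  best_path <- vector("list", n * n)
  dfs <- function(path, dist) {
    v <- path[length(path)]
    i <- path[1]
    if (length(path) > 1 && dist < best_d[i, v]) {
      best_d[i, v] <<- dist
      best_path[[(i - 1) * n + v]] <<- path
    }
    for (w in seq_len(n)) {
      if (w %in% path) next
      l <- len[v, w]
      if (!is.finite(l) || l <= 0) next
      dfs(c(path, w), dist + l)
    }
  }
  for (i in seq_len(n)) dfs(i, 0)
  list(d = best_d, path = function(i, j) best_path[[(i - 1) * n + j]])
}

# longitudinal betweenness from the enumeration oracle
oracle_longitudinal_betweenness <- function(len, base_idx, fup_idx) {
  or <- oracle_all_paths(len)
  counts <- numeric(nrow(len))
  for (i in base_idx) for (j in fup_idx) {
    if (i == j || !is.finite(or$d[i, j])) next
    pth <- or$path(i, j)
    interior <- pth[-c(1, length(pth))]
    counts[interior] <- counts[interior] + 1
  }
  counts
}

# OLS residuals by explicit normal equations
oracle_ols_residuals <- function(y, X) {
  as.numeric(y - X %*% solve(t(X) %*% X, t(X) %*% y))
}

# random symmetric positive-weight graph, resampled until connected
random_connected_graph <- function(n, p_edge = 0.4, wmin = 0.2, wmax = 0.9) {
  repeat {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W))
    on <- ut[runif(length(ut)) < p_edge]
    W[on] <- runif(length(on), wmin, wmax)
    W <- W + t(W)
    # connectivity by BFS
    seen <- logical(n)
    queue <- 1L
    seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(W[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (all(seen)) return(W)
  }
}

# wrap a bare weight matrix as a two-layer network object
as_test_tmsn <- function(W, n_baseline = floor(nrow(W) / 2)) {
  n <- nrow(W)
  ids <- sprintf("n%02d", seq_len(n))
  layer <- rep(c("baseline", "followup"), c(n_baseline, n - n_baseline))
  nodes <- data.frame(node = paste0(ids, ifelse(layer == "baseline",
                                                "@bl", "@fu")),
                      item_id = ids, instrument = "GEN", layer = layer,
                      stringsAsFactors = FALSE)
  dimnames(W) <- list(nodes$node, nodes$node)
  tmsn:::.new_tmsn(W, nodes, mask = W != 0, r = W)
}

# off-diagonal cross-lag matrix used by the prediction-superiority checks:
# diagonal autocorrelation plus nearest-neighbour cross-lags
offdiagonal_cross_lag <- function(p, rho = 0.35, eff = 0.15) {
  A <- diag(rho, p)
  for (i in seq_len(p)) for (d in c(-1L, 1L)) {
    j <- i + d
    if (j >= 1 && j <= p) A[i, j] <- A[i, j] + eff
  }
  A
}
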