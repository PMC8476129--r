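test_that("eigendecomposition matches the 2x2 closed form and reconstructs W", {
  W <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  emb <- tmsn_embedding(as_test_tmsn(W, 1))
  expect_equal(emb$eigenvalues, c(0.5, -0.5))
  expect_equal(unname(abs(emb$loadings[, 1])), rep(1 / sqrt(2), 2))
  expect_equal(emb$var_explained, c(1, 0))   # positive-part normalization
  # reconstruction V diag(lambda) V' = W
  set.seed(6)
  W2 <- random_connected_graph(12)
  e2 <- tmsn_embedding(as_test_tmsn(W2))
  rec <- e2$loadings %*% diag(e2$eigenvalues) %*% t(e2$loadings)
  expect_lt(max(abs(rec - W2)) / max(abs(W2)), 1e-10)
  # zero matrix has an all-zero spectrum
  expect_equal(tmsn_embedding(as_test_tmsn(matrix(0, 4, 4)))$eigenvalues,
               rep(0, 4))
  expect_error(tmsn_embedding(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("embedding is equivariant under node relabeling", {
  set.seed(7)
  W <- random_connected_graph(10)
  perm <- sample(10)
  e1 <- tmsn_embedding(as_test_tmsn(W))
  e2 <- tmsn_embedding(as_test_tmsn(W[perm, perm]))
  expect_equal(e2$eigenvalues, e1$eigenvalues)
  for (k in 1:3) {   # compare up to the eigenvector sign
    a <- e1$loadings[perm, k]; b <- e2$loadings[, k]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)
  }
})

test_that("edge reshuffling preserves the weight multiset and symmetry", {
  set.seed(8)
  net <- planted_block_network(p_per_layer = 8, density = 0.5, seed = 8)
  Wn <- reshuffle_edges(net)
  expect_true(isSymmetric(Wn))
  expect_equal(unname(diag(Wn)), rep(0, nrow(Wn)))
  expect_equal(sort(Wn[upper.tri(Wn)][Wn[upper.tri(Wn)] != 0]),
               sort(net$W[upper.tri(net$W)][net$W[upper.tri(net$W)] != 0]))
})

test_that("component selection keeps planted structure and nothing from its own null", {
  # planted two-block network: at least the block and global components
  hits <- vapply(1:40, function(s) {
    net <- planted_block_network(p_per_layer = 20,
                                 w = c(0.6, 0.6, 0.05, 0.05),
                                 noise_sd = 0.05, seed = s)
    select_components(net, n_null = 100, seed = 1000 + s)$k_retained
  }, numeric(1))
  expect_gte(mean(hits >= 2), 0.95)
  # calibration: an observed network that IS one draw of its null retains
  # >= 1 component in about 5% of runs at the 95th percentile
  base <- planted_block_network(p_per_layer = 10, seed = 99)
  set.seed(123)
  ret <- vapply(1:200, function(i) {
    null_net <- as_test_tmsn(reshuffle_edges(base), 10)
    select_components(null_net, n_null = 100)$k_retained >= 1
  }, logical(1))
  expect_lt(abs(mean(ret) - 0.05), 0.05)
  # an empty network retains nothing
  empty <- as_test_tmsn(matrix(0, 8, 8))
  expect_equal(select_components(empty, n_null = 100)$k_retained, 0L)
})

test_that("2-D embedding separates blocks on x and layers on y with the stated orientation", {
  net <- planted_block_network(seed = 17)
  emb <- tmsn_embedding(net)
  co <- embed_nodes(emb)
  lay <- as.integer(co$layer == "followup")
  blk <- net$nodes$block
  expect_gt(abs(cor(co$x, blk)), 0.5)   # point-biserial, block on x
  expect_gt(abs(cor(co$y, lay)), 0.5)   # layer on y
  # orientation convention: follow-up mean above baseline mean, recorded
  expect_gt(mean(co$y[co$layer == "followup"]),
            mean(co$y[co$layer == "baseline"]))
  orient <- attr(co, "orientation")
  expect_true(is.logical(orient$y_flipped))
  # anchoring fixes the x sign explicitly
  co2 <- embed_nodes(emb, anchor = co$node[1])
  expect_gte(co2$x[1], 0)
})

test_that("nodes with identical connectivity get identical coordinates", {
  # nodes 1 and 2 have identical rows; the two leading eigenvalues must be
  # simple so the coordinates are determined up to sign
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- W[1, 3] <- W[3, 1] <- W[2, 3] <- W[3, 2] <- 0.6
  W[3, 4] <- W[4, 3] <- 0.4
  emb <- tmsn_embedding(as_test_tmsn(W, 2))
  expect_gt(emb$eigenvalues[1] - emb$eigenvalues[2], 1e-6)
  expect_gt(abs(emb$eigenvalues[2]), 1e-6)
  co <- embed_nodes(emb)
  expect_equal(co$x[1], co$x[2], tolerance = 1e-10)
  expect_equal(co$y[1], co$y[2], tolerance = 1e-10)
})

test_that("distance in a faithful embedding tracks correlation strength", {
  net <- planted_block_network(seed = 23)
  co <- embed_nodes(tmsn_embedding(net))
  for (subset in c("all", "baseline", "followup", "longitudinal")) {
    chk <- distance_correlation_check(net, co, subset)
    expect_lt(chk$r, -0.2)
    expect_lt(chk$p, 0.01)
  }
  # a distance that decreases exactly with weight gives r = -1: place nodes
  # on a line so |xi - xj| = 1 - w for the only pairs with edges
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.8
  W[1, 3] <- W[3, 1] <- 0.2
  W[2, 3] <- W[3, 2] <- 0.4
  net2 <- as_test_tmsn(W, 1)
  co2 <- data.frame(node = net2$nodes$node, item_id = net2$nodes$item_id,
                    layer = net2$nodes$layer,
                    x = c(0, 0.2, 0.8), y = 0)
  expect_equal(distance_correlation_check(net2, co2, "all")$r, -1)
  # random coordinates carry no signal
  set.seed(9)
  rs <- vapply(1:50, function(i) {
    cor_rand <- co
    cor_rand$x <- rnorm(nrow(co)); cor_rand$y <- rnorm(nrow(co))
    distance_correlation_check(net, cor_rand, "all")$r
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.1), 0.9)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("fewer than three pairs is an error", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  net <- as_test_tmsn(W, 2)
  co <- embed_nodes(tmsn_embedding(net))
  expect_error(distance_correlation_check(net, co, "all"), "3 pairs")
})

test_that("the time dimension correlates with longitudinal connectivity as planted", {
  # baseline items 1..p/2 carry all the cross-lags: their dim-2 association
  # should be positive at baseline and the layer difference significant
  p <- 20
  A <- matrix(0, p, p)
  carriers <- 1:10
  for (i in carriers) {
    A[i, i] <- 0.35
    A[i, setdiff(seq_len(p), i)[seq(1, p - 1, by = 2)]] <- 0.22
  }
  spec <- generative_spec(n_subjects = 200, p_items = p, cross_lag = A)
  hits <- vapply(1:30, function(s) {
    coh <- sample_cohort(spec, seed = s)$cohort
    net <- suppressWarnings(tmsn(coh))
    co <- embed_nodes(tmsn_embedding(net))
    d2 <- dim2_longitudinal_association(net, co)
    d2$r_baseline > 0 && d2$p_difference < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # degenerate: no longitudinal edges at all
  Wd <- matrix(0, 4, 4)
  Wd[1, 2] <- Wd[2, 1] <- 0.5    # baseline-baseline only
  netd <- as_test_tmsn(Wd, 2)
  cod <- embed_nodes(tmsn_embedding(netd))
  expect_error(dim2_longitudinal_association(netd, cod),
               "no surviving longitudinal edge")
})

test_that("loading comparison resolves the eigenvector sign ambiguity", {
  net <- planted_block_network(seed = 29)
  emb <- tmsn_embedding(net)
  same <- compare_loadings(emb, emb, dim = 1)
  expect_equal(same$r, 1)
  expect_false(same$flipped)
  flipped <- emb
  flipped$loadings <- -flipped$loadings
  cmp <- compare_loadings(emb, flipped, dim = 1)
  expect_equal(cmp$r, 1)
  expect_true(cmp$flipped)
  # two cohorts from one generative spec agree on dimension 1
  spec <- generative_spec(n_subjects = 200, p_items = 12)
  agree <- vapply(1:20, function(s) {
    e1 <- tmsn_embedding(suppressWarnings(
      tmsn(sample_cohort(spec, seed = 2 * s)$cohort)))
    e2 <- tmsn_embedding(suppressWarnings(
      tmsn(sample_cohort(spec, seed = 2 * s + 1)$cohort)))
    compare_loadings(e1, e2, dim = 1)$r > 0.2
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})
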