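test_that("weight-to-length conversion follows the inverse and neg-log rules", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.25
  net <- as_test_tmsn(W, 2)
  lg <- weights_to_lengths(net)
  expect_equal(lg$L[1, 2], 2)
  expect_equal(lg$L[2, 3], 4)
  expect_true(is.infinite(lg$L[1, 3]))
  expect_equal(unname(diag(lg$L)), rep(0, 3))
  nl <- weights_to_lengths(net, "neg_log")
  expect_equal(nl$L[1, 2], -log(0.5))
  # monotonicity: stronger edges are shorter under both rules
  expect_lt(lg$L[1, 2], lg$L[2, 3])
  expect_lt(nl$L[1, 2], nl$L[2, 3])
  # w = 1 is fine for the inverse rule, degenerate for neg-log
  W1 <- matrix(0, 2, 2); W1[1, 2] <- W1[2, 1] <- 1
  expect_equal(weights_to_lengths(as_test_tmsn(W1, 1))$L[1, 2], 1)
  expect_error(weights_to_lengths(as_test_tmsn(W1, 1), "neg_log"),
               "degenerate")
  # negative edges must be removed before path analysis
  Wn <- matrix(0, 2, 2); Wn[1, 2] <- Wn[2, 1] <- -0.4
  expect_error(weights_to_lengths(as_test_tmsn(Wn, 1)), "positive_only")
})

test_that("Floyd-Warshall finds multi-hop shortcuts on toy graphs", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  paths <- shortest_paths_fw(weights_to_lengths(as_test_tmsn(W, 2)))
  expect_equal(paths$d[1, 3], 2)
  expect_equal(reconstruct_path(paths, 1, 3), c(1, 2, 3))
  # triangle: direct length 3 vs two hops of 1 + 1
  Wt <- matrix(0, 3, 3)
  Wt[1, 3] <- Wt[3, 1] <- 1 / 3
  Wt[1, 2] <- Wt[2, 1] <- 1; Wt[2, 3] <- Wt[3, 2] <- 1
  pt <- shortest_paths_fw(weights_to_lengths(as_test_tmsn(Wt, 2)))
  expect_equal(pt$d[1, 3], 2)
  expect_equal(reconstruct_path(pt, 1, 3), c(1, 2, 3))
  # unreachable pairs stay infinite
  Wd <- matrix(0, 4, 4); Wd[1, 2] <- Wd[2, 1] <- 0.5
  pd <- shortest_paths_fw(weights_to_lengths(as_test_tmsn(Wd, 2)))
  expect_true(is.infinite(pd$d[1, 3]))
  expect_null(reconstruct_path(pd, 1, 3))
})

test_that("distances and betweenness match exhaustive enumeration on random graphs", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    W <- random_connected_graph(n, p_edge = 0.5)
    nb <- sample(2:(n - 2), 1)
    net <- as_test_tmsn(W, nb)
    lg <- weights_to_lengths(net)
    paths <- shortest_paths_fw(lg)
    oracle <- oracle_all_paths(lg$L)
    expect_equal(paths$d, oracle$d, ignore_attr = TRUE)
    got <- longitudinal_betweenness(lg, paths)
    want <- oracle_longitudinal_betweenness(lg$L, seq_len(nb),
                                            (nb + 1):n)
    expect_equal(unname(got), want)
  }
})

test_that("interior-node counting follows the worked toy examples", {
  # baseline {A,B}, follow-up {C}; edges A-B, B-C: only B is interior
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5; W[2, 3] <- W[3, 2] <- 0.5
  expect_equal(unname(longitudinal_betweenness(as_test_tmsn(W, 2))),
               c(0, 1, 0))
  # baseline {A,B}, follow-up {F,T}; edges A-F, B-F, F-T: F mediates twice
  W2 <- matrix(0, 4, 4)
  W2[1, 3] <- W2[3, 1] <- 0.5
  W2[2, 3] <- W2[3, 2] <- 0.5
  W2[3, 4] <- W2[4, 3] <- 0.5
  expect_equal(unname(longitudinal_betweenness(as_test_tmsn(W2, 2))),
               c(0, 0, 2, 0))
  # no finite baseline-to-follow-up path: zero counts with a warning
  W3 <- matrix(0, 4, 4); W3[1, 2] <- W3[2, 1] <- 0.5
  expect_warning(b3 <- longitudinal_betweenness(as_test_tmsn(W3, 2)),
                 "no finite")
  expect_equal(unname(b3), rep(0, 4))
})

test_that("strengthening an edge on a unique shortest path cannot reduce interior betweenness", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5   # baseline 1 - baseline 2
  W[2, 3] <- W[3, 2] <- 0.5   # baseline 2 - followup 3
  W[1, 3] <- W[3, 1] <- 0.2   # weak direct route
  W[3, 4] <- W[4, 3] <- 0.5
  before <- longitudinal_betweenness(as_test_tmsn(W, 2))
  W[2, 3] <- W[3, 2] <- 0.9
  after <- longitudinal_betweenness(as_test_tmsn(W, 2))
  expect_true(all(after[2] >= before[2]))
})

test_that("the permutation test is deterministic at a fixed seed and p-values behave", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.6
  W[2, 3] <- W[3, 2] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.4
  net <- as_test_tmsn(W, 2)
  a <- centrality_null_test(net, n_null = 100, seed = 77)
  b <- centrality_null_test(net, n_null = 100, seed = 77)
  expect_identical(a$table, b$table)
  expect_identical(a$null_distribution, b$null_distribution)
  # a node with zero observed betweenness has p = 1
  expect_true(all(a$table$p[a$table$betweenness == 0] == 1))
  expect_true(all(a$table$p > 0 & a$table$p <= 1))
  # an empty network gives all p = 1 deterministically
  empty <- as_test_tmsn(matrix(0, 4, 4), 2)
  ce <- suppressWarnings(centrality_null_test(empty, n_null = 100, seed = 1))
  expect_true(all(ce$table$p == 1))
})

test_that("null p-values are valid under exchangeable random networks", {
  set.seed(41)
  base <- planted_block_network(p_per_layer = 6, density = 0.5, seed = 41)
  base$W <- abs(base$W)   # positive lengths
  ps <- vapply(1:150, function(i) {
    Wnull <- reshuffle_edges(base$W)
    net <- as_test_tmsn(Wnull, 6)
    suppressWarnings(
      centrality_null_test(net, n_null = 100)$table$p[1])
  }, numeric(1))
  for (t in c(0.05, 0.1, 0.2))
    expect_lte(mean(ps <= t), t + 1 / 101 + 0.06)  # + Monte-Carlo slack
})

test_that("planted gateways are recovered with few false same-layer hubs", {
  spec <- plant_pathway_structure(generative_spec(), gateway_count = 1,
                                  funnel_count = 0, effect = 0.3)
  res <- vapply(1:10, function(s) {
    coh <- sample_cohort(spec, seed = s)$cohort
    net <- suppressWarnings(tmsn(coh, sign_mode = "positive_only"))
    cr <- centrality_null_test(net, n_null = 500, seed = 5000 + s)
    gf <- classify_gateways_funnels(cr)
    c(hit = paste0(spec$gateways, "@bl") %in% gf$gateways,
      false_gw = length(setdiff(gf$gateways,
                                paste0(spec$gateways, "@bl"))))
  }, numeric(2))
  expect_gte(mean(res[1, ]), 0.9)
  expect_lt(median(res[2, ]), 1)
})

test_that("gateway and funnel labels go to the right layers", {
  spec <- plant_pathway_structure(generative_spec(), 0, 1, 0.3)
  coh <- sample_cohort(spec, seed = 2)$cohort
  cr <- centrality_null_test(
    suppressWarnings(tmsn(coh, sign_mode = "positive_only")),
    n_null = 500, seed = 12)
  gf <- classify_gateways_funnels(cr)
  expect_true(all(grepl("@bl$", gf$gateways)))
  expect_true(all(grepl("@fu$", gf$funnels)))
  expect_true(paste0(spec$funnels, "@fu") %in% gf$funnels)
  # classes in the table agree with the q threshold
  expect_true(all((cr$table$class != "none") == (cr$table$q < cr$alpha)))
})

test_that("nodewise predictability recovers exact and partial dependence", {
  set.seed(51)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y_exact <- x1
  y_half <- 0.5 * (x1 + x2) + rnorm(n, 0, sd(0.5 * (x1 + x2)))
  bl <- cbind(a = x1, b = x2)
  fu <- cbind(c = y_exact, d = y_half)
  coh <- cohort(bl, fu, data.frame(age_baseline = rnorm(n, 14),
                                   age_followup = rnorm(n, 17),
                                   sex = rbinom(n, 1, 0.5)),
                item_panel(c("a", "b"), scale_min = -30, scale_max = 30),
                item_panel(c("c", "d"), scale_min = -30, scale_max = 30))
  W <- matrix(0, 4, 4)
  W[1, 3] <- W[3, 1] <- 0.9               # c's only neighbor is a
  W[1, 4] <- W[4, 1] <- 0.4               # d depends on a and b
  W[2, 4] <- W[4, 2] <- 0.4
  net <- as_test_tmsn(W, 2)
  net$nodes$node <- c("a@bl", "b@bl", "c@fu", "d@fu")
  pr <- nodewise_predictability(coh, net, folds = NULL)
  expect_gt(pr$r2[pr$node == "c@fu"], 0.95)
  expect_lt(abs(pr$r2[pr$node == "d@fu"] - 0.5), 0.1)
  expect_lt(abs(pr$r2[pr$node == "b@bl"] - 0.25), 0.1)
  # an isolated node has predictability 0
  W2 <- W; W2[, 2] <- W2[2, ] <- 0
  net2 <- net; net2$W <- W2
  pr2 <- nodewise_predictability(coh, net2)
  expect_equal(pr2$r2[pr2$node == "b@bl"], 0)
})
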