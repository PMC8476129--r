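#' Specify a synthetic two-wave cohort
#'
#' Defines a linear-Gaussian cross-lagged panel on the standardized scale,
#' emulating the structure the network pipeline assumes in real clinical
#' panels: baseline items drawn from a block-structured covariance (an
#' "affective" and a "negative/disorganized" module), follow-up items
#' generated as `followup = t(A) baseline + noise`, where the innovations
#' share the block correlation (so both temporal layers carry the same
#' cross-sectional module structure) and are scaled per item so variances
#' stay stationary at 1, plus linear age and sex effects. The
#' cross-lag matrix `A` has `A[i, j]` = standardized effect of baseline
#' item i on follow-up item j; its default is `auto_rho` on the diagonal
#' (pure autocorrelation). Scores are affinely mapped to an instrument-like
#' 0-6 range (optionally discretized to integers).
#'
#' @param n_subjects number of subjects.
#' @param p_items items per wave.
#' @param blocks integer block assignment of length `p_items`; default
#'   splits items into two equal modules.
#' @param within_block_r,between_block_r target cross-sectional
#'   correlations.
#' @param auto_rho diagonal cross-lag (stationary autocorrelation),
#'   in `[0, 1)`; the default 0.35 matches the item-level clinical
#'   stability typically observed over a multi-year follow-up.
#' @param cross_lag optional full p x p cross-lag matrix `A`, overriding
#'   `auto_rho` off the default diagonal.
#' @param noise_sd `NULL` (default) derives per-item innovation sds that
#'   keep item variances stationary at 1, flooring the sd at 0.2 (with a
#'   non-stationarity flag) for items whose planted incoming effects
#'   already explain almost all variance; a vector/scalar overrides them.
#' @param age_slope severity change per year of age, z units.
#' @param sex_offset additive z-unit offset for sex = 1, applied to the
#'   items flagged in `sex_items` (default: the first module).
#' @param sex_items logical vector of length `p_items`.
#' @param discretize round scores to the integer 0-6 scale (for Spearman
#'   robustness checks); the default keeps them continuous.
#' @param seed RNG seed stored in the spec and used by [sample_cohort()].
#' @return an object of class `tmsn_genspec` (with the implied baseline
#'   covariance `Sigma`, the cross-lag `A` and innovation sds
#'   precomputed).
#' @export
generative_spec <- function(n_subjects = 200, p_items = 20, blocks = NULL,
                            within_block_r = 0.3, between_block_r = 0.05,
                            auto_rho = 0.35, cross_lag = NULL,
                            noise_sd = NULL, age_slope = 0.02,
                            sex_offset = 0.15, sex_items = NULL,
                            discretize = FALSE, seed = NULL) {
  stopifnot(n_subjects >= 4, p_items >= 2)
  if (auto_rho < 0 || auto_rho >= 1)
    stop("auto_rho must lie in [0, 1)")
  blocks <- blocks %||% c(rep(1, ceiling(p_items / 2)),
                          rep(2, floor(p_items / 2)))
  blocks <- rep_len(as.integer(blocks), p_items)
  Sigma <- outer(blocks, blocks,
                 function(a, b) ifelse(a == b, within_block_r,
                                       between_block_r))
  diag(Sigma) <- 1
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8)
    stop("implied baseline covariance is not positive definite ",
         "(within_block_r = ", within_block_r, ", between_block_r = ",
         between_block_r, ")")
  A <- cross_lag %||% diag(auto_rho, p_items)
  stopifnot(nrow(A) == p_items, ncol(A) == p_items)
  fuvar <- diag(t(A) %*% Sigma %*% A)
  nonstationary <- logical(p_items)
  if (is.null(noise_sd)) {
    # innovations share the cross-sectional block correlation (so both
    # temporal layers carry the same module structure) and are scaled
    # per item to keep variances stationary at 1 where the cross-lag
    # structure leaves room; items whose explained variance already
    # exceeds 1 - floor^2 (heavily planted funnels) get the floor sd
    # and are flagged non-stationary.
    floor_sd <- 0.2
    nonstationary <- fuvar > 1 - floor_sd^2
    noise_sd <- sqrt(pmax(1 - fuvar, floor_sd^2))
  } else {
    noise_sd <- rep_len(noise_sd, p_items)
    if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  }
  sex_items <- sex_items %||% (blocks == blocks[1])
  structure(list(n_subjects = n_subjects, p_items = p_items,
                 blocks = blocks, within_block_r = within_block_r,
                 between_block_r = between_block_r, auto_rho = auto_rho,
                 A = A, Sigma = Sigma, noise_sd = noise_sd,
                 nonstationary = nonstationary,
                 age_slope = age_slope, sex_offset = sex_offset,
                 sex_items = rep_len(sex_items, p_items),
                 discretize = discretize, seed = seed,
                 gateways = character(0), funnels = character(0)),
            class = "tmsn_genspec")
}

#' @export
print.tmsn_genspec <- function(x, ...) {
  cat(sprintf("Synthetic two-wave cohort spec: n = %d, p = %d items/wave\n",
              x$n_subjects, x$p_items))
  cat(sprintf("  blocks: %s; within r = %s, between r = %s, auto rho = %s\n",
              paste(table(x$blocks), collapse = "+"),
              format(x$within_block_r), format(x$between_block_r),
              format(x$auto_rho)))
  if (length(x$gateways))
    cat("  planted gateways:", paste(x$gateways, collapse = ", "), "\n")
  if (length(x$funnels))
    cat("  planted funnels:", paste(x$funnels, collapse = ", "), "\n")
  invisible(x)
}

.item_ids <- function(p) sprintf("item%02d", seq_len(p))

#' Plant gateway and funnel structure into a generative spec
#'
#' Gateways are baseline items with broad out-going cross-lags: each
#' designated item gets a standardized effect onto at least half of the
#' follow-up items (rows of `A` with broad support). Funnels are follow-up
#' items broadly receiving effects from at least half of the baseline
#' items (columns of `A` with broad support). Innovation sds are
#' re-derived to keep variances stationary; an effect too large for
#' stationarity is an error suggesting a smaller one.
#'
#' @param spec a `tmsn_genspec`.
#' @param gateway_count,funnel_count how many items to designate; gateways
#'   are taken from the start of the panel, funnels from the end.
#' @param effect standardized cross-lag slope added per planted edge.
#' @param coverage fraction of opposite-wave items each planted item
#'   connects to (>= 0.5 by definition of broad support).
#' @return the modified spec, with `gateways` / `funnels` recorded.
#' @export
plant_pathway_structure <- function(spec, gateway_count = 1,
                                    funnel_count = 1, effect = 0.3,
                                    coverage = 0.5) {
  stopifnot(inherits(spec, "tmsn_genspec"),
            gateway_count + funnel_count <= spec$p_items, coverage >= 0.5,
            coverage <= 1)
  if (effect == 0) return(spec)
  p <- spec$p_items
  ids <- .item_ids(p)
  gw <- seq_len(gateway_count)
  fn <- seq.int(p - funnel_count + 1L, length.out = funnel_count)
  if (length(intersect(gw, fn)))
    stop("gateway and funnel sets overlap; reduce the counts")
  A <- spec$A
  k <- ceiling(coverage * p)
  # planted edges are interleaved over the panel so both modules are
  # covered evenly (a contiguous target set would leave a single
  # cross-module bridge item that becomes a hub of its own)
  spread <- function(cand, k)
    cand[round(seq(1, length(cand), length.out = k))]
  for (g in gw) {
    targets <- spread(setdiff(seq_len(p), c(g, fn)), k)
    A[g, targets] <- A[g, targets] + effect
  }
  for (f in fn) {
    sources <- spread(setdiff(seq_len(p), c(f, gw)), k)
    A[sources, f] <- A[sources, f] + effect
  }
  out <- tryCatch(
    generative_spec(n_subjects = spec$n_subjects, p_items = p,
                    blocks = spec$blocks,
                    within_block_r = spec$within_block_r,
                    between_block_r = spec$between_block_r,
                    auto_rho = spec$auto_rho, cross_lag = A,
                    age_slope = spec$age_slope,
                    sex_offset = spec$sex_offset,
                    sex_items = spec$sex_items,
                    discretize = spec$discretize, seed = spec$seed),
    error = function(e)
      stop("planting failed (", conditionMessage(e),
           "); try a smaller effect", call. = FALSE))
  # planted effects may push a funnel above unit variance (flagged), but a
  # column whose explained sd exceeds twice the stationary target is out of
  # the regime the generator is meant to emulate
  fuvar <- diag(t(out$A) %*% out$Sigma %*% out$A)
  if (any(fuvar > 4))
    stop("planted effects explain more than twice the stationary sd for ",
         "item(s) ", paste(ids[fuvar > 4], collapse = ", "),
         "; try a smaller effect", call. = FALSE)
  out$gateways <- ids[gw]
  out$funnels <- ids[fn]
  out
}

#' Draw a synthetic cohort from a generative spec
#'
#' Baseline z-scores are multivariate normal with the spec's block
#' covariance; follow-up z-scores are `t(A) baseline + noise` with
#' stationary scaling; age (baseline about 12-18 years, follow-up about
#' 3 years later) and sex (Bernoulli 1/2) effects are added; and scores
#' are mapped to an instrument-like scale centred at 3 (discretized and
#' clipped to 0-6 integers when the spec says so). Instruments are named
#' after the block ("AFF", "NEG") so instrument-augmentation code paths
#' can be exercised.
#'
#' @param spec a `tmsn_genspec`.
#' @param seed overrides the spec's seed.
#' @return list with `cohort` (a `tmsn_cohort`) and `truth` (block labels,
#'   planted gateway/funnel item ids, `A`, `Sigma`, `noise_sd`).
#' @export
sample_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "tmsn_genspec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  p <- spec$p_items
  ids <- .item_ids(p)
  Zb <- matrix(rnorm(n * p), n, p) %*% chol(spec$Sigma)
  Zf <- Zb %*% spec$A +
    (matrix(rnorm(n * p), n, p) %*% chol(spec$Sigma)) %*%
      diag(spec$noise_sd, p)
  age_b <- round(runif(n, 12, 18), 1)
  age_f <- age_b + round(runif(n, 2.5, 4.5), 1)
  sex <- rbinom(n, 1, 0.5)
  sex_vec <- spec$sex_offset * spec$sex_items
  Zb <- Zb + outer(age_b - 15, rep(spec$age_slope, p)) + outer(sex, sex_vec)
  Zf <- Zf + outer(age_f - 18.5, rep(spec$age_slope, p)) + outer(sex, sex_vec)
  to_scale <- function(Z) {
    S <- Z + 3
    if (spec$discretize) S <- pmin(pmax(round(S), 0), 6)
    S
  }
  lo <- if (spec$discretize) 0 else -22
  hi <- if (spec$discretize) 6 else 28
  panel <- item_panel(ids,
                      instrument = c("AFF", "NEG")[spec$blocks],
                      scale_min = lo, scale_max = hi)
  coh <- cohort(to_scale(Zb), to_scale(Zf),
                covariates = data.frame(age_baseline = age_b,
                                        age_followup = age_f, sex = sex),
                baseline_items = panel, followup_items = panel)
  list(cohort = coh,
       truth = list(gateways = spec$gateways, funnels = spec$funnels,
                    blocks = setNames(spec$blocks, ids), A = spec$A,
                    Sigma = spec$Sigma, noise_sd = spec$noise_sd))
}

#' A structureless calibration cohort
#'
#' Items are i.i.d. standard normal at both waves, with covariates present
#' but without any effect: every surviving edge, retained component or
#' flagged hub downstream is a false positive, which makes this the
#' fixture for calibration checks.
#'
#' @param n,p subjects and items per wave.
#' @param seed RNG seed.
#' @return a `tmsn_cohort`.
#' @export
null_cohort <- function(n = 200, p = 20, seed = NULL) {
  spec <- generative_spec(n_subjects = n, p_items = p, within_block_r = 0,
                          between_block_r = 0, auto_rho = 0, age_slope = 0,
                          sex_offset = 0, seed = seed)
  sample_cohort(spec)$cohort
}

#' Planted two-block, two-wave network fixture
#'
#' Builds a multilayer adjacency directly (no cohort sampling) with a known
#' spectral architecture: two symptom modules ("blocks") spanning two
#' temporal layers, with edge weights set by whether a pair shares a block
#' and whether it shares a layer, plus symmetric Gaussian jitter and
#' optional sparsification. With the defaults -- within-block edges 0.6
#' (same layer) / 0.2 (cross-layer), between-block edges -0.1 / -0.5
#' (anticorrelated modules, weights chosen so the block contrast is the
#' leading non-global spectral component and the layer contrast the
#' second) -- the first embedding dimension separates the blocks and the
#' second separates the layers. Setting all four weights positive (e.g.
#' `w = c(0.6, 0.6, 0.05, 0.05)`) gives the classic planted two-block
#' model.
#'
#' @param p_per_layer items per layer (nodes total: `2 * p_per_layer`).
#' @param w length-4 weights: within-block same-layer, within-block
#'   cross-layer, between-block same-layer, between-block cross-layer.
#' @param noise_sd sd of the symmetric jitter added to present edges.
#' @param density fraction of node pairs kept as edges.
#' @param seed RNG seed.
#' @return a `tmsn` whose node table carries a `block` column;
#'   `r` equals the weight matrix.
#' @export
planted_block_network <- function(p_per_layer = 20,
                                  w = c(0.6, 0.2, -0.1, -0.5),
                                  noise_sd = 0.05, density = 1,
                                  seed = NULL) {
  stopifnot(length(w) == 4, density > 0, density <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- p_per_layer
  ids <- .item_ids(p)
  block <- rep(rep(1:2, c(ceiling(p / 2), floor(p / 2))), 2)
  layer <- rep(c("baseline", "followup"), each = p)
  nodes <- data.frame(node = paste0(rep(ids, 2),
                                    rep(c("@bl", "@fu"), each = p)),
                      item_id = rep(ids, 2), instrument = "GEN",
                      layer = layer, block = block,
                      stringsAsFactors = FALSE)
  nn <- 2 * p
  same_b <- outer(block, block, "==")
  same_l <- outer(layer, layer, "==")
  W <- ifelse(same_b, ifelse(same_l, w[1], w[2]),
              ifelse(same_l, w[3], w[4]))
  jit <- matrix(rnorm(nn * nn, 0, noise_sd), nn, nn)
  W <- W + (jit + t(jit)) / sqrt(2)
  keep <- matrix(TRUE, nn, nn)
  if (density < 1) {
    ut <- which(upper.tri(keep))
    drop <- sample(ut, round((1 - density) * length(ut)))
    keep[drop] <- FALSE
    keep <- keep & t(keep)
  }
  W <- W * keep
  diag(W) <- 0
  dimnames(W) <- list(nodes$node, nodes$node)
  .new_tmsn(W, nodes, mask = W != 0, r = W)
}
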