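#' Graph Laplacian of the diffusion network
#'
#' Builds L = D - W (combinatorial) or the symmetric normalized variant
#' D^{-1/2} (D - W) D^{-1/2}, where D is the diagonal matrix of node
#' strengths (sum of absolute incident weights). The Laplacian acts as the
#' difference operator of the diffusion equation dx/dt = -gamma L x.
#' Diffusion is intended for positive-weight networks: signed input is
#' accepted with a warning (the clamped equilibrium may then violate the
#' maximum principle). Zero-strength nodes leave their normalized row zero.
#'
#' @param net a `tmsn`, or a symmetric weight matrix.
#' @param kind `"combinatorial"` (default) or `"normalized"`.
#' @return the Laplacian matrix.
#' @export
build_laplacian <- function(net, kind = c("combinatorial", "normalized")) {
  kind <- match.arg(kind)
  W <- if (inherits(net, "tmsn")) net$W else as.matrix(net)
  .assert_symmetric(W, "weight matrix")
  if (any(W < 0))
    warning("negative edge weights: the diffusion operator is experimental ",
            "for signed networks")
  s <- rowSums(abs(W))
  L <- diag(s, nrow(W)) - W
  if (kind == "normalized") {
    inv <- ifelse(s > 0, 1 / sqrt(s), 0)
    L <- L * outer(inv, inv)
  }
  dimnames(L) <- dimnames(W)
  L
}

#' Diffusion solver settings
#'
#' @param gamma diffusion rate (1/time, > 0). The clamped equilibrium does
#'   not depend on it; only convergence speed does.
#' @param step explicit-Euler time step; `NULL` (default) picks
#'   1/(gamma * lambda_max(L)), inside the stability region
#'   step < 2/(gamma * lambda_max).
#' @param tol convergence threshold on the max-abs signal change over free
#'   nodes between iterations (default 1e-9).
#' @param max_iter iteration cap; hitting it flags non-convergence.
#' @param laplacian_kind see [build_laplacian()].
#' @return a list of class `diffusion_config`.
#' @export
diffusion_config <- function(gamma = 1, step = NULL, tol = 1e-9,
                             max_iter = 1e6,
                             laplacian_kind = c("combinatorial",
                                                "normalized")) {
  stopifnot(gamma > 0, tol > 0, max_iter >= 1)
  structure(list(gamma = gamma, step = step, tol = tol,
                 max_iter = as.integer(max_iter),
                 laplacian_kind = match.arg(laplacian_kind)),
            class = "diffusion_config")
}

.default_step <- function(L, gamma) {
  lmax <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (lmax <= 0) return(1)
  1 / (gamma * lmax)
}

#' Clamped (Dirichlet) graph diffusion to steady state
#'
#' Iterates the explicit finite-difference scheme
#' x <- x - gamma * step * L x and, after every iteration, re-imposes the
#' observed values on the clamped (baseline-layer) nodes, until the max-abs
#' change over the free nodes drops below `tol` (default 1e-9). The free
#' nodes converge to the harmonic extension of the clamped boundary values
#' (see [harmonic_steady_state()]).
#'
#' @param L Laplacian matrix from [build_laplacian()].
#' @param x0 initial signal; clamped entries hold the observed values,
#'   free entries are conventionally started at 0.
#' @param clamped logical mask of clamped nodes.
#' @param config a [diffusion_config()].
#' @return an object of class `tmsn_signal`: `x` (steady signal),
#'   `clamped`, `iterations`, `delta`, `converged`.
#' @export
clamped_diffusion <- function(L, x0, clamped, config = diffusion_config()) {
  stopifnot(length(x0) == nrow(L), length(clamped) == nrow(L))
  step <- config$step %||% .default_step(L, config$gamma)
  res <- cpp_clamped_diffusion(L, as.numeric(x0), as.logical(clamped),
                               config$gamma, step, config$tol,
                               config$max_iter)
  if (res$diverged)
    stop("diffusion diverged; reduce the time step ",
         "(stability needs step < 2/(gamma*lambda_max))")
  structure(list(x = setNames(res$x, rownames(L)), clamped = clamped,
                 iterations = res$iterations, delta = res$delta,
                 converged = res$converged, step = step,
                 gamma = config$gamma),
            class = "tmsn_signal")
}

#' @export
print.tmsn_signal <- function(x, ...) {
  cat(sprintf("Clamped diffusion signal: %d nodes (%d clamped), %s after %d iterations (delta = %.2e)\n",
              length(x$x), sum(x$clamped),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$delta))
  invisible(x)
}

#' Harmonic (equilibrium) solution of the clamped diffusion
#'
#' At the steady state of the clamped diffusion, L x = 0 on the free nodes,
#' so the free values solve the Dirichlet problem
#' L_UU x_U = -L_UB x_B given the boundary (clamped) values x_B. This exact
#' linear solve is the analytic oracle for [clamped_diffusion()] and the
#' fast path of [loocv_predict()]. A free connected component with no edge
#' to any clamped node has a singular block: in lenient mode (default) its
#' nodes get value 0 and are flagged; otherwise this is an error.
#'
#' @param L Laplacian matrix.
#' @param values boundary values (full-length vector; free entries ignored,
#'   or a vector of length `sum(clamped)`).
#' @param clamped logical mask of boundary nodes.
#' @param lenient assign 0 to unreachable free components instead of
#'   erroring.
#' @return full signal vector with attributes `"free"` (indices) and
#'   `"unreached"` (flagged free nodes, if any).
#' @export
harmonic_steady_state <- function(L, values, clamped, lenient = TRUE) {
  n <- nrow(L)
  clamped <- as.logical(clamped)
  stopifnot(length(clamped) == n)
  xB <- if (length(values) == n) values[clamped] else values
  stopifnot(length(xB) == sum(clamped))
  x <- numeric(n)
  x[clamped] <- xB
  U <- which(!clamped)
  if (!length(U)) return(structure(x, free = integer(0),
                                   unreached = integer(0)))
  # free components grounded to the boundary via any nonzero off-diagonal
  A <- L[U, U, drop = FALSE]
  off <- abs(A) > 0; diag(off) <- FALSE
  comp <- rep(0L, length(U)); cid <- 0L
  for (s in seq_along(U)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(off[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  LB <- L[U, clamped, drop = FALSE]
  grounded_comp <- unique(comp[rowSums(abs(LB)) > 0])
  solvable <- comp %in% grounded_comp
  if (any(!solvable)) {
    if (!lenient)
      stop("free component(s) without boundary attachment: nodes ",
           paste(U[!solvable], collapse = ", "))
    x[U[!solvable]] <- 0
  }
  if (any(solvable)) {
    Us <- U[solvable]
    x[Us] <- solve(L[Us, Us, drop = FALSE],
                   -L[Us, clamped, drop = FALSE] %*% xB)
  }
  structure(x, free = U, unreached = U[!solvable])
}

#' Closed-form unclamped diffusion
#'
#' Evaluates x(t) = exp(-gamma L t) x0 through the symmetric
#' eigendecomposition of L. Used to verify the finite-difference scheme:
#' on a connected graph with combinatorial Laplacian the signal relaxes to
#' the conserved mean of x0 as t grows.
#'
#' @param L symmetric Laplacian matrix.
#' @param x0 initial signal.
#' @param gamma diffusion rate.
#' @param t diffusion time.
#' @return the signal at time `t`.
#' @export
matrix_exponential_diffusion <- function(L, x0, gamma = 1, t = 1) {
  .assert_symmetric(L, "Laplacian")
  e <- eigen(L, symmetric = TRUE)
  drop(e$vectors %*% (exp(-gamma * e$values * t) * crossprod(e$vectors, x0)))
}
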