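`%||%` <- function(a, b) if (is.null(a)) b else a

# sample skewness; 0 for (near-)symmetric input
.skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s < 1e-12) return(0)
  mean(x^3) / s^3
}

.assert_symmetric <- function(M, what = "matrix", tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(what, " must be a square matrix", call. = FALSE)
  if (max(abs(M - t(M))) > tol)
    stop(what, " must be symmetric", call. = FALSE)
  invisible(TRUE)
}

# two-sided p for a difference of two independent Pearson correlations
# (Fisher r-to-z)
.fisher_r_diff_p <- function(r1, n1, r2, n2) {
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * pnorm(-abs(z1 - z2) / se)
}

# correlation + two-sided p from the t transform with n-2 df
.cor_pval <- function(r, n) {
  p <- rep(1, length(r))
  ok <- is.finite(r) & abs(r) < 1
  t <- abs(r[ok]) * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(t, df = n - 2, lower.tail = FALSE)
  p[is.finite(r) & abs(r) >= 1] <- 0
  p
}
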