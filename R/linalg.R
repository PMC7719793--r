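#' Condensed singular value decomposition
#'
#' Decomposes `X` as `U %*% diag(d) %*% t(V)` keeping only the strictly
#' positive singular triplets, so `U` is `p x r` and `V` is `q x r` with
#' orthonormal columns and `d` the non-increasing positive singular values.
#' Singular values at or below `rank_tol * d[1]` are treated as numerically
#' zero and dropped.
#'
#' @param X a numeric matrix with finite entries.
#' @param rank_tol non-negative relative tolerance deciding numerical rank.
#' @return a list of class `"condensed_svd"` with components `u` (`p x r`),
#'   `d` (length `r`) and `v` (`q x r`); `r` may be zero.
#' @examples
#' s <- condensed_svd(diag(c(3, 1, 0)))
#' s$d  # 3 1
#' @export
condensed_svd <- function(X, rank_tol = 1e-12) {
  X <- as_finite_matrix(X, "X")
  if (!is.numeric(rank_tol) || length(rank_tol) != 1L || rank_tol < 0)
    stop("'rank_tol' must be a single non-negative number")
  s <- svd(X)
  keep <- if (length(s$d) == 0L || s$d[1] <= 0) logical(0) else
    s$d > max(rank_tol * s$d[1], 0)
  r <- sum(keep)
  out <- list(
    u = s$u[, seq_len(r), drop = FALSE],
    d = s$d[seq_len(r)],
    v = s$v[, seq_len(r), drop = FALSE]
  )
  class(out) <- "condensed_svd"
  out
}

#' Singular value thresholding (proximal operator of the nuclear norm)
#'
#' Soft-thresholds the singular values of `X` by `tau`:
#' `svt(X, tau) = U diag(pmax(d - tau, 0)) t(V)`. This is the unique
#' minimizer of `tau * ||S||_* + 0.5 * ||S - X||_F^2` over `S`.
#'
#' @param X a numeric matrix.
#' @param tau non-negative threshold.
#' @return a matrix of the same dimension as `X`, with rank at most `rank(X)`.
#' @examples
#' svt(diag(c(3, 1)), 2)  # diag(1, 0)
#' @export
svt <- function(X, tau) {
  X <- as_finite_matrix(X, "X")
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("'tau' must be a single non-negative number")
  if (tau == 0) return(X)
  s <- svd(X)
  d <- pmax(s$d - tau, 0)
  pos <- d > 0
  if (!any(pos)) return(matrix(0, nrow(X), ncol(X)))
  s$u[, pos, drop = FALSE] %*% (d[pos] * t(s$v[, pos, drop = FALSE]))
}

#' Nuclear norm (sum of singular values)
#'
#' @param X a numeric matrix.
#' @return the sum of singular values of `X`; zero iff `X` is the zero matrix.
#' @export
nuclear_norm <- function(X) {
  X <- as_finite_matrix(X, "X")
  sum(svd(X, nu = 0, nv = 0)$d)
}

#' Distance from a matrix to the subdifferential of the nuclear norm
#'
#' The subdifferential of `||X||_*` at `X` with condensed SVD `U diag(d) V'`
#' is the set `U V' + Z` over matrices `Z` orthogonal to the row and column
#' spaces of `X` (`U'Z = 0`, `Z V = 0`) with spectral norm at most one. The
#' residual returned is the maximum of (a) the Frobenius norm of the part of
#' `G - U V'` that leaks into the span of `U` or `V`, and (b) the excess
#' spectral norm `max(0, sigma_1(Z) - 1)` of the orthogonal-complement part.
#' It is zero (up to tolerance) iff `G` is a valid subgradient.
#'
#' @param X,G numeric matrices of identical dimension.
#' @param rank_tol relative tolerance for the numerical rank of `X`.
#' @return a single non-negative number.
#' @export
nuclear_subgradient_residual <- function(X, G, rank_tol = 1e-12) {
  X <- as_finite_matrix(X, "X")
  G <- as_finite_matrix(G, "G")
  if (!all(dim(X) == dim(G)))
    stop("'X' and 'G' must have identical dimensions")
  s <- condensed_svd(X, rank_tol)
  base <- if (length(s$d)) s$u %*% t(s$v) else matrix(0, nrow(X), ncol(X))
  D <- G - base
  # project onto the orthogonal complement of col(U) x col(V)
  Z <- D
  if (length(s$d)) {
    Z <- Z - s$u %*% crossprod(s$u, Z)
    Z <- Z - (Z %*% s$v) %*% t(s$v)
  }
  leakage <- sqrt(sum((D - Z)^2))
  sig1 <- if (all(Z == 0)) 0 else svd(Z, nu = 0, nv = 0)$d[1]
  max(leakage, max(0, sig1 - 1))
}

# Frobenius norm shorthand used throughout the optimizer.
frob <- function(X) sqrt(sum(X * X))

as_finite_matrix <- function(X, name) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop(sprintf("'%s' must be a numeric matrix", name))
  if (!all(is.finite(X)))
    stop(sprintf("'%s' contains non-finite entries", name))
  X
}
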