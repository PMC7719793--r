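#' Box-constrained dual quadratic program
#'
#' Container for the dual problem
#' `max_alpha -0.5 * t(alpha) K alpha + t(H) alpha` subject to
#' `0 <= alpha <= C` and `t(alpha) %*% Y == 0`, the form taken by the
#' `(W, b)` subproblem of the support matrix machine and by the linear SVM
#' dual. `K` must be symmetric positive semidefinite and `Y` a vector of
#' +/-1 labels.
#'
#' @param K symmetric PSD `N x N` matrix.
#' @param H numeric vector of length `N`.
#' @param Y numeric vector of +/-1 labels of length `N`.
#' @param C positive box bound.
#' @return an object of class `"dual_qp"`.
#' @export
dual_qp <- function(K, H, Y, C) {
  K <- as_finite_matrix(K, "K")
  n <- nrow(K)
  if (ncol(K) != n) stop("'K' must be square")
  if (max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K))))
    stop("'K' must be symmetric")
  H <- as.numeric(H); Y <- as.numeric(Y)
  if (length(H) != n || length(Y) != n)
    stop("'H' and 'Y' must have length nrow(K)")
  if (!all(abs(Y) == 1)) stop("'Y' entries must be -1 or +1")
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
    stop("'C' must be a single positive number")
  structure(list(K = K, H = H, Y = Y, C = C), class = "dual_qp")
}

#' Solve the box-constrained equality-constrained dual QP
#'
#' Maximizes `-0.5 t(a) K a + t(H) a` over `0 <= a <= C`, `sum(a * Y) = 0`
#' by pairwise coordinate ascent in the maximal-violating-pair direction
#' (SMO): each step moves along `Y[i] e_i - Y[j] e_j`, which preserves the
#' equality constraint exactly, with the step length solved in closed form
#' and clipped to the box. `alpha = 0` is always feasible, so the problem is
#' never infeasible. If the Gram matrix has a negative smallest eigenvalue
#' (numerically singular near-duplicate trials) it is regularized by
#' `+1e-10 * I` before solving.
#'
#' @param problem a [dual_qp()] object.
#' @param tol convergence tolerance on the KKT residual.
#' @param max_iter maximum number of pair updates.
#' @param alpha0 optional feasible starting point (warm start, e.g. the
#'   previous ADMM iteration's multipliers); defaults to zero.
#' @return a list of class `"dual_solution"` with `alpha`, `objective`,
#'   `support_set` (indices with `alpha > 1e-8 * C`), `kkt_residual` and
#'   `iterations`.
#' @seealso [kkt_residual()]
#' @export
solve_box_eq_qp <- function(problem, tol = 1e-8, max_iter = 10000L,
                            alpha0 = NULL) {
  stopifnot(inherits(problem, "dual_qp"))
  K <- problem$K; H <- problem$H; Y <- problem$Y; C <- problem$C
  n <- length(H)
  if (!isTRUE(attr(K, "psd_checked"))) {
    ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 0) K <- K + diag(1e-10, n)
  }

  if (is.null(alpha0)) {
    a <- numeric(n)
    g <- H                    # gradient of the objective: H - K a
  } else {
    a <- pmin(pmax(as.numeric(alpha0), 0), C)
    if (abs(sum(a * Y)) > 1e-12 * max(1, C * n)) {
      a <- numeric(n)         # infeasible warm start: fall back to zero
    }
    g <- H - if (all(a == 0)) 0 else as.numeric(K %*% a)
  }
  Fv <- Y * g
  it <- 0L
  res <- Inf
  if (n == 1L) {
    # the equality constraint pins the single variable at zero
    res <- 0
  } else {
    eps_b <- 1e-12 * C
    dK <- diag(K)
    # Periodic exact ascent on the current free set: pairwise updates
    # equilibrate free support vectors very slowly when the reduced Hessian
    # is ill-conditioned (rank-deficient Gram matrices of vectorized
    # trials). Working in the null space of the equality constraint, a
    # Newton jump solves the well-posed eigendirections exactly, and a
    # second box-capped move follows the gradient along numerically flat
    # eigendirections (each such move pins a variable to a bound, changing
    # the active set). Every move is an exact line search on the concave
    # quadratic, so the objective never decreases and feasibility is exact.
    newton_every <- 50L
    line_jump <- function(a, g, d) {
      lo_cap <- ifelse(d < 0, a / -d, Inf)
      hi_cap <- ifelse(d > 0, (C - a) / d, Inf)
      theta_max <- min(lo_cap, hi_cap)
      slope <- sum(g * d)
      if (!is.finite(theta_max) || theta_max <= 0 || slope <= 1e-16)
        return(NULL)
      curv_d <- sum(d * as.numeric(K %*% d))
      theta <- if (curv_d > 1e-14) min(slope / curv_d, theta_max)
      else theta_max
      a2 <- pmin(pmax(a + theta * d, 0), C)
      list(a = a2, g = H - as.numeric(K %*% a2))
    }
    try_newton <- function(a, g) {
      free <- a > eps_b & a < C - eps_b
      nf <- sum(free)
      if (nf < 2L) return(NULL)
      Z <- qr.Q(qr(matrix(Y[free], ncol = 1)), complete = TRUE)[, -1,
                                                                drop = FALSE]
      Hr <- crossprod(Z, K[free, free, drop = FALSE] %*% Z)
      es <- eigen((Hr + t(Hr)) / 2, symmetric = TRUE)
      lam <- es$values
      solved <- lam > 1e-12 * max(lam, 1e-300)
      gs <- as.numeric(crossprod(es$vectors, crossprod(Z, g[free])))
      moved <- FALSE
      u1 <- es$vectors %*% ifelse(solved, gs / pmax(lam, 1e-300), 0)
      d1 <- numeric(n); d1[free] <- as.numeric(Z %*% u1)
      r <- line_jump(a, g, d1)
      if (!is.null(r)) { a <- r$a; g <- r$g; moved <- TRUE }
      if (any(!solved)) {
        gs2 <- as.numeric(crossprod(es$vectors, crossprod(Z, g[free])))
        u2 <- es$vectors %*% ifelse(solved, 0, gs2)
        d2 <- numeric(n); d2[free] <- as.numeric(Z %*% u2)
        r2 <- line_jump(a, g, d2)
        if (!is.null(r2)) { a <- r2$a; g <- r2$g; moved <- TRUE }
      }
      if (!moved) return(NULL)
      list(a = a, g = g)
    }
    repeat {
      up <- (Y > 0 & a < C - eps_b) | (Y < 0 & a > eps_b)
      dn <- (Y > 0 & a > eps_b) | (Y < 0 & a < C - eps_b)
      if (!any(up) || !any(dn)) { res <- 0; break }
      i <- which(up)[which.max(Fv[up])]
      m_dn <- min(Fv[dn])
      res <- Fv[i] - m_dn
      if (res <= tol || it >= max_iter) break
      if (it > 0L && it %% newton_every == 0L) {
        nt <- try_newton(a, g)
        if (!is.null(nt)) {
          a <- nt$a; g <- nt$g; Fv <- Y * g
          it <- it + 1L
          next
        }
      }
      # second-order partner: maximal objective gain among descent partners
      cand <- which(dn & Fv < Fv[i])
      if (length(cand) == 0L) cand <- which(dn)
      curv_c <- pmax(K[i, i] + dK[cand] - 2 * Y[i] * Y[cand] * K[cand, i],
                     1e-12)
      j <- cand[which.max((Fv[i] - Fv[cand])^2 / curv_c)]
      # move along d = Y[i] e_i - Y[j] e_j by t > 0
      curv <- K[i, i] + K[j, j] - 2 * Y[i] * Y[j] * K[i, j]
      tmax_i <- if (Y[i] > 0) C - a[i] else a[i]
      tmax_j <- if (Y[j] > 0) a[j] else C - a[j]
      tmax <- min(tmax_i, tmax_j)
      t_step <- if (curv > 1e-14) min((Fv[i] - Fv[j]) / curv, tmax) else tmax
      if (t_step <= 0) break
      a[i] <- a[i] + Y[i] * t_step
      a[j] <- a[j] - Y[j] * t_step
      dg <- -(K[, i] * (Y[i] * t_step)) + K[, j] * (Y[j] * t_step)
      g <- g + dg
      Fv <- Y * g
      it <- it + 1L
    }
  }
  obj <- sum(H * a) - 0.5 * sum(a * (K %*% a))
  out <- structure(list(
    alpha = a,
    objective = obj,
    support_set = which(a > 1e-8 * C),
    kkt_residual = kkt_residual(problem, a),
    iterations = it
  ), class = "dual_solution")
  if (res > tol && it >= max_iter) {
    cond <- structure(
      class = c("klsmm_solver_failure", "error", "condition"),
      list(message = sprintf(
        "dual QP did not reach tol %.1e within %d updates (residual %.3e)",
        tol, max_iter, res),
        call = sys.call(-1), best = out))
    stop(cond)
  }
  out
}

#' KKT residual of a candidate dual solution
#'
#' Measures the maximal stationarity violation of `K a - H + mu * Y` with the
#' scalar multiplier `mu` chosen optimally, respecting the active-set sign
#' conditions: interior coordinates must be stationary, coordinates at the
#' lower (upper) box bound may only have a gradient pushing outward. Zero at
#' the exact optimum. The minimization over `mu` is exact: the violation is
#' piecewise linear and convex in `mu`, so it is evaluated at all breakpoints
#' and midpoints.
#'
#' @param problem a [dual_qp()] object.
#' @param alpha candidate multipliers, inside the box up to `1e-8 * C`.
#' @return a single non-negative number.
#' @export
kkt_residual <- function(problem, alpha) {
  stopifnot(inherits(problem, "dual_qp"))
  K <- problem$K; H <- problem$H; Y <- problem$Y; C <- problem$C
  a <- as.numeric(alpha)
  if (length(a) != length(H)) stop("'alpha' has wrong length")
  if (any(a < -1e-8 * C) || any(a > C * (1 + 1e-8)))
    stop("'alpha' violates the box constraint")
  g <- H - as.numeric(K %*% a)
  Fv <- Y * g
  eps <- 1e-10 * C
  at_lo <- a <= eps
  at_hi <- a >= C - eps
  interior <- !at_lo & !at_hi
  # i "up-binding" (needs F_i <= mu): free to increase along +Y_i direction
  needs_le <- interior | (at_lo & Y > 0) | (at_hi & Y < 0)
  needs_ge <- interior | (at_lo & Y < 0) | (at_hi & Y > 0)
  viol <- function(mu) {
    v1 <- if (any(needs_le)) max(0, max(Fv[needs_le] - mu)) else 0
    v2 <- if (any(needs_ge)) max(0, max(mu - Fv[needs_ge])) else 0
    max(v1, v2)
  }
  cand <- sort(unique(Fv))
  if (length(cand) > 1L) cand <- c(cand, (cand[-1] + cand[-length(cand)]) / 2)
  cand <- c(cand, min(Fv) - 1, max(Fv) + 1)  # one-sided cases
  min(vapply(cand, viol, numeric(1)))
}
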