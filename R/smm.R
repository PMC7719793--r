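#' Fit a support matrix machine, optionally with model-parameter transfer
#'
#' Fits the matrix classifier `f(X) = sum(W * X) + b` by minimizing the
#' spectral elastic net plus hinge loss
#' \deqn{\tfrac12 tr(W'W) + \tau \|W\|_* + C \sum_i \max(0, 1 - y_i f(X_i))
#'   + \lambda\, tr[(W_s - W)'(W_s - W)],}
#' where the nuclear-norm term encourages a low-rank coefficient matrix and
#' the optional last term (the knowledge-leverage penalty, active when
#' `lambda > 0` and `W_source` is supplied) pulls the target coefficient
#' matrix toward a source subject's fitted matrix `W_s` — transferring model
#' parameters rather than raw trials. With `lambda = 0` this is the plain
#' support matrix machine; with `tau = 0` and `lambda = 0` it coincides with
#' a soft-margin linear SVM on the vectorized trials.
#'
#' The solver is ADMM on the split `S = W`: the `(W, b)` subproblem is solved
#' through its box-constrained dual QP (coefficient matrix
#' `K_ij = y_i y_j tr(X_i' X_j) / (2*lambda + rho + 1)`), the `S` subproblem
#' by singular value thresholding (`S = svt(rho*W - Lambda, tau) / rho`), and
#' the multiplier by `Lambda <- Lambda + rho * (S - W)`. All state is
#' initialized at zero; the optimizer uses no randomness. An optional
#' accelerated mode applies Nesterov-style extrapolation to `(S, Lambda)`
#' with a restart rule triggered when the combined residual fails to decay
#' by factor `eta`.
#'
#' @param x trials: a list of `p x q` matrices, a `c(p, q, N)` array, or a
#'   [matrix_dataset()].
#' @param y binary labels (ignored if `x` is a labeled dataset).
#' @param C positive hinge-loss weight.
#' @param tau non-negative nuclear-norm weight.
#' @param lambda non-negative transfer weight; requires `W_source` if > 0.
#' @param W_source source coefficient matrix `W_s` (`p x q`) or `NULL`.
#' @param rho ADMM penalty parameter, fixed across iterations.
#' @param max_iter maximum ADMM iterations.
#' @param tol_primal relative tolerance on the primal residual
#'   `||S - W||_F <= tol_primal * max(1, ||W||_F)`.
#' @param tol_obj relative tolerance on the objective change.
#' @param accelerated logical; use the extrapolated solver.
#' @param eta restart factor in (0, 1) for the accelerated mode.
#' @param qp_tol,qp_max_iter tolerances passed to [solve_box_eq_qp()].
#' @return an object of class `"smm"`; see Details. Components include the
#'   coefficient matrix `W`, intercept `b`, dual variables `alpha`, support
#'   set, convergence diagnostics (`objective_trace`, `primal_trace`,
#'   `stationarity_residual`, `kkt_residual`, `converged`, `n_iter`) and the
#'   call parameters.
#' @examples
#' set.seed(1)
#' mod <- make_lowrank_model(p = 4, q = 4, rank = 2, shift = 0, seed = 1)
#' ds <- sample_matrix_dataset(mod$W_source, 0, n = 40, seed = 2)
#' fit <- smm(ds, C = 1, tau = 0.1)
#' mean(predict(fit, ds) == ds$y)
#' @export
smm <- function(x, y = NULL, C = 1, tau = 0.1, lambda = 0, W_source = NULL,
                rho = 1, max_iter = 500L, tol_primal = 1e-4, tol_obj = 1e-6,
                accelerated = FALSE, eta = 0.999,
                qp_tol = 1e-8, qp_max_iter = 20000L) {
  data <- if (inherits(x, "matrix_dataset")) x else matrix_dataset(x, y)
  if (is.null(data$y)) stop("training data must be labeled")
  if (!any(data$y > 0) || !any(data$y < 0))
    stop("training data must contain both classes")
  check_pos <- function(v, nm) if (!is.numeric(v) || length(v) != 1 ||
                                   !is.finite(v) || v <= 0)
    stop(sprintf("'%s' must be a single positive number", nm))
  check_pos(C, "C"); check_pos(rho, "rho")
  if (tau < 0) stop("'tau' must be non-negative")
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (lambda > 0 && is.null(W_source))
    stop("'W_source' is required when lambda > 0")
  if (!is.null(W_source)) {
    W_source <- as_finite_matrix(W_source, "W_source")
    if (nrow(W_source) != data$p || ncol(W_source) != data$q)
      stop("'W_source' dimensions must match the trials")
  }
  if (accelerated && (eta <= 0 || eta >= 1))
    stop("'eta' must lie in (0, 1)")

  p <- data$p; q <- data$q; n <- data$n
  yy <- data$y
  Xv <- trial_design(data)                  # n x pq
  ws <- if (is.null(W_source)) numeric(p * q) else vec_rm(W_source)
  denom <- 2 * lambda + rho + 1
  K <- (tcrossprod(Xv) * tcrossprod(yy)) / denom
  # Gram matrices of near-duplicate trials can be numerically indefinite;
  # regularize once, then skip the spectral check inside the iteration loop
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) < 0)
    K <- K + diag(1e-10, n)
  attr(K, "psd_checked") <- TRUE

  w <- numeric(p * q); b <- 0
  S <- numeric(p * q); L <- numeric(p * q)
  S_h <- S; L_h <- L; v_acc <- 1; c_prev <- Inf

  obj_trace <- numeric(0); primal_trace <- numeric(0)
  alpha <- numeric(n); delta <- integer(0)
  converged <- FALSE; warned_delta <- FALSE
  stat_res <- NA_real_; kkt <- NA_real_
  obj_prev <- Inf

  for (k in seq_len(max_iter)) {
    S_use <- if (accelerated) S_h else S
    L_use <- if (accelerated) L_h else L
    Mv <- L_use + rho * S_use + 2 * lambda * ws
    Hh <- 1 - yy * as.numeric(Xv %*% Mv) / denom
    prob <- dual_qp(K, Hh, yy, C)
    sol <- tryCatch(solve_box_eq_qp(prob, tol = qp_tol,
                                    max_iter = qp_max_iter,
                                    alpha0 = if (k > 1) alpha),
                    klsmm_solver_failure = function(e) {
                      warning(conditionMessage(e), call. = FALSE)
                      e$best
                    })
    alpha <- sol$alpha
    kkt <- sol$kkt_residual
    w <- (Mv + as.numeric(crossprod(Xv, alpha * yy))) / denom
    dec0 <- as.numeric(Xv %*% w)
    eps <- 1e-8 * C
    delta <- which(alpha > eps & alpha < C - eps)
    if (length(delta) == 0L) delta <- which(alpha > eps)
    if (length(delta) == 0L) {
      delta <- seq_len(n)
      if (!warned_delta) {
        warning("no support vectors (all alpha at zero); intercept averaged over all trials",
                call. = FALSE)
        warned_delta <- TRUE
      }
    }
    b <- mean(yy[delta] - dec0[delta])
    stat_res <- sqrt(sum((denom * w - Mv -
                            as.numeric(crossprod(Xv, alpha * yy)))^2))

    W_mat <- unvec_rm(w, p, q)
    S_new_mat <- svt(rho * W_mat - unvec_rm(L_use, p, q), tau) / rho
    S_new <- vec_rm(S_new_mat)
    L_new <- L_use + rho * (S_new - w)

    primal <- sqrt(sum((S_new - w)^2))
    obj <- objective_value(Xv, yy, w, b, C, tau, lambda,
                           if (is.null(W_source)) NULL else ws, p, q)
    obj_trace <- c(obj_trace, obj)
    primal_trace <- c(primal_trace, primal)

    if (accelerated) {
      ck <- sum((L_new - L_use)^2) / rho + rho * sum((S_new - S_h)^2)
      if (ck < eta * c_prev) {
        v_new <- (1 + sqrt(1 + 4 * v_acc^2)) / 2
        mom <- (v_acc - 1) / v_new
        S_h <- S_new + mom * (S_new - S)   # S still holds the previous iterate
        L_h <- L_new + mom * (L_new - L)
        v_acc <- v_new
      } else {             # restart: fall back to unextrapolated state
        v_acc <- 1
        S_h <- S_new
        L_h <- L_new
        ck <- c_prev / eta
      }
      c_prev <- ck
    }
    S <- S_new; L <- L_new

    if (is.finite(obj_prev) &&
        primal <= tol_primal * max(1, sqrt(sum(w^2))) &&
        abs(obj - obj_prev) <= tol_obj * max(1, abs(obj_prev))) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }

  out <- list(
    W = unvec_rm(w, p, q), b = b,
    S = unvec_rm(S, p, q), Lambda = unvec_rm(L, p, q),
    alpha = alpha, support_set = delta,
    C = C, tau = tau, lambda = lambda,
    W_source = W_source, rho = rho,
    accelerated = accelerated, eta = eta,
    converged = converged, n_iter = length(obj_trace),
    objective = obj_trace[length(obj_trace)],
    objective_trace = obj_trace, primal_trace = primal_trace,
    primal_residual = primal_trace[length(primal_trace)],
    stationarity_residual = stat_res, kkt_residual = kkt,
    label_levels = data$label_levels,
    p = p, q = q, n_train = n,
    w_source_dist = if (is.null(W_source)) NA_real_ else
      frob(unvec_rm(w, p, q) - W_source)
  )
  class(out) <- "smm"
  out
}

objective_value <- function(Xv, yy, w, b, C, tau, lambda, ws, p, q) {
  hinge <- pmax(0, 1 - yy * (as.numeric(Xv %*% w) + b))
  val <- 0.5 * sum(w^2) + C * sum(hinge)
  if (tau > 0) val <- val + tau * nuclear_norm(unvec_rm(w, p, q))
  if (!is.null(ws) && lambda > 0) val <- val + lambda * sum((ws - w)^2)
  val
}

#' Objective value of the (KL-)SMM at given parameters
#'
#' Evaluates the primal objective: half squared Frobenius norm of `W`, plus
#' `tau` times its nuclear norm, plus `C` times the total hinge loss, plus
#' `lambda * ||W_source - W||_F^2` when a source matrix is given.
#'
#' @inheritParams smm
#' @param W coefficient matrix, `b` intercept.
#' @param b intercept.
#' @return a single number.
#' @export
smm_objective <- function(x, y = NULL, W, b, C = 1, tau = 0, lambda = 0,
                          W_source = NULL) {
  data <- if (inherits(x, "matrix_dataset")) x else matrix_dataset(x, y)
  if (is.null(data$y)) stop("labels required")
  W <- as_finite_matrix(W, "W")
  ws <- if (is.null(W_source)) NULL else vec_rm(as_finite_matrix(W_source, "W_source"))
  objective_value(trial_design(data), data$y, vec_rm(W), b, C, tau, lambda,
                  ws, data$p, data$q)
}

#' @export
coef.smm <- function(object, ...) object$W

#' Predict from a fitted support matrix machine
#'
#' @param object an `"smm"` fit.
#' @param newdata a [matrix_dataset()], list of matrices, or `c(p, q, N)`
#'   array.
#' @param type `"class"` for labels (original coding), `"decision"` for the
#'   raw decision values `sum(W * X) + b`. A decision value of exactly zero
#'   is assigned to the positive class.
#' @param ... unused.
#' @return a vector of length `N`.
#' @export
predict.smm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  data <- if (inherits(newdata, "matrix_dataset")) newdata
  else matrix_dataset(newdata)
  if (data$p != object$p || data$q != object$q)
    stop("trial dimensions do not match the fitted model")
  dec <- as.numeric(trial_design(data) %*% vec_rm(object$W)) + object$b
  if (type == "decision") return(dec)
  cls <- ifelse(dec >= 0, 1, -1)
  lv <- object$label_levels
  if (!is.null(lv) && length(lv) == 2L) ifelse(cls > 0, lv[1], lv[2]) else cls
}

#' @export
residuals.smm <- function(object, newdata = NULL, ...) {
  # hinge slacks on new (or training-shaped) data require the data back
  if (is.null(newdata))
    stop("training trials are not stored; pass 'newdata' with labels")
  data <- if (inherits(newdata, "matrix_dataset")) newdata
  else stop("'newdata' must be a matrix_dataset with labels")
  if (is.null(data$y)) stop("'newdata' must be labeled")
  dec <- predict(object, data, type = "decision")
  pmax(0, 1 - data$y * dec)
}

#' @export
print.smm <- function(x, ...) {
  kind <- if (x$lambda > 0) "knowledge-leverage support matrix machine"
  else "support matrix machine"
  cat(sprintf("%s (%d x %d coefficients)\n", kind, x$p, x$q))
  cat(sprintf("  C = %g, tau = %g, lambda = %g, rho = %g%s\n",
              x$C, x$tau, x$lambda, x$rho,
              if (x$accelerated) ", accelerated" else ""))
  cat(sprintf("  %d training trials, %d support vectors\n",
              x$n_train, length(x$support_set)))
  cat(sprintf("  converged: %s in %d iterations (primal residual %.2e)\n",
              x$converged, x$n_iter, x$primal_residual))
  invisible(x)
}

#' @export
summary.smm <- function(object, ...) {
  sv <- svd(object$W, nu = 0, nv = 0)$d
  rk <- sum(sv > 1e-6 * max(sv, .Machine$double.eps))
  out <- list(model = object, singular_values = sv, rank = rk)
  class(out) <- "summary.smm"
  out
}

#' @export
print.summary.smm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  objective: %.6g\n", x$model$objective))
  cat(sprintf("  numerical rank of W: %d (sigma_1 = %.4g)\n",
              x$rank, x$singular_values[1]))
  if (!is.na(x$model$w_source_dist))
    cat(sprintf("  ||W - W_source||_F = %.4g\n", x$model$w_source_dist))
  cat(sprintf("  dual KKT residual: %.2e, stationarity residual: %.2e\n",
              x$model$kkt_residual, x$model$stationarity_residual))
  invisible(x)
}

#' @export
plot.smm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$objective_trace), x$objective_trace,
                 type = "l", xlab = "ADMM iteration", ylab = "objective",
                 main = "objective trace", ...)
  sv <- svd(x$W, nu = 0, nv = 0)$d
  graphics::plot(seq_along(sv), sv, type = "h", xlab = "index",
                 ylab = "singular value", main = "spectrum of W", ...)
  invisible(x)
}

#' Serialize / restore a fitted model
#'
#' Writes a fitted `"smm"` object to a single JSON archive holding the
#' numeric arrays (`W`, and `W_source` when present) at full precision plus
#' a metadata record (intercept, hyperparameters, label coding, convergence
#' info). Arrays round-trip to better than 1e-15 relative error; metadata
#' round-trips exactly.
#'
#' @param model an `"smm"` fit.
#' @param path file path for the archive.
#' @return `write_smm` returns `path` invisibly; `read_smm` returns the
#'   restored `"smm"` object.
#' @export
write_smm <- function(model, path) {
  stopifnot(inherits(model, "smm"))
  keep <- unclass(model)
  keep$S <- NULL; keep$Lambda <- NULL
  jsonlite::write_json(keep, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_smm
#' @export
read_smm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("W", "W_source")) {
    if (!is.null(obj[[nm]])) obj[[nm]] <- as_finite_matrix(obj[[nm]], nm)
  }
  for (nm in c("alpha", "objective_trace", "primal_trace", "support_set"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.numeric(obj[[nm]])
  obj$support_set <- as.integer(obj$support_set)
  if (is.null(obj$W_source)) obj["W_source"] <- list(NULL)
  class(obj) <- "smm"
  obj
}

#' Dual QP coefficients of the (W, b) subproblem
#'
#' Builds the box-constrained dual of the smooth ADMM subproblem:
#' `K_ij = y_i y_j * sum(X_i * X_j) / (2*lambda + rho + 1)` and
#' `h_i = 1 - y_i * sum((Lambda + rho*S + 2*lambda*W_source) * X_i) /
#' (2*lambda + rho + 1)`. With `lambda = 0` the source term vanishes and the
#' plain SMM dual is obtained. `K` is positive semidefinite by construction
#' (a label-signed Gram matrix of vectorized trials).
#'
#' @param data a labeled [matrix_dataset()].
#' @param Lambda,S current multiplier and auxiliary matrices (`p x q`).
#' @param W_source source coefficient matrix or `NULL`.
#' @param lambda,rho transfer weight and ADMM penalty.
#' @param C box bound for the resulting [dual_qp()].
#' @return a [dual_qp()] object.
#' @export
build_dual_coefficients <- function(data, Lambda, S, W_source = NULL,
                                    lambda = 0, rho = 1, C = 1) {
  stopifnot(inherits(data, "matrix_dataset"))
  if (is.null(data$y)) stop("labeled data required")
  Lambda <- as_finite_matrix(Lambda, "Lambda")
  S <- as_finite_matrix(S, "S")
  if (lambda > 0 && is.null(W_source))
    stop("'W_source' is required when lambda > 0")
  if (!is.null(W_source)) {
    W_source <- as_finite_matrix(W_source, "W_source")
    if (!all(dim(W_source) == c(data$p, data$q)))
      stop("'W_source' dimensions must match the trials")
  }
  Xv <- trial_design(data)
  yy <- data$y
  denom <- 2 * lambda + rho + 1
  ws <- if (is.null(W_source)) numeric(data$p * data$q) else vec_rm(W_source)
  Mv <- vec_rm(Lambda) + rho * vec_rm(S) + 2 * lambda * ws
  K <- (tcrossprod(Xv) * tcrossprod(yy)) / denom
  Hh <- 1 - yy * as.numeric(Xv %*% Mv) / denom
  dual_qp(K, Hh, yy, C)
}

#' ADMM auxiliary update: proximal step of the nuclear-norm term
#'
#' Solves `min_S tau*||S||_* + sum(Lambda * S) + (rho/2) * ||S - W||_F^2`
#' in closed form as `svt(rho*W - Lambda, tau) / rho`.
#'
#' @param W,Lambda current coefficient and multiplier matrices.
#' @param tau nuclear-norm weight.
#' @param rho ADMM penalty.
#' @return the updated `S` matrix.
#' @export
admm_update_S <- function(W, Lambda, tau, rho = 1) {
  W <- as_finite_matrix(W, "W")
  Lambda <- as_finite_matrix(Lambda, "Lambda")
  if (rho <= 0) stop("'rho' must be positive")
  svt(rho * W - Lambda, tau) / rho
}
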