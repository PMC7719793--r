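#' Soft-margin linear SVM on vectorized trials
#'
#' Reference classifier: minimizes `0.5 * ||w||^2 + C * sum(hinge)` on
#' vector inputs via the same box-constrained dual machinery as the matrix
#' models (`K_ij = y_i y_j x_i . x_j`, `H = 1`). With matrix trials
#' flattened row-major, the decision values coincide with those of the
#' support matrix machine at `tau = 0`, `lambda = 0`.
#'
#' @param X an `N x d` numeric matrix of vector features.
#' @param y binary labels.
#' @param C positive hinge weight.
#' @param qp_tol,qp_max_iter passed to [solve_box_eq_qp()].
#' @return an object of class `"linear_svm"` with `w`, `b`, `alpha`,
#'   `support_set`, `kkt_residual` and the label coding.
#' @export
fit_linear_svm <- function(X, y, C = 1, qp_tol = 1e-8, qp_max_iter = 20000L) {
  X <- as_finite_matrix(X, "X")
  lv <- unique(y)
  if (length(lv) < 2L) stop("both classes must be present")
  if (length(lv) > 2L) stop("labels must take two values")
  if (is.numeric(y) && all(y %in% c(-1, 1))) lv <- c(1, -1)
  yy <- ifelse(y == lv[1], 1, -1)
  K <- tcrossprod(X) * tcrossprod(yy)
  sol <- solve_box_eq_qp(dual_qp(K, rep(1, nrow(X)), yy, C),
                         tol = qp_tol, max_iter = qp_max_iter)
  a <- sol$alpha
  w <- as.numeric(crossprod(X, a * yy))
  eps <- 1e-8 * C
  delta <- which(a > eps & a < C - eps)
  if (length(delta) == 0L) delta <- which(a > eps)
  if (length(delta) == 0L) delta <- seq_along(yy)
  b <- mean(yy[delta] - as.numeric(X[delta, , drop = FALSE] %*% w))
  structure(list(w = w, b = b, alpha = a, support_set = delta,
                 C = C, kkt_residual = sol$kkt_residual,
                 label_levels = lv),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  X <- as_finite_matrix(newdata, "newdata")
  dec <- as.numeric(X %*% object$w) + object$b
  if (type == "decision") return(dec)
  lv <- object$label_levels
  ifelse(dec >= 0, lv[1], lv[2])
}

#' Adaptive SVM: learn a perturbation of a fixed source decision function
#'
#' Model-parameter transfer baseline for vector inputs: the target decision
#' function is `f(x) = lam_A * f_s(x) + w . x + b`, where `f_s` is a frozen
#' source decision function and only the perturbation `(w, b)` is learned by
#' minimizing `0.5 * ||w||^2 + C * sum(hinge(y * f))`. In the dual this only
#' shifts the linear term to `h_i = 1 - lam_A * y_i * f_s(x_i)`. With
#' `lam_A = 0` the model reduces to [fit_linear_svm()]. How the scaling
#' enters the source term follows the classical perturbation formulation;
#' `lam_A` controls how much source knowledge is transferred.
#'
#' @param source_decision a function mapping an `N x d` matrix to `N`
#'   decision values (e.g. built from a source [fit_linear_svm()] model).
#' @param X,y target vector features and binary labels.
#' @param C positive hinge weight.
#' @param lam_A non-negative source scaling.
#' @param qp_tol,qp_max_iter passed to [solve_box_eq_qp()].
#' @return an object of class `"asvm"` with the perturbation `w`, `b`, the
#'   frozen `source_decision` and `lam_A`.
#' @export
fit_asvm <- function(source_decision, X, y, C = 1, lam_A = 1,
                     qp_tol = 1e-8, qp_max_iter = 20000L) {
  stopifnot(is.function(source_decision))
  X <- as_finite_matrix(X, "X")
  lv <- unique(y)
  if (length(lv) < 2L) stop("both classes must be present")
  if (length(lv) > 2L) stop("labels must take two values")
  if (is.numeric(y) && all(y %in% c(-1, 1))) lv <- c(1, -1)
  yy <- ifelse(y == lv[1], 1, -1)
  fs <- as.numeric(source_decision(X))
  if (length(fs) != nrow(X) || !all(is.finite(fs)))
    stop("'source_decision' must return one finite value per row")
  K <- tcrossprod(X) * tcrossprod(yy)
  Hh <- 1 - lam_A * yy * fs
  sol <- solve_box_eq_qp(dual_qp(K, Hh, yy, C),
                         tol = qp_tol, max_iter = qp_max_iter)
  a <- sol$alpha
  w <- as.numeric(crossprod(X, a * yy))
  eps <- 1e-8 * C
  delta <- which(a > eps & a < C - eps)
  if (length(delta) == 0L) delta <- which(a > eps)
  if (length(delta) == 0L) delta <- seq_along(yy)
  own <- as.numeric(X[delta, , drop = FALSE] %*% w)
  b <- mean(yy[delta] - lam_A * fs[delta] - own)
  structure(list(w = w, b = b, alpha = a, support_set = delta,
                 lam_A = lam_A, C = C,
                 source_decision = source_decision,
                 kkt_residual = sol$kkt_residual,
                 label_levels = lv),
            class = "asvm")
}

#' @export
predict.asvm <- function(object, newdata,
                         type = c("class", "decision"), ...) {
  type <- match.arg(type)
  X <- as_finite_matrix(newdata, "newdata")
  dec <- object$lam_A * as.numeric(object$source_decision(X)) +
    as.numeric(X %*% object$w) + object$b
  if (type == "decision") return(dec)
  lv <- object$label_levels
  ifelse(dec >= 0, lv[1], lv[2])
}
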