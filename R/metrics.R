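#' Confusion counts and derived classification metrics
#'
#' Computes TP/TN/FP/FN (positive class = +1) and the derived metrics:
#' `ACC = (TP + TN) / (TP + FN + FP + TN)`, positive predictive value
#' `PPV = TP / (TP + FP)`, sensitivity `SEN = TP / (TP + FN)` and
#' `F1 = 2 * PPV * SEN / (PPV + SEN)`. When `PPV + SEN` is zero (no true
#' positives at all) the F1 score is reported as 0 with the `f1_degenerate`
#' flag set.
#'
#' @param y_true,y_pred vectors of +/-1 labels of equal length.
#' @return an object of class `"metrics_report"`: a list with the four
#'   counts, `ACC`, `PPV`, `SEN`, `F1`, `n` and `f1_degenerate`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 1L)
    stop("'y_true' and 'y_pred' must be equal-length, non-empty")
  if (!all(y_true %in% c(-1, 1)) || !all(y_pred %in% c(-1, 1)))
    stop("labels must be -1 or +1")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fp <- sum(y_true == -1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  n <- tp + tn + fp + fn
  acc <- (tp + tn) / n
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  sen <- if (tp + fn > 0) tp / (tp + fn) else 0
  degenerate <- (ppv + sen) == 0
  f1 <- if (degenerate) 0 else 2 * ppv * sen / (ppv + sen)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, n = n,
                 ACC = acc, PPV = ppv, SEN = sen, F1 = f1,
                 f1_degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  TP %d  TN %d  FP %d  FN %d\n",
              x$n, x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("ACC %.4f  PPV %.4f  SEN %.4f  F1 %.4f%s\n",
              x$ACC, x$PPV, x$SEN, x$F1,
              if (x$f1_degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation with tie correction: the probability that a
#' randomly chosen positive trial receives a higher decision value than a
#' randomly chosen negative one, ties counting one half. Invariant under any
#' strictly increasing transform of the decision values.
#'
#' @param y_true vector of +/-1 labels; both classes must be present.
#' @param decision_values numeric decision values of equal length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(y_true, decision_values) {
  y_true <- as.numeric(y_true)
  d <- as.numeric(decision_values)
  if (length(y_true) != length(d)) stop("lengths differ")
  if (!all(y_true %in% c(-1, 1))) stop("labels must be -1 or +1")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == -1)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute AUC")
  r <- rank(d)                      # average ranks handle ties as 1/2
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Paired two-sided t-test on per-unit scores
#'
#' Thin wrapper over `stats::t.test(..., paired = TRUE)` comparing two
#' methods' scores over the same units (subjects or seeds). Zero-variance
#' differences make the statistic undefined; the result is then flagged
#' `degenerate` with `p = NA`.
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 2).
#' @return a list with `t`, `p`, `df`, `mean_diff` and `degenerate`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  a <- as.numeric(scores_a); b <- as.numeric(scores_b)
  if (length(a) != length(b) || length(a) < 2L)
    stop("scores must be equal-length with at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0)
    return(list(t = if (mean(d) == 0) 0 else NA_real_, p = NA_real_,
                df = length(d) - 1L, mean_diff = mean(d), degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Default hyperparameter grids
#'
#' The grids used for model selection: 8 values of the hinge weight `C`
#' (1e-6 ... 1e1 by decades), 16 values of the nuclear-norm weight `tau`
#' (1-2-5 ladder from 1e-5 to 1e0), and 9 values of the transfer weight
#' `lambda` (1-5 ladder from 1e-4 to 1e0).
#'
#' @return a list with `C_grid`, `tau_grid`, `lambda_grid`.
#' @export
default_grids <- function() {
  list(
    C_grid = 10^seq(-6, 1),
    tau_grid = c(1e-5, 2e-5, 5e-5, 1e-4, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3,
                 1e-2, 2e-2, 5e-2, 1e-1, 2e-1, 5e-1, 1e0),
    lambda_grid = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2, 1e-1, 5e-1, 1e0)
  )
}

#' Stratified cross-validated grid search
#'
#' Exhaustive search over a `C x tau x lambda` grid by stratified k-fold
#' cross-validation on labeled matrix trials (fold count auto-reduced to the
#' smallest class count when the labeled set is tiny). The selection
#' maximizes mean CV accuracy; ties are broken toward the smallest `C`, then
#' smallest `tau`, then smallest `lambda` — the simplest model. The fold
#' assignment is a pure function of `seed`.
#'
#' @param data a labeled [matrix_dataset()].
#' @param C_grid,tau_grid,lambda_grid non-empty candidate vectors
#'   (`lambda_grid = 0` searches no transfer weight).
#' @param W_source source coefficient matrix, required if any
#'   `lambda_grid > 0`.
#' @param n_folds requested fold count (default 5).
#' @param seed integer seed fixing the folds.
#' @param ... further arguments passed to [smm()].
#' @return a list with `best` (named list `C`, `tau`, `lambda`) and
#'   `cv_table` (one row per grid point with mean CV accuracy).
#' @export
cross_validate_grid <- function(data, C_grid = default_grids()$C_grid,
                                tau_grid = default_grids()$tau_grid,
                                lambda_grid = 0, W_source = NULL,
                                n_folds = 5L, seed = 1L, ...) {
  stopifnot(inherits(data, "matrix_dataset"))
  if (is.null(data$y)) stop("labeled data required")
  stopifnot(length(C_grid) >= 1, length(tau_grid) >= 1,
            length(lambda_grid) >= 1)
  if (any(lambda_grid > 0) && is.null(W_source))
    stop("'W_source' required when the lambda grid is positive")
  folds <- stratified_folds(data$y, n_folds, seed)
  grid <- expand.grid(C = sort(C_grid), tau = sort(tau_grid),
                      lambda = sort(lambda_grid))
  # order so that which.max's first-hit tie-break prefers small C, tau, lambda
  grid <- grid[order(grid$C, grid$tau, grid$lambda), , drop = FALSE]
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fold_acc <- rep(NA_real_, max(folds))
    for (f in seq_len(max(folds))) {
      tr_idx <- which(folds != f); te_idx <- which(folds == f)
      if (length(unique(data$y[tr_idx])) < 2L) next
      tr <- matrix_dataset(data$trials[tr_idx], data$y[tr_idx])
      fit <- tryCatch(
        smm(tr, C = grid$C[g], tau = grid$tau[g], lambda = grid$lambda[g],
            W_source = if (grid$lambda[g] > 0) W_source else NULL, ...),
        error = function(e) {
          warning(sprintf("fold %d at grid row %d failed: %s",
                          f, g, conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(fit)) next
      te <- matrix_dataset(data$trials[te_idx])
      pred <- ifelse(predict(fit, te, type = "decision") >= 0, 1, -1)
      fold_acc[f] <- mean(pred == data$y[te_idx])
    }
    acc[g] <- mean(fold_acc, na.rm = TRUE)
  }
  best_row <- which.max(acc)
  list(best = list(C = grid$C[best_row], tau = grid$tau[best_row],
                   lambda = grid$lambda[best_row]),
       cv_table = cbind(grid, cv_acc = acc))
}
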