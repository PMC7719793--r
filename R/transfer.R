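#' Fit the source-subject model
#'
#' Trains a plain support matrix machine (no transfer term) on source-domain
#' trials. Only the fitted coefficient matrix `W` of the returned model is
#' consumed by the transfer step, so raw source trials never need to leave
#' the source site (model-parameter transfer preserves privacy).
#'
#' @param x,y source trials and labels (see [smm()]).
#' @param ... further arguments passed to [smm()]; `lambda` is forced to 0.
#' @return an `"smm"` fit.
#' @export
fit_source <- function(x, y = NULL, ...) {
  args <- list(...)
  args$lambda <- 0
  args$W_source <- NULL
  do.call(smm, c(list(x = x, y = y), args))
}

#' Bundle a transfer task
#'
#' @param source_model a fitted `"smm"` source model (only its `W` is used).
#' @param target_train labeled target trials available for training; the
#'   first `n_labeled` are used, mimicking a short calibration session.
#' @param target_test held-out labeled target trials for evaluation.
#' @param n_labeled number of labeled target trials to use (>= 2, both
#'   classes must be present among them); defaults to all of `target_train`.
#' @return an object of class `"transfer_task"`.
#' @export
transfer_task <- function(source_model, target_train, target_test,
                          n_labeled = target_train$n) {
  stopifnot(inherits(source_model, "smm"),
            inherits(target_train, "matrix_dataset"),
            inherits(target_test, "matrix_dataset"))
  if (source_model$p != target_train$p || source_model$q != target_train$q)
    stop("source model and target trials have mismatched dimensions")
  if (n_labeled < 2 || n_labeled > target_train$n)
    stop("'n_labeled' must be between 2 and the number of target trials")
  yy <- target_train$y[seq_len(n_labeled)]
  if (is.null(yy) || !any(yy > 0) || !any(yy < 0))
    stop("the first 'n_labeled' target trials must contain both classes")
  structure(list(source_model = source_model, target_train = target_train,
                 target_test = target_test, n_labeled = n_labeled),
            class = "transfer_task")
}

task_train_subset <- function(task) {
  idx <- seq_len(task$n_labeled)
  ds <- task$target_train
  sub <- matrix_dataset(ds$trials[idx])
  sub$y <- ds$y[idx]
  sub$label_levels <- ds$label_levels
  sub
}

#' Fit the knowledge-leverage SMM on a transfer task
#'
#' Fits the target classifier on the task's first `n_labeled` target trials
#' with the transfer penalty pulling the coefficient matrix toward the
#' source model's `W`. Behavior depends on the source only through that
#' matrix.
#'
#' @param task a [transfer_task()].
#' @param lambda transfer weight (`0` recovers the plain SMM on the labeled
#'   target trials).
#' @param ... further arguments passed to [smm()].
#' @return an `"smm"` fit; `w_source_dist` records `||W_t - W_s||_F`.
#' @export
fit_transfer <- function(task, lambda = 0.1, ...) {
  stopifnot(inherits(task, "transfer_task"))
  train <- task_train_subset(task)
  smm(train, lambda = lambda, W_source = task$source_model$W, ...)
}

#' Transfer-weight sensitivity profile
#'
#' Refits the transfer model for each value of `lambda_grid` on fixed data
#' and reports held-out accuracy and the distance of the fitted coefficient
#' matrix from the source matrix. On tasks with a moderate source-to-target
#' shift, accuracy typically rises with the transfer weight (the source
#' model compensates for the few labeled trials) and then falls (the source
#' mismatch dominates).
#'
#' @param task a [transfer_task()].
#' @param lambda_grid non-empty vector of non-negative transfer weights.
#' @param file optional CSV path; the table is written with columns
#'   `lambda, acc, w_dist`.
#' @param ... further arguments passed to [smm()].
#' @return a `data.frame` with columns `lambda`, `acc` (test accuracy) and
#'   `w_dist` (`||W_t - W_s||_F`).
#' @export
lambda_sensitivity <- function(task, lambda_grid, file = NULL, ...) {
  stopifnot(inherits(task, "transfer_task"), length(lambda_grid) >= 1)
  rows <- lapply(lambda_grid, function(lam) {
    fit <- fit_transfer(task, lambda = lam, ...)
    pred <- predict(fit, task$target_test)
    acc <- mean(pred == original_labels(task$target_test))
    data.frame(lambda = lam, acc = acc, w_dist = fit$w_source_dist)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.csv(out, file, row.names = FALSE)
  out
}

# labels of a dataset in their original coding
original_labels <- function(data) {
  lv <- data$label_levels
  if (is.null(lv) || length(lv) < 2L) return(data$y)
  ifelse(data$y > 0, lv[1], lv[2])
}

#' Select the transfer weight by cross-validation on the labeled trials
#'
#' Stratified k-fold cross-validation over `lambda_grid` on the task's
#' labeled target trials, with the fold count reduced to the smallest class
#' count when fewer than `n_folds` trials per class are available (down to
#' leave-one-out within the smaller class). Ties are broken toward the
#' smaller `lambda`.
#'
#' @param task a [transfer_task()].
#' @param lambda_grid candidate transfer weights.
#' @param n_folds requested fold count (default 5).
#' @param seed integer seed fixing the fold assignment.
#' @param ... further arguments passed to [smm()].
#' @return a list with `lambda` (selected), `cv_table` (mean CV accuracy per
#'   candidate).
#' @export
select_lambda <- function(task, lambda_grid, n_folds = 5L, seed = 1L, ...) {
  stopifnot(inherits(task, "transfer_task"))
  train <- task_train_subset(task)
  folds <- stratified_folds(train$y, n_folds, seed)
  acc <- vapply(lambda_grid, function(lam) {
    fold_acc <- vapply(seq_len(max(folds)), function(f) {
      tr_idx <- which(folds != f); te_idx <- which(folds == f)
      if (length(unique(train$y[tr_idx])) < 2L) return(NA_real_)
      tr <- matrix_dataset(train$trials[tr_idx], train$y[tr_idx])
      fit <- smm(tr, lambda = lam, W_source = task$source_model$W, ...)
      te <- matrix_dataset(train$trials[te_idx])
      mean(ifelse(predict(fit, te, type = "decision") >= 0, 1, -1) ==
             train$y[te_idx])
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  }, numeric(1))
  best <- lambda_grid[which.max(acc)]  # which.max takes the first maximum
  list(lambda = best,
       cv_table = data.frame(lambda = lambda_grid, cv_acc = acc))
}

# stratified fold labels; fold count = min(n_folds, smallest class count)
stratified_folds <- function(yy, n_folds, seed) {
  k <- max(2L, min(n_folds, min(table(yy))))
  k <- min(k, length(yy))
  folds <- integer(length(yy))
  with_seed(seed, {
    for (cls in unique(yy)) {
      idx <- which(yy == cls)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}
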