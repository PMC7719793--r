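#' Labeled matrix-form trial dataset
#'
#' Bundles `N` trials, each a `p x q` numeric feature matrix (for EEG,
#' typically spatial filters by time segments of band power), with binary
#' labels. Labels may be given in any two-valued coding; they are mapped
#' internally to +1 (first class seen) and -1, and the mapping is recorded so
#' predictions can be reported in the original coding.
#'
#' @param x a list of `p x q` numeric matrices sharing dimensions, or a
#'   3-d array of dimension `c(p, q, N)`.
#' @param y a vector of length `N` with at most two distinct values, or
#'   `NULL` for unlabeled trials.
#' @return an object of class `"matrix_dataset"`: a list with `trials`
#'   (list of matrices), `y` (+/-1 or `NULL`), `p`, `q`, `n` and
#'   `label_levels` (original codings mapped to +1, -1).
#' @export
matrix_dataset <- function(x, y = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  }
  if (!is.list(x) || length(x) == 0L)
    stop("'x' must be a non-empty list of matrices or a 3-d array")
  trials <- lapply(x, as_finite_matrix, name = "trial")
  p <- nrow(trials[[1]]); q <- ncol(trials[[1]])
  ok <- vapply(trials, function(m) nrow(m) == p && ncol(m) == q, logical(1))
  if (!all(ok)) stop("all trials must share the same dimensions")
  label_levels <- NULL
  yy <- NULL
  if (!is.null(y)) {
    if (length(y) != length(trials))
      stop("'y' must have one label per trial")
    lv <- unique(y)
    if (length(lv) > 2L) stop("labels must take at most two values")
    if (is.numeric(y) && all(y %in% c(-1, 1))) lv <- c(1, -1)
    label_levels <- lv
    yy <- ifelse(y == lv[1], 1, -1)
  }
  structure(list(trials = trials, y = yy, p = p, q = q, n = length(trials),
                 label_levels = label_levels),
            class = "matrix_dataset")
}

#' @export
print.matrix_dataset <- function(x, ...) {
  lab <- if (is.null(x$y)) "unlabeled"
  else sprintf("%d/%d in class +1/-1", sum(x$y > 0), sum(x$y < 0))
  cat(sprintf("matrix_dataset: %d trials of %d x %d (%s)\n",
              x$n, x$p, x$q, lab))
  invisible(x)
}

# N x (p*q) row-major design matrix; tr(t(W) %*% X) becomes a dot product.
trial_design <- function(data) {
  v <- vapply(data$trials, function(m) as.numeric(t(m)),
              numeric(data$p * data$q))
  if (is.matrix(v)) t(v) else matrix(v, ncol = 1L)
}

vec_rm <- function(M) as.numeric(t(M))
unvec_rm <- function(v, p, q) matrix(v, p, q, byrow = TRUE)

#' Flatten matrix trials into vectors
#'
#' Row-major flattening of each trial, the reshape applied before feeding
#' matrix features to vector-input classifiers. The flattening is invertible
#' given `(p, q)` and preserves the Frobenius inner product:
#' `sum(W * X) == sum(vectorize(W) * vectorize(X))`.
#'
#' @param data a [matrix_dataset()].
#' @return a list with `vectors` (`N x (p*q)` matrix), `labels` (+/-1 or
#'   `NULL`), and the original `p`, `q`.
#' @export
vectorize_trials <- function(data) {
  stopifnot(inherits(data, "matrix_dataset"))
  list(vectors = trial_design(data), labels = data$y, p = data$p, q = data$q)
}

#' Write / read a trial directory
#'
#' The on-disk exchange format for matrix trials: one CSV per trial
#' (`trial_0001.csv`, ... ; plain numeric grid, no header) plus a manifest
#' `labels.csv` with columns `trial_id,label`.
#'
#' @param data a [matrix_dataset()].
#' @param path directory to create/read.
#' @return `write_trial_dir` returns `path` invisibly; `read_trial_dir`
#'   returns a [matrix_dataset()].
#' @export
write_trial_dir <- function(data, path) {
  stopifnot(inherits(data, "matrix_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("trial_%04d", seq_len(data$n))
  for (i in seq_len(data$n)) {
    utils::write.table(data$trials[[i]],
                       file.path(path, paste0(ids[i], ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  lab <- if (is.null(data$y)) rep(NA, data$n) else data$y
  utils::write.csv(data.frame(trial_id = ids, label = lab),
                   file.path(path, "labels.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_dir
#' @export
read_trial_dir <- function(path) {
  man <- utils::read.csv(file.path(path, "labels.csv"),
                         stringsAsFactors = FALSE)
  trials <- lapply(man$trial_id, function(id) {
    as.matrix(utils::read.csv(file.path(path, paste0(id, ".csv")),
                              header = FALSE))
  })
  trials <- lapply(trials, function(m) {
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    m
  })
  y <- if (all(is.na(man$label))) NULL else man$label
  matrix_dataset(trials, y)
}
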