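#' Epoched multichannel EEG container
#'
#' @param data numeric array `trials x channels x samples`.
#' @param sfreq sampling rate in Hz.
#' @param window `c(t_start, t_end)` in seconds relative to the cue; the
#'   motor-imagery interval typically used is `c(0.5, 3)`.
#' @param channel_names optional character vector.
#' @return an object of class `"epoch_array"`.
#' @export
epoch_array <- function(data, sfreq, window = c(0.5, 3),
                        channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a trials x channels x samples array")
  if (!all(is.finite(data))) stop("'data' contains non-finite values")
  if (sfreq <= 0) stop("'sfreq' must be positive")
  if (length(window) != 2L || window[2] <= window[1])
    stop("'window' must be c(t_start, t_end) with t_end > t_start")
  ns <- dim(data)[3]
  expect_ns <- round((window[2] - window[1]) * sfreq)
  if (abs(ns - expect_ns) > 1)
    stop(sprintf("window of %.2f s at %g Hz implies %d samples, got %d",
                 window[2] - window[1], sfreq, expect_ns, ns))
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2]))
  structure(list(data = data, sfreq = sfreq, window = window,
                 channel_names = channel_names),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_array: %d trials x %d channels x %d samples @ %g Hz, window [%g, %g] s\n",
              d[1], d[2], d[3], x$sfreq, x$window[1], x$window[2]))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every trial and channel with a Butterworth band-pass of the given
#' design order, applied forward and backward (`signal::filtfilt`) so the
#' phase is not distorted inside the analysis window; the effective
#' amplitude attenuation is squared relative to a single pass. The 8-30 Hz
#' default covers the mu and beta rhythms dominant in motor imagery.
#'
#' @param epochs an [epoch_array()].
#' @param band `c(low, high)` edge frequencies in Hz; must satisfy
#'   `0 < low < high < sfreq / 2`.
#' @param order Butterworth design order (default 5).
#' @return a filtered [epoch_array()] of identical shape.
#' @export
bandpass_epochs <- function(epochs, band = c(8, 30), order = 5L) {
  stopifnot(inherits(epochs, "epoch_array"))
  nyq <- epochs$sfreq / 2
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= nyq)
    stop("'band' must satisfy 0 < low < high < sfreq/2")
  if (order < 1) stop("'order' must be >= 1")
  bf <- signal::butter(order, band / nyq, type = "pass")
  out <- epochs$data
  d <- dim(out)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      out[i, j, ] <- signal::filtfilt(bf, epochs$data[i, j, ])
    }
  }
  epochs$data <- out
  epochs
}

#' Common spatial pattern filters
#'
#' Learns spatial filters maximizing the variance ratio between the two
#' classes: per-trial channel covariances are trace-normalized, averaged by
#' class, shrunk slightly toward the identity, and the generalized
#' eigenproblem of (class-1 covariance, composite covariance) is solved by
#' whitening. The returned filters are the `n_filters/2` most discriminative
#' from each end of the eigenvalue spectrum (largest and smallest class-1
#' variance ratio), in eigenvalue order.
#'
#' @param epochs a band-passed [epoch_array()].
#' @param y binary labels, one per trial.
#' @param n_filters even number of filters (capped at the channel count).
#' @param shrink identity-shrinkage coefficient applied to the class
#'   covariances before the eigenproblem.
#' @return a `channels x n_filters` matrix with attribute `"eigenvalues"`.
#' @export
fit_spatial_filters <- function(epochs, y, n_filters = 6L, shrink = 1e-6) {
  stopifnot(inherits(epochs, "epoch_array"))
  d <- dim(epochs$data)
  if (length(y) != d[1]) stop("'y' must have one label per trial")
  lv <- unique(y)
  if (length(lv) != 2L) stop("both classes must be present")
  if (n_filters %% 2 != 0) stop("'n_filters' must be even")
  n_filters <- min(n_filters, d[2] - d[2] %% 2L)
  cov_of <- function(idx) {
    acc <- matrix(0, d[2], d[2])
    for (i in idx) {
      Xi <- epochs$data[i, , , drop = TRUE]
      if (is.null(dim(Xi))) Xi <- matrix(Xi, nrow = 1)
      Ci <- tcrossprod(Xi)
      acc <- acc + Ci / sum(diag(Ci))
    }
    acc / length(idx)
  }
  C1 <- cov_of(which(y == lv[1]))
  C2 <- cov_of(which(y != lv[1]))
  reg <- function(C) (1 - shrink) * C + shrink * (sum(diag(C)) / d[2]) * diag(d[2])
  C1 <- reg(C1); C2 <- reg(C2)
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  ev <- pmax(ec$values, max(ec$values) * 1e-12)
  P <- diag(1 / sqrt(ev)) %*% t(ec$vectors)     # whitening: P Cc P' = I
  Swhite <- P %*% C1 %*% t(P)
  es <- eigen((Swhite + t(Swhite)) / 2, symmetric = TRUE)
  Wfull <- t(P) %*% es$vectors                  # columns: filters, eig-sorted
  half <- n_filters / 2
  pick <- c(seq_len(half), d[2] - rev(seq_len(half)) + 1L)
  filt <- Wfull[, pick, drop = FALSE]
  attr(filt, "eigenvalues") <- es$values[pick]
  filt
}

#' Band-power feature matrices
#'
#' Projects each (already band-passed) trial onto the spatial filters,
#' splits the window into `n_windows` equal time segments, and takes the
#' per-filter, per-segment log variance. The result is one
#' `n_filters x n_windows` matrix per trial: rows carry the spatial
#' structure, columns the temporal evolution of band power — the structure
#' the matrix classifiers exploit.
#'
#' @param epochs a band-passed [epoch_array()].
#' @param filters a `channels x n_filters` matrix from
#'   [fit_spatial_filters()].
#' @param n_windows number of equal time segments (each must keep at least
#'   10 samples).
#' @param y optional labels attached to the returned dataset.
#' @param log_power take `log` of the variance (floored at 1e-12 to guard
#'   degenerate constant segments).
#' @return a [matrix_dataset()] with `p = ncol(filters)`, `q = n_windows`.
#' @export
band_power_matrix <- function(epochs, filters, n_windows = 5L, y = NULL,
                              log_power = TRUE) {
  stopifnot(inherits(epochs, "epoch_array"))
  filters <- as_finite_matrix(filters, "filters")
  d <- dim(epochs$data)
  if (nrow(filters) != d[2])
    stop("'filters' must have one row per channel")
  seg_len <- floor(d[3] / n_windows)
  if (seg_len < 10)
    stop("segments shorter than 10 samples; reduce 'n_windows'")
  starts <- (seq_len(n_windows) - 1L) * seg_len + 1L
  trials <- lapply(seq_len(d[1]), function(i) {
    Xi <- matrix(epochs$data[i, , ], nrow = d[2])
    Z <- crossprod(filters, Xi)               # n_filters x samples
    M <- vapply(seq_len(n_windows), function(s) {
      seg <- Z[, starts[s]:(starts[s] + seg_len - 1L), drop = FALSE]
      v <- apply(seg, 1, stats::var)
      if (log_power) log(pmax(v, 1e-12)) else v
    }, numeric(ncol(filters)))
    matrix(M, nrow = ncol(filters))
  })
  matrix_dataset(trials, y)
}

#' Per-entry standardization of feature matrices
#'
#' Computes entrywise mean and standard deviation over the trials of a
#' (labeled training) dataset, and applies the z-scoring to any number of
#' datasets. Statistics always come from the training partition only.
#'
#' @param train a [matrix_dataset()] supplying the statistics.
#' @return `fit_feature_scaler`: a list with `center` and `scale` matrices.
#' @export
fit_feature_scaler <- function(train) {
  stopifnot(inherits(train, "matrix_dataset"))
  arr <- simplify2array(train$trials)
  center <- apply(arr, c(1, 2), mean)
  scl <- apply(arr, c(1, 2), stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = center, scale = scl)
}

#' @rdname fit_feature_scaler
#' @param data a [matrix_dataset()] to transform.
#' @param scaler a scaler from `fit_feature_scaler`.
#' @export
apply_feature_scaler <- function(data, scaler) {
  stopifnot(inherits(data, "matrix_dataset"))
  out <- data
  out$trials <- lapply(data$trials, function(m) (m - scaler$center) / scaler$scale)
  out
}
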