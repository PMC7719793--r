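#' Ground-truth low-rank classifier pair for transfer experiments
#'
#' Builds a source coefficient matrix `W_s = A %*% t(B)` (standard-normal
#' factors, Frobenius-normalized) of the requested rank, and a target matrix
#' `W_t = normalize(W_s + shift * E)` with `E` a Frobenius-normalized random
#' matrix — a controllable stand-in for the cross-subject variation of EEG
#' patterns: `shift = 0` means source and target agree exactly, larger
#' values move the target boundary away from the source one.
#'
#' @param p,q matrix dimensions.
#' @param rank rank of the source matrix, at most `min(p, q)`.
#' @param shift non-negative perturbation magnitude (relative, since both
#'   matrices have unit Frobenius norm).
#' @param seed integer seed; output is a pure function of the arguments.
#' @return a list with `W_source`, `W_target` (both unit Frobenius norm) and
#'   `b_true = 0`.
#' @export
make_lowrank_model <- function(p, q, rank, shift = 0, seed = 1L) {
  stopifnot(p >= 1, q >= 1, rank >= 1, rank <= min(p, q), shift >= 0)
  with_seed(seed, {
    A <- matrix(stats::rnorm(p * rank), p, rank)
    B <- matrix(stats::rnorm(q * rank), q, rank)
    Ws <- A %*% t(B)
    Ws <- Ws / frob(Ws)
    E <- matrix(stats::rnorm(p * q), p, q)
    E <- E / frob(E)
    Wt <- if (shift == 0) Ws else {
      Wt <- Ws + shift * E
      Wt / frob(Wt)
    }
    list(W_source = Ws, W_target = Wt, b_true = 0)
  })
}

#' Sample a labeled matrix dataset from a ground-truth linear matrix model
#'
#' Trials are i.i.d. standard-normal `p x q` matrices; the label is the sign
#' of the true decision value `sum(W_true * X) + b_true`. Trials whose
#' decision magnitude falls below `0.1 * margin_scale * ||W_true||_F` are
#' rejected and resampled, so that tiny training sets (the 8-trial
#' calibration regime) remain learnable. Labels are then flipped
#' independently with probability `label_noise`. The sampler redraws until
#' at least two trials of each class are present.
#'
#' @param W_true true coefficient matrix.
#' @param b_true true intercept.
#' @param n number of trials (>= 2... both classes are enforced, so n >= 4
#'   is advisable at strong class imbalance).
#' @param label_noise flip probability in `[0, 0.5)`.
#' @param margin_scale positive scaling of the rejection threshold.
#' @param seed integer seed; output is a pure function of the arguments.
#' @return a labeled [matrix_dataset()].
#' @export
sample_matrix_dataset <- function(W_true, b_true = 0, n, label_noise = 0,
                                  margin_scale = 1, seed = 1L) {
  W_true <- as_finite_matrix(W_true, "W_true")
  stopifnot(n >= 2, label_noise >= 0, label_noise < 0.5, margin_scale > 0)
  p <- nrow(W_true); q <- ncol(W_true)
  thr <- 0.1 * margin_scale * frob(W_true)
  with_seed(seed, {
    draw_trial <- function(want_sign = 0) {
      repeat {
        X <- matrix(stats::rnorm(p * q), p, q)
        d <- sum(W_true * X) + b_true
        if (abs(d) >= thr && (want_sign == 0 || sign(d) == want_sign))
          return(list(X = X, y = if (d >= 0) 1 else -1))
      }
    }
    trials <- vector("list", n)
    y <- numeric(n)
    for (i in seq_len(n)) {
      tr <- draw_trial()
      trials[[i]] <- tr$X
      y[i] <- tr$y
    }
    flip <- stats::runif(n) < label_noise
    y[flip] <- -y[flip]
    # guarantee at least two trials per class: overwrite majority trials
    # (from the end) with forced minority draws
    for (cls in c(1, -1)) {
      k <- n
      while (sum(y == cls) < 2 && k >= 1) {
        if (y[k] != cls) {
          tr <- draw_trial(want_sign = cls)
          trials[[k]] <- tr$X
          y[k] <- cls
        }
        k <- k - 1
      }
    }
    ds <- matrix_dataset(trials)
    ds$y <- y
    ds$label_levels <- c(1, -1)
    ds
  })
}

#' Build a complete synthetic transfer task
#'
#' Samples a source dataset from the source ground truth, fits the source
#' support matrix machine on it, samples target train/test sets from the
#' shifted target ground truth, and packages everything as a
#' [transfer_task()]. This mirrors the cross-subject protocol where one
#' subject's model is fitted on plentiful data and another supplies only a
#' few labeled calibration trials.
#'
#' @param p,q,rank,shift,seed ground-truth parameters; see
#'   [make_lowrank_model()].
#' @param n_source,n_target_train,n_target_test dataset sizes.
#' @param label_noise,margin_scale sampling parameters; see
#'   [sample_matrix_dataset()].
#' @param n_labeled labeled target trials exposed by the task.
#' @param source_C,source_tau source-fit hyperparameters.
#' @return a [transfer_task()]; the ground-truth matrices are attached as
#'   attribute `"truth"`.
#' @export
make_transfer_task <- function(p = 6, q = 5, rank = 2, shift = 0.3,
                               n_source = 200, n_target_train = 40,
                               n_target_test = 100, n_labeled = 8,
                               label_noise = 0.05, margin_scale = 1,
                               source_C = 1, source_tau = 0.1, seed = 1L) {
  truth <- make_lowrank_model(p, q, rank, shift, seed = derive_seed(seed, 1))
  src <- sample_matrix_dataset(truth$W_source, truth$b_true, n_source,
                               label_noise, margin_scale,
                               seed = derive_seed(seed, 2))
  src_fit <- fit_source(src, C = source_C, tau = source_tau)
  tr <- sample_matrix_dataset(truth$W_target, truth$b_true, n_target_train,
                              label_noise, margin_scale,
                              seed = derive_seed(seed, 3))
  # calibration sessions present cues in balanced alternating order, so the
  # first n_labeled trials always contain both classes
  ord <- interleave_classes(tr$y)
  tr$trials <- tr$trials[ord]
  tr$y <- tr$y[ord]
  te <- sample_matrix_dataset(truth$W_target, truth$b_true, n_target_test,
                              label_noise, margin_scale,
                              seed = derive_seed(seed, 4))
  task <- transfer_task(src_fit, tr, te, n_labeled = n_labeled)
  attr(task, "truth") <- truth
  task
}

# alternate indices of the two classes (+1 first), leftovers appended
interleave_classes <- function(y) {
  pos <- which(y > 0); neg <- which(y < 0)
  k <- min(length(pos), length(neg))
  head <- as.vector(rbind(pos[seq_len(k)], neg[seq_len(k)]))
  c(head, setdiff(seq_along(y), head))
}

#' Synthetic motor-imagery EEG with a planted ERD effect
#'
#' Generates band-limited noise sources mixed into channels by a random
#' (per-call, seed-fixed) mixing matrix. In class +1 trials the variance of
#' the first source is attenuated by `effect_size` — an event-related
#' desynchronization (ERD)-like band-power decrease that a CSP + band-power
#' front-end should recover. `effect_size = 1` plants no effect (classes are
#' then indistinguishable); smaller values give stronger attenuation.
#'
#' @param n_trials number of trials (labels are balanced, order shuffled).
#' @param channels number of channels (equals the number of latent sources).
#' @param sfreq sampling rate in Hz.
#' @param band frequency band of the source noise, `c(low, high)` Hz.
#' @param effect_size variance attenuation factor in `(0, 1]` applied to
#'   source 1 in class +1.
#' @param window epoch window in seconds; see [epoch_array()].
#' @param seed integer seed; output is a pure function of the arguments.
#' @return a list with `epochs` (an [epoch_array()]) and `y` (labels +/-1).
#' @export
synth_eeg <- function(n_trials = 200, channels = 3, sfreq = 250,
                      band = c(8, 30), effect_size = 0.3,
                      window = c(0.5, 3), seed = 1L) {
  stopifnot(n_trials >= 2, channels >= 2, sfreq > 2 * band[2],
            effect_size > 0, effect_size <= 1)
  ns <- round((window[2] - window[1]) * sfreq)
  bf <- signal::butter(4, band / (sfreq / 2), type = "pass")
  with_seed(seed, {
    A <- matrix(stats::rnorm(channels * channels), channels, channels)
    y <- sample(rep(c(1, -1), length.out = n_trials))
    dat <- array(0, dim = c(n_trials, channels, ns))
    pad <- 3 * sfreq %/% 2
    for (i in seq_len(n_trials)) {
      S <- vapply(seq_len(channels), function(ch) {
        x <- signal::filtfilt(bf, stats::rnorm(ns + 2 * pad))
        x[(pad + 1):(pad + ns)]
      }, numeric(ns))                      # ns x channels
      S <- t(S)                            # channels x ns
      S <- S / sqrt(rowMeans(S^2))         # unit RMS sources
      if (y[i] > 0) S[1, ] <- S[1, ] * sqrt(effect_size)
      dat[i, , ] <- A %*% S
    }
    list(epochs = epoch_array(dat, sfreq, window), y = y)
  })
}
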