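#' Run a full synthetic transfer-learning experiment
#'
#' End-to-end orchestration of the evaluation protocol on synthetic transfer
#' tasks: for every seed (playing the role of a subject) and every size of
#' the labeled calibration set, fit the requested methods — vectorized
#' linear SVM, plain support matrix machine, adaptive SVM, and the
#' knowledge-leverage SMM with a cross-validation-tuned transfer weight —
#' and score them on the held-out target trials. Emits per-metric CSV tables
#' (methods by seeds, plus an `Avg.` column), a paired t-test table of the
#' transfer model against every baseline per calibration size, a
#' transfer-weight sensitivity table, and a JSON run manifest. All
#' randomness derives from `config$seed`; a rerun with the same config is
#' bit-identical.
#'
#' @param config a named list or path to a JSON file with (all optional)
#'   fields: `task` (arguments for [make_transfer_task()] minus `n_labeled`
#'   and `seed`), `methods` (subset of `"svm"`, `"smm"`, `"asvm"`,
#'   `"klsmm"`), `n_labeled` (vector, default `c(8, 14, 20)`), `n_seeds`
#'   (default 10), `seed` (master seed, default 1), `C`, `tau`, `lam_A`,
#'   `lambda_grid`.
#' @param out_dir directory for the CSV/JSON outputs.
#' @return invisibly, a list with the accuracy tables (`acc[[n_labeled]]`:
#'   methods x seeds data frames), the t-test table and the sensitivity
#'   table.
#' @export
run_experiment <- function(config = list(), out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (!is.list(config)) stop("'config' must be a list or a JSON file path")
  known <- c("task", "methods", "n_labeled", "n_seeds", "seed",
             "C", "tau", "lam_A", "lambda_grid")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  methods <- config$methods %||% c("svm", "smm", "asvm", "klsmm")
  bad_m <- setdiff(methods, c("svm", "smm", "asvm", "klsmm"))
  if (length(bad_m)) stop("unknown methods: ", paste(bad_m, collapse = ", "))
  n_labeled <- config$n_labeled %||% c(8, 14, 20)
  n_seeds <- config$n_seeds %||% 10L
  seed <- config$seed %||% 1L
  C <- config$C %||% 1
  tau <- config$tau %||% 0.1
  lam_A <- config$lam_A %||% 1
  lambda_grid <- config$lambda_grid %||% default_grids()$lambda_grid
  task_args <- config$task %||% list()

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  acc_tables <- list()
  ttest_rows <- list()
  for (nl in n_labeled) {
    acc <- matrix(NA_real_, nrow = length(methods), ncol = n_seeds,
                  dimnames = list(methods, paste0("seed", seq_len(n_seeds))))
    for (s in seq_len(n_seeds)) {
      task <- do.call(make_transfer_task,
                      c(task_args,
                        list(n_labeled = nl, seed = derive_seed(seed, s))))
      res <- evaluate_methods(task, methods, C = C, tau = tau,
                              lam_A = lam_A, lambda_grid = lambda_grid,
                              seed = derive_seed(seed, 1000 + s))
      acc[, s] <- res[methods]
    }
    df <- as.data.frame(acc)
    df$Avg. <- rowMeans(acc)
    df <- cbind(method = rownames(acc), df)
    utils::write.csv(df, file.path(out_dir, sprintf("acc_n%02d.csv", nl)),
                     row.names = FALSE)
    acc_tables[[as.character(nl)]] <- df
    if ("klsmm" %in% methods) {
      for (m in setdiff(methods, "klsmm")) {
        tt <- paired_ttest(acc["klsmm", ], acc[m, ])
        ttest_rows[[length(ttest_rows) + 1L]] <-
          data.frame(n_labeled = nl, comparison = paste0("klsmm_vs_", m),
                     t = tt$t, p = tt$p, mean_diff = tt$mean_diff)
      }
    }
  }
  ttest_table <- if (length(ttest_rows)) do.call(rbind, ttest_rows) else NULL
  if (!is.null(ttest_table))
    utils::write.csv(ttest_table, file.path(out_dir, "ttest.csv"),
                     row.names = FALSE)

  sens_task <- do.call(make_transfer_task,
                       c(task_args, list(n_labeled = n_labeled[1],
                                         seed = derive_seed(seed, 1))))
  sens <- lambda_sensitivity(sens_task, lambda_grid, C = C, tau = tau,
                             file = file.path(out_dir, "lambda_sensitivity.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("klsmm")),
    seed = seed, n_seeds = n_seeds, n_labeled = n_labeled,
    methods = methods,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(acc = acc_tables, ttest = ttest_table, sensitivity = sens))
}

# fit + score every requested method on one transfer task
evaluate_methods <- function(task, methods, C, tau, lam_A, lambda_grid,
                             seed) {
  train <- task_train_subset(task)
  test <- task$target_test
  y_te <- test$y
  out <- c(svm = NA_real_, smm = NA_real_, asvm = NA_real_,
           klsmm = NA_real_)
  Xtr <- trial_design(train); Xte <- trial_design(test)
  if ("svm" %in% methods) {
    f <- fit_linear_svm(Xtr, train$y, C = C)
    out["svm"] <- mean(sign0(predict(f, Xte, type = "decision")) == y_te)
  }
  if ("smm" %in% methods) {
    f <- smm(train, C = C, tau = tau)
    out["smm"] <- mean(sign0(predict(f, test, type = "decision")) == y_te)
  }
  if ("asvm" %in% methods) {
    ws <- vec_rm(task$source_model$W); bs <- task$source_model$b
    src_dec <- function(M) as.numeric(M %*% ws) + bs
    f <- fit_asvm(src_dec, Xtr, train$y, C = C, lam_A = lam_A)
    out["asvm"] <- mean(sign0(predict(f, Xte, type = "decision")) == y_te)
  }
  if ("klsmm" %in% methods) {
    sel <- select_lambda(task, lambda_grid, seed = seed, C = C, tau = tau)
    f <- fit_transfer(task, lambda = sel$lambda, C = C, tau = tau)
    out["klsmm"] <- mean(sign0(predict(f, test, type = "decision")) == y_te)
  }
  out[methods]
}

sign0 <- function(x) ifelse(x >= 0, 1, -1)

`%||%` <- function(a, b) if (is.null(a)) b else a
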