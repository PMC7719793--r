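test_that("transfer task validates its invariants", {
  task <- make_transfer_task(n_labeled = 8, seed = 1)
  expect_s3_class(task, "transfer_task")
  expect_error(transfer_task(task$source_model, task$target_train,
                             task$target_test, n_labeled = 1),
               "between 2")
  small <- matrix_dataset(task$target_train$trials[1:4],
                          rep(1, 4))
  expect_error(transfer_task(task$source_model, small, task$target_test,
                             n_labeled = 4), "both classes")
})

test_that("source fitting is plain SMM and rejects single-class data", {
  ds <- toy_dataset(n = 30, seed = 2, noise = 0.05)
  src <- fit_source(ds, C = 1, tau = 0.1, lambda = 5)  # lambda forced to 0
  expect_equal(src$lambda, 0)
  expect_error(fit_source(ds$trials, rep(1, 30)), "both classes")
})

test_that("self-transfer reproduces the source boundary direction", {
  ds <- toy_dataset(n = 60, p = 5, q = 5, seed = 3, noise = 0.02)
  src <- fit_source(ds, C = 1, tau = 0.1)
  task <- transfer_task(src, ds, ds, n_labeled = 60)
  fit <- fit_transfer(task, lambda = 100, C = 1, tau = 0.1)
  cosine <- sum(fit$W * src$W) / sqrt(sum(fit$W^2) * sum(src$W^2))
  expect_gt(cosine, 0.99)
})

test_that("transfer at lambda zero is the plain SMM on the labeled prefix", {
  task <- make_transfer_task(n_labeled = 8, seed = 4)
  f_tr <- fit_transfer(task, lambda = 0, C = 1, tau = 0.1)
  prefix <- matrix_dataset(task$target_train$trials[1:8],
                           task$target_train$y[1:8])
  f_plain <- smm(prefix, C = 1, tau = 0.1)
  expect_equal(f_tr$objective, f_plain$objective, tolerance = 1e-6)
})

test_that("large lambda collapses the target model onto the source", {
  task <- make_transfer_task(n_labeled = 8, seed = 5)
  fit <- fit_transfer(task, lambda = 1e8, C = 1, tau = 0.1)
  Ws <- task$source_model$W
  expect_lt(sqrt(sum((fit$W - Ws)^2)) / sqrt(sum(Ws^2)), 1e-3)
})

test_that("transfer depends on the source only through its coefficient matrix", {
  task <- make_transfer_task(n_labeled = 10, seed = 6)
  f1 <- fit_transfer(task, lambda = 0.3, C = 1, tau = 0.1)
  # scramble every source field except W: same fit, bit for bit
  garbled <- task
  garbled$source_model$alpha <- rnorm(length(task$source_model$alpha))
  garbled$source_model$b <- 99
  garbled$source_model$objective_trace <- numeric(0)
  f2 <- fit_transfer(garbled, lambda = 0.3, C = 1, tau = 0.1)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$b, f2$b)
})

test_that("lambda sensitivity table matches direct fits and writes CSV", {
  task <- make_transfer_task(n_labeled = 8, seed = 7)
  tab <- lambda_sensitivity(task, 0.1, C = 1, tau = 0.1)
  expect_equal(nrow(tab), 1L)
  direct <- fit_transfer(task, lambda = 0.1, C = 1, tau = 0.1)
  acc <- mean(predict(direct, task$target_test) == task$target_test$y)
  expect_equal(tab$acc, acc)
  expect_equal(tab$w_dist, direct$w_source_dist)

  path <- tempfile(fileext = ".csv")
  tab2 <- lambda_sensitivity(task, c(0.01, 0.1), C = 1, tau = 0.1,
                             file = path)
  expect_equal(read.csv(path), tab2, tolerance = 1e-12)
})

test_that("distance to the source is non-increasing along the lambda grid", {
  grid <- default_grids()$lambda_grid
  hits <- 0
  for (s in 1:20) {
    task <- make_transfer_task(n_labeled = 8, seed = 400 + s)
    tab <- lambda_sensitivity(task, grid, C = 1, tau = 0.1)
    hits <- hits + all(diff(tab$w_dist) <= 1e-8)
  }
  expect_gte(hits, 19)
})

test_that("with no source-target shift, trusting the source does not hurt", {
  grid <- default_grids()$lambda_grid
  hits <- 0
  prof <- matrix(NA_real_, 15, length(grid))
  for (s in 1:15) {
    task <- make_transfer_task(shift = 0, n_labeled = 8, seed = 500 + s)
    tab <- lambda_sensitivity(task, grid, C = 1, tau = 0.1)
    prof[s, ] <- tab$acc
    hits <- hits + (tab$acc[length(grid)] >= tab$acc[1])
  }
  expect_gte(hits, 14)                     # endpoint-wise, >= 90% of seeds
  mean_prof <- colMeans(prof)
  expect_true(all(diff(mean_prof) >= -0.01))  # mean profile non-decreasing
})

test_that("an uninformative source hurts at large lambda", {
  hits <- 0; diffs <- numeric(30)
  for (s in 1:30) {
    task <- make_transfer_task(shift = 0.3, n_labeled = 8, seed = 600 + s)
    truth <- attr(task, "truth")
    E <- rand_matrix(6, 5, 700 + s)
    E <- E - sum(E * truth$W_target) * truth$W_target / sum(truth$W_target^2)
    task$source_model$W <- E / sqrt(sum(E^2))   # orthogonal to the truth
    tab <- lambda_sensitivity(task, c(1e-4, 1e0), C = 1, tau = 0.1)
    diffs[s] <- tab$acc[2] - tab$acc[1]
    hits <- hits + (diffs[s] <= 0)
  }
  # the transfer weight also acts as a ridge, so an orthogonal source can
  # help by chance on single seeds; the mean effect is clearly negative
  expect_gte(hits, 15)
  expect_lt(mean(diffs), -0.01)
})

test_that("lambda selection uses stratified folds capped by class counts", {
  task <- make_transfer_task(n_labeled = 8, seed = 8)
  sel <- suppressWarnings(
    select_lambda(task, c(0.01, 0.1, 1), n_folds = 5, seed = 1,
                  C = 1, tau = 0.1))
  expect_true(sel$lambda %in% c(0.01, 0.1, 1))
  expect_equal(nrow(sel$cv_table), 3L)
  # 8 balanced trials -> smallest class has 4 -> 4 folds
  folds <- klsmm:::stratified_folds(task$target_train$y[1:8], 5, 1)
  expect_equal(max(folds), 4L)
  expect_true(all(table(folds, task$target_train$y[1:8]) == 1))
})

test_that("parameter recovery: zero-shift transfer recovers the true matrix", {
  for (s in 1:5) {
    task <- make_transfer_task(shift = 0, label_noise = 0,
                               n_target_train = 200, n_labeled = 200,
                               seed = 800 + s)
    truth <- attr(task, "truth")
    f <- fit_transfer(task, lambda = 0.1, C = 1, tau = 0.01)
    cosine <- sum(f$W * truth$W_target) /
      sqrt(sum(f$W^2) * sum(truth$W_target^2))
    expect_gt(cosine, 0.95)
  }
})
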