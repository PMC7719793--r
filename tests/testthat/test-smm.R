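test_that("dual coefficients follow the trace formulas", {
  ds <- matrix_dataset(list(matrix(2), matrix(-1)), c(1, -1))
  Z <- matrix(0, 1, 1)
  pr <- build_dual_coefficients(ds, Lambda = Z, S = Z, lambda = 0, rho = 1)
  expect_equal(unname(pr$K), 0.5 * matrix(c(4, 2, 2, 1), 2), tolerance = 1e-12)
  expect_equal(pr$H, c(1, 1))

  # with Lambda = S = 0 and lambda = 0 the linear term is all ones
  ds2 <- toy_dataset(n = 10, seed = 5)
  Z2 <- matrix(0, 4, 4)
  pr2 <- build_dual_coefficients(ds2, Z2, Z2, lambda = 0, rho = 2)
  expect_equal(pr2$H, rep(1, 10))

  # K is PSD: signed Gram of vectorized trials
  ev <- eigen(pr2$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)

  # source term enters H but not K
  Ws <- rand_matrix(4, 4, 6)
  pr3 <- build_dual_coefficients(ds2, Z2, Z2, W_source = Ws, lambda = 0.5,
                                 rho = 1)
  vd <- vectorize_trials(ds2)
  h_expect <- 1 - vd$labels * as.numeric(vd$vectors %*% as.numeric(t(Ws))) /
    (2 * 0.5 + 1 + 1)
  expect_equal(pr3$H, h_expect, tolerance = 1e-12)
  expect_error(build_dual_coefficients(ds2, Z2, Z2, lambda = 1), "W_source")
})

test_that("the auxiliary update solves its proximal subproblem", {
  W <- rand_matrix(5, 4, 61); L <- rand_matrix(5, 4, 62)
  expect_equal(admm_update_S(W, L, tau = 0, rho = 3), W - L / 3,
               tolerance = 1e-12)
  expect_equal(admm_update_S(W, matrix(0, 5, 4), tau = 0.4, rho = 1),
               svt(W, 0.4), tolerance = 1e-12)

  # optimality of min tau*||S||_* + tr(L'S) + rho/2 ||S - W||_F^2:
  # (rho*W - L - rho*S)/tau must be a nuclear-norm subgradient at S
  rho <- 2; tau <- 0.3
  S <- admm_update_S(W, L, tau, rho)
  expect_lt(nuclear_subgradient_residual(S, (rho * W - L - rho * S) / tau),
            1e-8)
  obj <- function(S) tau * nuclear_norm(S) + sum(L * S) +
    rho / 2 * sum((S - W)^2)
  set.seed(63)
  for (k in 1:50) {
    R <- matrix(rnorm(20), 5, 4); R <- R / sqrt(sum(R^2))
    expect_gte(obj(S + 1e-4 * R), obj(S) - 1e-12)
  }
})

test_that("fitting validates inputs", {
  ds <- toy_dataset(n = 10, seed = 1)
  expect_error(smm(ds$trials, rep(1, 10)), "both classes")
  expect_error(smm(ds, C = -1), "positive")
  expect_error(smm(ds, lambda = 0.1), "W_source")
  expect_error(smm(ds, lambda = 0.1, W_source = matrix(0, 2, 2)),
               "dimensions")
})

test_that("fit converges with certified residuals and a decreasing objective", {
  for (s in 1:5) {
    ds <- toy_dataset(n = 25, seed = s, noise = 0.05)
    fit <- smm(ds, C = 1, tau = 0.2)
    expect_true(fit$converged)
    expect_lte(fit$primal_residual,
               1e-4 * max(1, sqrt(sum(fit$W^2))))
    expect_lt(fit$stationarity_residual, 1e-8)
    expect_lt(fit$kkt_residual, 1e-6)
    tr <- fit$objective_trace
    if (length(tr) > 5)
      expect_true(all(diff(tr[5:length(tr)]) <=
                        1e-10 * pmax(1, abs(tr[5:(length(tr) - 1)]))))
  }
})

test_that("fitted objective is a local minimum of the primal", {
  ds <- toy_dataset(n = 20, seed = 9, noise = 0.1)
  Ws <- rand_matrix(4, 4, 91)
  fit <- smm(ds, C = 0.5, tau = 0.1, lambda = 0.2, W_source = Ws)
  f0 <- smm_objective(ds, W = fit$W, b = fit$b, C = 0.5, tau = 0.1,
                      lambda = 0.2, W_source = Ws)
  set.seed(92)
  for (k in 1:100) {
    dW <- matrix(rnorm(16, sd = 1e-3), 4, 4)
    db <- rnorm(1, sd = 1e-3)
    expect_gte(smm_objective(ds, W = fit$W + dW, b = fit$b + db, C = 0.5,
                             tau = 0.1, lambda = 0.2, W_source = Ws),
               f0 - 1e-9)
  }
})

test_that("objective closed forms hold at reference points", {
  ds <- toy_dataset(n = 12, seed = 15)
  expect_equal(smm_objective(ds, W = matrix(0, 4, 4), b = 0, C = 2),
               2 * 12)  # every hinge equals 1
  Ws <- rand_matrix(4, 4, 16)
  # C = 0, tau = 0 leaves only the Frobenius term at W = Ws
  expect_equal(smm_objective(ds, W = Ws, b = 0, C = 1e-300, tau = 0,
                             lambda = 1, W_source = Ws),
               0.5 * sum(Ws^2), tolerance = 1e-10)
})

test_that("KL-SMM at vanishing lambda equals the plain SMM", {
  ds <- toy_dataset(n = 20, seed = 17, noise = 0.05)
  f0 <- smm(ds, C = 1, tau = 0.1, lambda = 0)
  f1 <- smm(ds, C = 1, tau = 0.1, lambda = 1e-12,
            W_source = rand_matrix(4, 4, 18))
  expect_equal(f0$objective, f1$objective, tolerance = 1e-6)
})

test_that("with no nuclear penalty the fit matches a vectorized linear SVM", {
  mod <- make_lowrank_model(4, 4, 2, 0, seed = 1)
  for (s in 1:20) {
    ds <- sample_matrix_dataset(mod$W_source, 0, 30, seed = s)
    fit <- smm(ds, C = 1, tau = 0, tol_primal = 1e-7, tol_obj = 1e-12,
               max_iter = 3000)
    vd <- vectorize_trials(ds)
    ref <- fit_linear_svm(vd$vectors, vd$labels, C = 1)
    expect_lt(max(abs(predict(fit, ds, type = "decision") -
                        predict(ref, vd$vectors, type = "decision"))), 1e-4)
  }
})

test_that("large transfer weight drives the coefficients to the source", {
  ds <- toy_dataset(n = 20, seed = 23)
  Ws <- rand_matrix(4, 4, 24)
  fit <- smm(ds, C = 1, tau = 0.1, lambda = 1e8, W_source = Ws)
  expect_lt(sqrt(sum((fit$W - Ws)^2)) / sqrt(sum(Ws^2)), 1e-6)
})

test_that("nuclear penalty shrinks the rank of the coefficient matrix", {
  hits <- 0
  for (s in 1:10) {
    ds <- toy_dataset(n = 30, p = 5, q = 5, seed = 200 + s, noise = 0.05)
    rk <- function(W) {
      d <- svd(W, nu = 0, nv = 0)$d
      sum(d > 1e-6 * d[1])
    }
    r0 <- rk(smm(ds, C = 1, tau = 0)$W)
    r1 <- rk(smm(ds, C = 1, tau = 0.5)$W)
    hits <- hits + (r1 <= r0)
  }
  expect_gte(hits, 9)
})

test_that("accelerated and plain ADMM reach the same objective", {
  for (s in 1:3) {
    ds <- toy_dataset(n = 25, seed = 300 + s, noise = 0.05)
    f_plain <- smm(ds, C = 1, tau = 0.2)
    f_acc <- smm(ds, C = 1, tau = 0.2, accelerated = TRUE)
    expect_equal(f_plain$objective, f_acc$objective, tolerance = 1e-5)
  }
})

test_that("prediction implements the trace decision rule", {
  fit <- structure(list(W = matrix(0, 2, 2), b = 0.5, p = 2, q = 2,
                        label_levels = c(1, -1)), class = "smm")
  X <- list(matrix(rnorm(4), 2, 2))
  expect_equal(predict(fit, X, type = "decision"), 0.5)
  expect_equal(predict(fit, X), 1)

  # decision equals the vectorized dot product
  W <- rand_matrix(3, 2, 71)
  fit2 <- structure(list(W = W, b = -0.3, p = 3, q = 2,
                         label_levels = c(1, -1)), class = "smm")
  set.seed(72)
  for (k in 1:10) {
    X <- matrix(rnorm(6), 3, 2)
    expect_equal(predict(fit2, list(X), type = "decision"),
                 sum(W * X) - 0.3, tolerance = 1e-12)
  }
  expect_error(predict(fit2, list(matrix(0, 2, 2))), "dimensions")

  # tie at exactly zero goes to the positive class
  fit3 <- structure(list(W = matrix(0, 1, 1), b = 0, p = 1, q = 1,
                         label_levels = c("left", "right")), class = "smm")
  expect_equal(predict(fit3, list(matrix(1))), "left")
})

test_that("noiseless separable data is fit perfectly", {
  ds <- toy_dataset(n = 40, seed = 33, noise = 0)
  fit <- smm(ds, C = 10, tau = 0.01)
  expect_equal(mean(predict(fit, ds) == ds$y), 1)
})

test_that("the model archive round-trips", {
  ds <- toy_dataset(n = 15, seed = 44, noise = 0.05)
  Ws <- rand_matrix(4, 4, 45)
  fit <- smm(ds, C = 0.7, tau = 0.05, lambda = 0.3, W_source = Ws)
  path <- tempfile(fileext = ".json")
  write_smm(fit, path)
  back <- read_smm(path)
  expect_lt(max(abs(back$W - fit$W)) / max(abs(fit$W)), 1e-15)
  expect_lt(max(abs(back$W_source - Ws)) / max(abs(Ws)), 1e-15)
  expect_identical(back$C, fit$C)
  expect_identical(back$tau, fit$tau)
  expect_identical(back$lambda, fit$lambda)
  expect_identical(back$converged, fit$converged)
  expect_identical(as.numeric(back$label_levels),
                   as.numeric(fit$label_levels))
  expect_equal(back$b, fit$b, tolerance = 1e-15)
  # predictions agree through the round trip
  expect_equal(predict(back, ds, type = "decision"),
               predict(fit, ds, type = "decision"), tolerance = 1e-12)
})
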