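# shared fixtures: small deterministic problems built in code

rand_matrix <- function(p, q, seed) {
  set.seed(seed)
  matrix(rnorm(p * q), p, q)
}

# a small separable labeled dataset with known generator
toy_dataset <- function(n = 30, p = 4, q = 4, seed = 1, noise = 0,
                        W = NULL) {
  if (is.null(W)) W <- make_lowrank_model(p, q, 2, 0, seed = seed)$W_source
  sample_matrix_dataset(W, 0, n, label_noise = noise, seed = seed + 100)
}

# random PSD dual problem of size n
random_dual_qp <- function(n, C = 1, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  K <- crossprod(A) / n
  Y <- sample(c(-1, 1), n, replace = TRUE)
  if (all(Y == Y[1])) Y[1] <- -Y[1]
  dual_qp(K, rnorm(n), Y, C)
}

# brute-force feasible-point search for the dual objective
random_search_objective <- function(problem, n_points = 1000, seed = 1) {
  set.seed(seed)
  K <- problem$K; H <- problem$H; Y <- problem$Y; C <- problem$C
  n <- length(H)
  best <- -Inf
  obj <- function(a) sum(H * a) - 0.5 * sum(a * (K %*% a))
  for (k in seq_len(n_points)) {
    a <- runif(n, 0, C)
    # project onto the equality constraint, then clip back into the box
    a <- a - Y * (sum(a * Y) / n)
    a <- pmin(pmax(a, 0), C)
    # small exact correction loop for the clip
    for (rep in 1:3) {
      a <- a - Y * (sum(a * Y) / n)
      a <- pmin(pmax(a, 0), C)
    }
    if (abs(sum(a * Y)) < 1e-9 * C * n) best <- max(best, obj(a))
  }
  best <- max(best, obj(numeric(n)))  # alpha = 0 is always feasible
  best
}

# prox objective of the nuclear norm at S given input X
prox_objective <- function(S, X, tau) {
  tau * nuclear_norm(S) + 0.5 * sum((S - X)^2)
}
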