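test_that("lag pairs follow the calendar and sequential policies", {
  vals <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  rm <- toy_ratings(vals)
  rm <- mask_days(rm, 4)                      # observed days 1,2,3,5
  cal <- suppressWarnings(build_lag_pairs(rm, "calendar"))
  expect_equal(cal$pairs$predictor_day, c(1L, 2L))
  expect_equal(cal$pairs$outcome_day, c(2L, 3L))
  expect_warning(build_lag_pairs(rm, "calendar"), "lag pairs")
  seq_ <- suppressWarnings(build_lag_pairs(rm, "sequential"))
  expect_equal(seq_$pairs$predictor_day, c(1L, 2L, 3L))
  expect_equal(seq_$pairs$outcome_day, c(2L, 3L, 5L))

  full <- toy_ratings(matrix(rnorm(20), 10, 2,
                             dimnames = list(NULL, c("a", "b"))))
  expect_equal(build_lag_pairs(full, "calendar")$n_pairs, 9)
  expect_equal(build_lag_pairs(full, "sequential")$n_pairs, 9)
})

test_that("pair columns are standardized to mean 0 and unit population SD", {
  set.seed(3)
  rm <- toy_ratings(matrix(rnorm(60, 5, 3), 30, 2,
                           dimnames = list(NULL, c("a", "b"))))
  lp <- build_lag_pairs(rm)
  for (M in list(lp$X, lp$Y)) {
    expect_lt(max(abs(colMeans(M))), 1e-12)
    expect_equal(unname(sqrt(colMeans(M^2))), c(1, 1), tolerance = 1e-12)
  }
})

test_that("a gappy diary yields fewer calendar pairs than observations - 1", {
  set.seed(9)
  vals <- matrix(rnorm(122 * 3), 122, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  rm <- mask_days(toy_ratings(vals), sort(sample(2:121, 32)))
  lp <- build_lag_pairs(rm, "calendar")
  expect_lt(lp$n_pairs, 89)
  expect_gt(lp$n_pairs, 0)
})

test_that("single-predictor LASSO matches the soft-threshold closed form", {
  set.seed(1)
  n <- 80
  std <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  x <- std(rnorm(n))
  y <- std(0.6 * x + rnorm(n))
  r <- mean(x * y)                       # sample correlation
  path <- fit_node_lasso(y, matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  oracle <- sign(r) * pmax(abs(r) - path$lambdas, 0)
  expect_lt(max(abs(path$coefficients[1, ] - oracle)), 1e-8)
})

test_that("an outcome orthogonal to all predictors selects the empty model", {
  set.seed(2)
  n <- 60
  X <- scale(matrix(rnorm(n * 3), n, 3))[, ]
  colnames(X) <- c("a", "b", "c")
  y <- rnorm(n)
  y <- residuals(lm(y ~ X))              # exactly orthogonal
  path <- fit_node_lasso(as.numeric(y), X)
  expect_true(all(path$chosen == 0))
})

test_that("the small-penalty limit reproduces OLS", {
  set.seed(4)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- as.numeric(X %*% c(0.5, -0.3, 0.2, 0, 0.1) + rnorm(n, sd = 0.4))
  path <- fit_node_lasso(y, X, lambda_min_ratio = 1e-6)
  ols <- coef(lm(y ~ X))[-1]
  expect_lt(max(abs(path$coefficients[, length(path$lambdas)] - ols)), 1e-4)
})

test_that("the penalty path starts empty and sparsity decays monotonically", {
  set.seed(8)
  n <- 100
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- as.numeric(X %*% c(0.6, -0.4, 0.3, 0, 0, 0) + rnorm(n, sd = 0.5))
  path <- fit_node_lasso(y, X)
  nnz <- colSums(path$coefficients != 0)
  expect_equal(nnz[1], 0, ignore_attr = TRUE)
  expect_true(all(diff(nnz) >= -1))      # tolerance 1 for coordinate descent
})

test_that("zero-variance predictors are forced to zero with a warning", {
  set.seed(10)
  n <- 50
  X <- cbind(good = rnorm(n), flat = rep(2, n))
  y <- 0.5 * X[, 1] + rnorm(n, sd = 0.3)
  expect_warning(path <- fit_node_lasso(y, X), "zero-variance")
  expect_true(all(path$coefficients["flat", ] == 0))
})

test_that("strong 2-node VAR(1) edges are detected and spurious ones stay weak", {
  A <- matrix(c(0.6, 0.4,
                0,   0.5), 2, 2, byrow = TRUE)  # origin -> destination
  found <- 0L
  spurious_ok <- 0L
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    rm <- var_fixture(A, n_days = 301, seed = s)
    W <- estimate_network(rm)$W
    found <- found + all(W[A != 0] != 0)
    spurious_ok <- spurious_ok + all(abs(W[A == 0]) < 0.15)
  }
  expect_gte(found / n_rep, 0.95)        # true structure is always seen
  expect_gte(spurious_ok / n_rep, 0.95)  # any false edge is much weaker
  # the stiffer BIC tuning recovers the exact support in most replicates
  hits <- 0L
  for (s in seq_len(n_rep)) {
    rm <- var_fixture(A, n_days = 301, seed = s)
    W <- estimate_network(rm, criterion = "bic")$W
    hits <- hits + identical(unname(W != 0), unname(A != 0))
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("item permutation and positive rescaling leave the network consistent", {
  set.seed(21)
  A <- random_sparse_var(p = 4, n_edges = 4, strength = 0.4, seed = 21)
  rm <- var_fixture(A, n_days = 200, seed = 21)
  net <- estimate_network(rm)

  perm <- c(3, 1, 4, 2)
  rmp <- rating_matrix(rm$values[, perm], rm$dates, rm$items[perm])
  netp <- estimate_network(rmp)
  expect_equal(netp$W, net$W[perm, perm], tolerance = 1e-6)
  expect_identical(unname(netp$W != 0), unname(net$W[perm, perm] != 0))

  scl <- rm$values
  scl[, 2] <- scl[, 2] * 7.3
  nets <- estimate_network(rating_matrix(scl, rm$dates, rm$items))
  expect_equal(nets$W, net$W, tolerance = 1e-6)
})

test_that("retained edges are shrunk relative to the bivariate lag correlation", {
  # near-orthogonal design (disjoint edges, no autoregression) so that
  # partial and bivariate relations coincide up to shrinkage
  A <- matrix(0, 4, 4)
  A[1, 2] <- 0.4
  A[3, 4] <- -0.4
  rm <- var_fixture(A, n_days = 400, seed = 31)
  net <- estimate_network(rm)
  lp <- build_lag_pairs(rm)
  nz <- which(net$W != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    r <- cor(lp$X[, nz[k, 1]], lp$Y[, nz[k, 2]])
    expect_lte(abs(net$W[nz[k, 1], nz[k, 2]]), abs(r) + 0.05)
  }
})

test_that("a 22-item network spans 484 possible lag-1 relations", {
  A <- random_sparse_var(p = 22, n_edges = 20, strength = 0.3, ar = 0.2,
                         seed = 41)
  rm <- var_fixture(A, n_days = 20, seed = 41)   # fewer pairs than items + 2
  expect_warning(net <- estimate_network(rm), "lag pairs")
  expect_equal(dim(net$W), c(22L, 22L))
  expect_equal(edge_counts(net)$possible, 484)
})
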