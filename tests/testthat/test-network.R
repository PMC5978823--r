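test_that("isolation pruning removes exactly the off-diagonally empty nodes", {
  set.seed(12)
  W <- random_signed_W(22, prob = 0.2)
  iso <- c(4, 9, 16)
  W[iso, ] <- 0
  W[, iso] <- 0
  W[cbind(iso, iso)] <- 0.4            # a self-loop alone must not rescue
  # ensure the rest is connected enough not to be isolated
  keep <- setdiff(1:22, iso)
  for (k in seq_along(keep[-1])) W[keep[k], keep[k + 1]] <- 0.3
  net <- lag_network(W)
  pr <- prune_isolated_nodes(net)
  expect_setequal(pr$removed, rownames(W)[iso])
  expect_equal(length(pr$network$nodes), 19)

  full <- lag_network(matrix(0.2, 3, 3))
  expect_equal(prune_isolated_nodes(full)$removed, character(0))

  expect_error(prune_isolated_nodes(lag_network(diag(0.5, 2))),
               "isolated")
})

test_that("edge counts follow the p^2 arithmetic and are permutation invariant", {
  expect_equal(edge_counts(lag_network(matrix(0, 3, 3))),
               list(possible = 9, zeroed = 9, retained = 0L))
  expect_equal(edge_counts(lag_network(diag(c(1, 1, 1, 1)))),
               list(possible = 16, zeroed = 12, retained = 4L))
  set.seed(13)
  W <- random_signed_W(6)
  perm <- sample(6)
  expect_equal(edge_counts(lag_network(W)),
               edge_counts(lag_network(W[perm, perm])))
})

test_that("pruning then counting equals counting the surviving block", {
  set.seed(14)
  for (s in 1:5) {
    W <- random_signed_W(8, prob = 0.25)
    net <- lag_network(W)
    pr <- prune_isolated_nodes(net)
    kept <- setdiff(net$nodes, pr$removed)
    # removed nodes contribute only (possibly) self-loops, which pruning
    # rules ignore; off-diagonal retained edges must coincide
    offdiag <- function(M) { diag(M) <- 0; sum(M != 0) }
    expect_equal(offdiag(pr$network$W), offdiag(W[kept, kept]))
    expect_equal(offdiag(W[kept, kept]), offdiag(W))
  }
})

test_that("bivariate cross-check reproduces the single-predictor closed form", {
  # with one informative predictor the retained partial weight is the
  # soft-thresholded bivariate correlation, so r_bivariate >= |weight|
  A <- matrix(c(0.5, 0.6,
                0,   0.3), 2, 2, byrow = TRUE)
  rm <- var_fixture(A, n_days = 400, seed = 15)
  net <- estimate_network(rm)
  tab <- bivariate_table(rm, net)
  expect_true(all(c("origin", "destination", "partial_weight",
                    "bivariate_r", "n_pairs") %in% names(tab)))
  expect_equal(nrow(tab), sum(net$W != 0))
  lp <- build_lag_pairs(rm)
  for (k in seq_len(nrow(tab))) {
    i <- match(tab$origin[k], rm$items)
    j <- match(tab$destination[k], rm$items)
    expect_equal(tab$bivariate_r[k], cor(lp$X_raw[, i], lp$Y_raw[, j]),
                 tolerance = 1e-12)
  }
})

test_that("collinear predictors can make the bivariate exceed the partial", {
  set.seed(16)
  n <- 300
  z <- rnorm(n + 1)
  x1 <- z + rnorm(n + 1, sd = 0.2)      # two nearly identical predictors
  x2 <- z + rnorm(n + 1, sd = 0.2)
  y <- 0.8 * z[-(n + 1)] + rnorm(n, sd = 0.4)
  vals <- cbind(a = x1, b = x2, c = c(y[1], y))  # c at t reacts to z at t-1
  rm <- toy_ratings(vals)
  net <- estimate_network(rm)
  tab <- bivariate_table(rm, net)
  into_c <- tab[tab$destination == "c" & tab$origin %in% c("a", "b"), ]
  expect_gt(nrow(into_c), 0)
  expect_true(any(abs(into_c$bivariate_r) > abs(into_c$partial_weight) + 0.1))
})

test_that("an empty network yields an empty bivariate table", {
  rm <- toy_ratings(matrix(rnorm(20), 10, 2,
                           dimnames = list(NULL, c("a", "b"))))
  net <- lag_network(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b"))))
  expect_equal(nrow(bivariate_table(rm, net)), 0)
})

test_that("feedback loops are the mutual nonzero pairs with sign patterns", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W[1, 2] <- 0.3
  W[2, 1] <- -0.2
  loops <- detect_feedback_loops(lag_network(W))
  expect_equal(nrow(loops), 1)
  expect_equal(loops$signs, "(+,-)")
  expect_equal(loops$weight_ab, 0.3)

  Wu <- matrix(0, 4, 4)
  Wu[upper.tri(Wu)] <- 0.2
  expect_equal(nrow(detect_feedback_loops(lag_network(Wu))), 0)
})

test_that("GraphML export round-trips weights and signs", {
  W <- matrix(c(0.4, -0.3, 0, 0.2), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  net <- lag_network(W)
  f <- tempfile(fileext = ".graphml")
  write_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(sort(igraph::E(g)$weight), sort(W[W != 0]))
  expect_setequal(igraph::E(g)$sign, c("+", "-"))
  expect_true(all(igraph::E(g)$lag == 1))
})
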