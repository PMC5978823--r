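# two positive cliques joined by one weak edge
two_clique_W <- function(eps = 0.1) {
  W <- matrix(0, 8, 8, dimnames = list(paste0("n", 1:8), paste0("n", 1:8)))
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  W[4, 5] <- eps
  W
}

test_that("a planted two-clique split is recovered across seeds", {
  hits <- 0L
  for (s in 1:50) {
    cm <- spinglass_communities(lag_network(two_clique_W()), seed = s,
                                n_restarts = 2)
    split_ok <- length(unique(cm$membership[1:4])) == 1 &&
      length(unique(cm$membership[5:8])) == 1 &&
      cm$membership[1] != cm$membership[5]
    hits <- hits + split_ok
  }
  expect_gte(hits / 50, 0.95)
})

test_that("the annealer agrees with an independent spin-glass implementation", {
  # igraph's spin-glass community detection is the external reference on a
  # connected positive-weight planted network
  net <- lag_network(two_clique_W(0.2))
  ours <- spinglass_communities(net, seed = 2)
  g <- igraph::graph_from_adjacency_matrix((net$W + t(net$W)) / 2,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(2)
  ig <- igraph::cluster_spinglass(g, gamma = 1)
  same_partition <- function(a, b) {
    a <- as.integer(unname(a))
    b <- as.integer(unname(b))
    identical(outer(a, a, "=="), outer(b, b, "=="))
  }
  expect_true(same_partition(ours$membership, igraph::membership(ig)))
})

test_that("a uniform complete graph collapses to a single community", {
  W <- matrix(0.5, 5, 5)
  diag(W) <- 0
  cm <- spinglass_communities(lag_network(W), seed = 3)
  expect_equal(cm$n_communities, 1L)
})

test_that("the reported Hamiltonian matches its recomputation", {
  set.seed(19)
  for (s in 1:5) {
    W <- random_signed_W(7, prob = 0.4)
    net <- lag_network(W)
    cm <- spinglass_communities(net, seed = s, n_restarts = 3)
    expect_equal(cm$hamiltonian,
                 spinglass_objective(net, cm$membership,
                                     cm$gamma_pos, cm$gamma_neg),
                 tolerance = 1e-8)
    expect_equal(sort(unique(unname(cm$membership))),
                 0:(cm$n_communities - 1))   # contiguous ids from 0
  }
})

test_that("annealing is bit-reproducible for a fixed seed", {
  net <- lag_network(two_clique_W())
  a <- spinglass_communities(net, seed = 7, n_restarts = 2)
  b <- spinglass_communities(net, seed = 7, n_restarts = 2)
  expect_identical(a$membership, b$membership)
  expect_identical(a$hamiltonian, b$hamiltonian)
})

test_that("disconnected graphs are partitioned per component", {
  W <- matrix(0, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1               # node 5 is a singleton
  cm <- spinglass_communities(lag_network(W), seed = 1, n_restarts = 2)
  m <- cm$membership
  expect_equal(m[["n1"]], m[["n2"]])
  expect_equal(m[["n3"]], m[["n4"]])
  expect_true(m[["n1"]] != m[["n3"]])
  expect_true(m[["n5"]] != m[["n1"]] && m[["n5"]] != m[["n3"]])
})

test_that("modularity matches a hand-evaluated 3-node example", {
  # directed cycle with weights 0.6, 0.4, 0.2; m = 1.2
  W <- matrix(c(0, 0.6, 0,
                0, 0,   0.4,
                0.2, 0, 0), 3, 3, byrow = TRUE)
  # one community: total weight equals its own null expectation, so Q = 0
  expect_equal(signed_modularity(W, rep(0, 3)), 0, tolerance = 1e-12)
  # {1,2} vs {3}: term-by-term hand evaluation gives
  #  [(0 - .6*.2/1.2) + (.6 - .6*.6/1.2) + (0 - .4*.2/1.2)
  #   + (0 - .4*.6/1.2) + (0 - .2*.4/1.2)] / 1.2 = -0.13333/1.2
  expect_equal(signed_modularity(W, c(0, 0, 1)), -1 / 9, tolerance = 1e-12)
})

test_that("modularity is relabeling-invariant and positive on planted blocks", {
  W <- two_clique_W()
  memb <- c(rep(0, 4), rep(1, 4))
  q <- signed_modularity(W, memb)
  expect_gt(q, 0)
  expect_equal(signed_modularity(W, 1 - memb), q)
  expect_equal(signed_modularity(W, c(rep(5, 4), rep(2, 4))), q)
})

test_that("random memberships on random weights have near-zero mean Q", {
  set.seed(20)
  W <- random_signed_W(10, prob = 0.4)
  qs <- replicate(100, signed_modularity(W, sample(0:2, 10, replace = TRUE)))
  expect_lt(abs(mean(qs)), 0.05)
})

test_that("the annealed membership beats random ones on planted networks", {
  W <- two_clique_W()
  net <- lag_network(W)
  cm <- spinglass_communities(net, seed = 5, n_restarts = 2)
  k <- cm$n_communities
  set.seed(5)
  q_rand <- replicate(100, {
    m <- sample(0:(k - 1), 8, replace = TRUE)
    signed_modularity(net, m)
  })
  expect_true(all(cm$modularity >= q_rand))
})
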