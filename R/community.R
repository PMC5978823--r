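#' Spin-glass community detection on a signed network
#'
#' Partitions the nodes by minimizing the signed spin-glass Hamiltonian
#' \deqn{H = -\sum_{i<j}\big[w^+_{ij} - \gamma^+ p^+_{ij}\big]\,
#'   \delta(\sigma_i,\sigma_j)
#'   + \sum_{i<j}\big[w^-_{ij} - \gamma^- p^-_{ij}\big]\,
#'   \delta(\sigma_i,\sigma_j),}
#' where \eqn{w^\pm} are the positive/negative weight magnitudes of the
#' symmetrized network and \eqn{p^\pm_{ij} = d^\pm_i d^\pm_j / 2m^\pm} are
#' configuration-model null expectations: grouping nodes is rewarded for
#' positive weight above chance within groups and penalized for negative
#' weight above chance. Direction is collapsed as \eqn{(W + W^T)/2} since
#' the spin-glass objective is defined on undirected graphs; self-loops are
#' ignored. The minimum is sought by simulated annealing (geometric cooling
#' 1.0 to 0.01 with factor 0.99, 50 p proposals per temperature) restarted
#' `n_restarts` times, keeping the best; the search is deterministic given
#' `seed`. Disconnected graphs are partitioned per connected component.
#'
#' @param net A [lag_network()] (weights may be negative).
#' @param gamma_pos,gamma_neg Resolution parameters for the positive and
#'   negative weight classes (default 1: plain configuration null).
#' @param seed RNG seed.
#' @param n_restarts Annealing restarts (default 20).
#' @return A `community_result`: `membership` (named, ids contiguous from
#'   0), `hamiltonian` (value of H at the returned membership),
#'   `modularity` (signed directed modularity of the membership, see
#'   [signed_modularity()]), `n_communities`, plus the parameters and seed.
#' @export
spinglass_communities <- function(net, gamma_pos = 1, gamma_neg = 1,
                                  seed = 1, n_restarts = 20) {
  stopifnot(inherits(net, "lag_network"))
  p <- length(net$nodes)
  Ws <- (net$W + t(net$W)) / 2
  diag(Ws) <- 0
  membership <- rep(NA_integer_, p)
  names(membership) <- net$nodes
  set.seed(seed)
  comp <- connected_components(Ws != 0)
  offset <- 0L
  for (cc in comp) {
    if (length(cc) == 1) {
      membership[cc] <- offset
      offset <- offset + 1L
      next
    }
    M <- spinglass_coupling(Ws[cc, cc, drop = FALSE], gamma_pos, gamma_neg)
    q <- length(cc)
    res <- spinglass_anneal(M, q, n_restarts, 1.0, 0.01, 0.99,
                            50L * length(cc))
    ids <- match(res$membership, unique(res$membership)) - 1L
    membership[cc] <- ids + offset
    offset <- offset + max(ids) + 1L
  }
  h <- spinglass_objective(net, membership, gamma_pos, gamma_neg)
  structure(list(membership = membership,
                 hamiltonian = h,
                 modularity = signed_modularity(net, membership),
                 n_communities = length(unique(membership)),
                 gamma_pos = gamma_pos, gamma_neg = gamma_neg,
                 seed = seed, n_restarts = n_restarts),
            class = "community_result")
}

#' @param x A `community_result`.
#' @param ... Unused.
#' @rdname spinglass_communities
#' @export
print.community_result <- function(x, ...) {
  cat(sprintf("<community_result> %d communities, modularity %.4f, H = %.4f\n",
              x$n_communities, x$modularity, x$hamiltonian))
  invisible(x)
}

# connected components of a symmetric adjacency pattern (list of index sets)
connected_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      members <- c(members, v)
      nb <- which((adj[v, ] | adj[, v]) & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# combined coupling matrix M so that H = -sum_{i<j} M_ij delta(s_i, s_j)
spinglass_coupling <- function(Ws, gamma_pos, gamma_neg) {
  wp <- pmax(Ws, 0)
  wn <- pmax(-Ws, 0)
  null_term <- function(w, gamma) {
    tw <- sum(w)
    if (tw <= 0) return(matrix(0, nrow(w), ncol(w)))
    d <- rowSums(w)
    gamma * outer(d, d) / tw
  }
  M <- (wp - null_term(wp, gamma_pos)) - (wn - null_term(wn, gamma_neg))
  diag(M) <- 0
  M
}

#' Spin-glass objective of a given membership
#'
#' Recomputes the signed spin-glass Hamiltonian (see
#' [spinglass_communities()]) for an arbitrary membership vector, on the
#' symmetrized network.
#'
#' @param net A [lag_network()].
#' @param membership Integer community id per node.
#' @param gamma_pos,gamma_neg Resolution parameters.
#' @return The Hamiltonian value (lower is better).
#' @export
spinglass_objective <- function(net, membership, gamma_pos = 1,
                                gamma_neg = 1) {
  stopifnot(inherits(net, "lag_network"),
            length(membership) == length(net$nodes))
  Ws <- (net$W + t(net$W)) / 2
  diag(Ws) <- 0
  M <- spinglass_coupling(Ws, gamma_pos, gamma_neg)
  same <- outer(membership, membership, "==")
  -sum(M[upper.tri(M)][same[upper.tri(same)]])
}

#' Signed directed modularity
#'
#' Newman-style modularity extended to signed directed weighted graphs:
#' \deqn{Q = Q^+ - Q^-,\qquad Q^\pm = \frac{1}{m^\pm}\sum_{ij}
#'   \Big[w^\pm_{ij} - \frac{s^{\pm,out}_i s^{\pm,in}_j}{m^\pm}\Big]
#'   \delta(c_i, c_j),}
#' where \eqn{w^+} and \eqn{w^-} are the positive/negative weight
#' magnitudes, \eqn{s^{out}/s^{in}} the corresponding out-/in-strengths and
#' \eqn{m^\pm} the total weight in each class (an empty class contributes
#' 0). Positive Q means more within-community positive weight (and less
#' negative weight) than expected under a strength-preserving random null;
#' negative Q means the grouping is less cohesive than chance.
#'
#' @param net A [lag_network()] or square weight matrix.
#' @param membership Integer community id per node.
#' @return The modularity Q (dimensionless, at most 1).
#' @export
signed_modularity <- function(net, membership) {
  W <- if (inherits(net, "lag_network")) net$W else as.matrix(net)
  stopifnot(nrow(W) == ncol(W), length(membership) == nrow(W))
  same <- outer(membership, membership, "==")
  qclass <- function(w) {
    m <- sum(w)
    if (m <= 0) return(0)
    null <- outer(rowSums(w), colSums(w)) / m
    sum(((w - null) * same)) / m
  }
  qclass(pmax(W, 0)) - qclass(pmax(-W, 0))
}
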