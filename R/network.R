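#' Signed weighted directed lag-1 network
#'
#' Container for the estimated network: `W[i, j]` is the lag-1 coefficient
#' from node i at day t-1 to node j at day t (rows send, columns receive);
#' the diagonal holds the autoregressive self-loops that carry each
#' symptom's persistence.
#'
#' @param W Square numeric matrix of edge weights (0 = pruned edge).
#' @param nodes Node labels (defaults to `rownames(W)`).
#' @param provenance Optional list recording estimation settings.
#' @param node_paths Optional per-node [fit_node_lasso()] paths.
#' @return A `lag_network` object.
#' @export
lag_network <- function(W, nodes = rownames(W), provenance = list(),
                        node_paths = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (any(!is.finite(W))) stop("W must be finite")
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(W)))
  if (length(nodes) != nrow(W)) stop("nodes must match dim(W)")
  dimnames(W) <- list(nodes, nodes)
  structure(list(W = W, nodes = nodes, provenance = provenance,
                 node_paths = node_paths),
            class = "lag_network")
}

#' @param x A `lag_network`.
#' @param ... Unused.
#' @rdname lag_network
#' @export
print.lag_network <- function(x, ...) {
  ec <- edge_counts(x)
  cat(sprintf("<lag_network> %d nodes, %d of %d possible lag-1 relations retained\n",
              length(x$nodes), ec$retained, ec$possible))
  invisible(x)
}

#' Remove dynamically isolated nodes
#'
#' Drops every node whose off-diagonal row and column are entirely zero —
#' i.e. a node with no lagged relation to or from any other symptom. A
#' self-loop alone does not save a node: a symptom that only predicts
#' itself carries no information about the rest of the system. Removal is
#' iterated until stable (removing zero rows/columns cannot create new
#' isolation, but the loop makes the contract explicit).
#'
#' @param net A [lag_network()].
#' @return List with `network` (pruned) and `removed` (labels, in removal
#'   order).
#' @export
prune_isolated_nodes <- function(net) {
  stopifnot(inherits(net, "lag_network"))
  W <- net$W
  removed <- character(0)
  repeat {
    off <- W
    diag(off) <- 0
    iso <- rowSums(off != 0) == 0 & colSums(off != 0) == 0
    if (!any(iso)) break
    removed <- c(removed, rownames(W)[iso])
    W <- W[!iso, !iso, drop = FALSE]
    if (nrow(W) == 0)
      stop("all nodes are dynamically isolated (degenerate network)")
  }
  list(network = lag_network(W, rownames(W), net$provenance),
       removed = removed)
}

#' Count possible, retained and zeroed lag-1 relations
#'
#' With p nodes there are p^2 possible lag-1 relations (self-loops
#' included); regularization prunes most of them. Counts are conventionally
#' reported on the full pre-pruning node set.
#'
#' @param net A [lag_network()].
#' @return List `possible`, `zeroed`, `retained`.
#' @export
edge_counts <- function(net) {
  stopifnot(inherits(net, "lag_network"))
  possible <- length(net$nodes)^2
  retained <- sum(net$W != 0)
  list(possible = possible, zeroed = possible - retained,
       retained = retained)
}

#' Bivariate cross-check for retained edges
#'
#' For every retained edge, reports the plain Pearson lag-1 correlation of
#' the origin item at day t-1 with the destination item at day t over the
#' same pair set used for estimation. Because penalized partial weights
#' reflect unique variance only, an edge whose bivariate correlation is
#' much larger than its partial weight flags shared (multicollinear)
#' variance worth inspecting.
#'
#' @param residuals The detrended residual [rating_matrix()] that produced
#'   `net`.
#' @param net A [lag_network()] (pre- or post-pruning).
#' @param policy Lag pairing policy used for estimation.
#' @return Data frame `origin`, `destination`, `partial_weight`,
#'   `bivariate_r`, `n_pairs`; zero rows for an empty network.
#' @export
bivariate_table <- function(residuals, net, policy = "calendar") {
  stopifnot(inherits(net, "lag_network"))
  nz <- which(net$W != 0, arr.ind = TRUE)
  empty <- data.frame(origin = character(0), destination = character(0),
                      partial_weight = numeric(0), bivariate_r = numeric(0),
                      n_pairs = integer(0), stringsAsFactors = FALSE)
  if (nrow(nz) == 0) return(empty)
  lp <- build_lag_pairs(residuals, policy)
  io <- match(net$nodes, lp$items)
  if (anyNA(io)) stop("network nodes not found in residual matrix")
  out <- data.frame(
    origin = net$nodes[nz[, 1]],
    destination = net$nodes[nz[, 2]],
    partial_weight = net$W[nz],
    bivariate_r = vapply(seq_len(nrow(nz)), function(r) {
      cor(lp$X_raw[, io[nz[r, 1]]], lp$Y_raw[, io[nz[r, 2]]])
    }, numeric(1)),
    n_pairs = lp$n_pairs,
    stringsAsFactors = FALSE)
  out[order(out$origin, out$destination), , drop = FALSE]
}

#' List lag-1 feedback loops (2-cycles)
#'
#' Finds all unordered node pairs with nonzero edges in both directions —
#' i predicts j tomorrow and j predicts i tomorrow — and annotates the sign
#' pattern, e.g. `(+,-)` for a loop that amplifies in one direction and
#' dampens in the other.
#'
#' @param net A [lag_network()].
#' @return Data frame `node_a`, `node_b`, `weight_ab`, `weight_ba`,
#'   `signs`.
#' @export
detect_feedback_loops <- function(net) {
  stopifnot(inherits(net, "lag_network"))
  W <- net$W
  p <- nrow(W)
  rows <- list()
  if (p >= 2) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      if (W[i, j] != 0 && W[j, i] != 0) {
        rows[[length(rows) + 1]] <- data.frame(
          node_a = net$nodes[i], node_b = net$nodes[j],
          weight_ab = W[i, j], weight_ba = W[j, i],
          signs = sprintf("(%s,%s)", ifelse(W[i, j] > 0, "+", "-"),
                          ifelse(W[j, i] > 0, "+", "-")),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(node_a = character(0), node_b = character(0),
                      weight_ab = numeric(0), weight_ba = numeric(0),
                      signs = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Convert a lag network to an igraph graph
#'
#' Directed graph on the nonzero edges, with attributes `weight` (signed
#' coefficient), `sign`, and `lag = 1`.
#'
#' @param net A [lag_network()].
#' @param loops Keep self-loops (default `TRUE`).
#' @return An `igraph` object.
#' @export
as_igraph <- function(net, loops = TRUE) {
  stopifnot(inherits(net, "lag_network"))
  W <- net$W
  if (!loops) diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                           weighted = TRUE, diag = loops)
  igraph::E(g)$sign <- ifelse(igraph::E(g)$weight > 0, "+", "-")
  igraph::E(g)$lag <- 1
  g
}

#' Export a lag network to GraphML
#'
#' @param net A [lag_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
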