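#' Out- and in-strength centrality
#'
#' Outdegree (out-strength) of node i is the sum of absolute weights of
#' edges leaving i — how much a symptom today influences other symptoms
#' tomorrow. Indegree (in-strength) sums the absolute weights of incoming
#' edges. Self-loops are excluded: persistence is reported separately, not
#' as influence on other symptoms. Absolute values follow the weighted-
#' network convention for graphs with negative edges.
#'
#' @param net A [lag_network()], normally after pruning.
#' @return List with numeric vectors `outdegree` and `indegree`, named by
#'   node.
#' @export
strength_centrality <- function(net) {
  stopifnot(inherits(net, "lag_network"))
  A <- abs(net$W)
  diag(A) <- 0
  list(outdegree = rowSums(A), indegree = colSums(A))
}

#' Weighted directed betweenness centrality
#'
#' Counts, for each node v, the fraction of lowest-cost directed paths
#' between ordered pairs of other nodes that pass through v, with
#' fractional (Brandes) splitting over co-minimal paths. Edge traversal
#' cost is 1/|w|, so strong relations — positive or negative — make short
#' paths. Self-loops are ignored.
#'
#' @param net A [lag_network()], normally after pruning.
#' @return Numeric vector of raw betweenness scores, named by node.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "lag_network"))
  g <- as_igraph(net, loops = FALSE)
  if (igraph::ecount(g) == 0)
    return(setNames(rep(0, length(net$nodes)), net$nodes))
  b <- igraph::betweenness(g, directed = TRUE,
                           weights = 1 / abs(igraph::E(g)$weight))
  setNames(as.numeric(b), net$nodes)
}

#' Z-standardize raw centrality indices
#'
#' Standardizes each index across nodes using the sample SD (n - 1
#' denominator), the convention behind standardized centrality plots. A
#' constant column cannot be standardized and is set to zero with a
#' warning.
#'
#' @param raw Data frame or named list of raw centrality vectors.
#' @return Data frame with the raw columns plus `<name>_z` columns.
#' @export
standardize_centrality <- function(raw) {
  df <- as.data.frame(raw, stringsAsFactors = FALSE)
  if (nrow(df) < 2) stop("need at least 2 nodes to standardize")
  for (cn in names(df)) {
    s <- sd(df[[cn]])
    if (is.na(s) || s == 0) {
      warning("constant centrality column '", cn, "'; z set to 0")
      df[[paste0(cn, "_z")]] <- rep(0, nrow(df))
    } else {
      df[[paste0(cn, "_z")]] <- (df[[cn]] - mean(df[[cn]])) / s
    }
  }
  df
}

#' Full centrality table for a lag network
#'
#' Combines [strength_centrality()] and [betweenness_centrality()] and
#' z-standardizes each index across the network's nodes.
#'
#' @param net A [lag_network()], normally after pruning.
#' @return Data frame with columns `node`, `outdegree_raw`, `indegree_raw`,
#'   `betweenness_raw` and the corresponding `_z` columns.
#' @export
centrality_table <- function(net) {
  s <- strength_centrality(net)
  b <- betweenness_centrality(net)
  raw <- data.frame(outdegree = s$outdegree, indegree = s$indegree,
                    betweenness = b)
  out <- standardize_centrality(raw)
  names(out)[1:3] <- paste0(names(raw), "_raw")
  cbind(data.frame(node = net$nodes, stringsAsFactors = FALSE), out,
        row.names = NULL)
}
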