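#' Force-directed layout and drawing metadata for a lag network
#'
#' Computes a Fruchterman-Reingold layout using `|w|` as attraction weight
#' (strongly related nodes gravitate to the center) plus the edge drawing
#' attributes used by [plot.lag_network()]: color green for positive and
#' red for negative weights, width proportional to `|w|`, arrows following
#' edge direction. Deterministic given `seed`. Returned as plain data
#' frames so plots can be tested structurally rather than by pixels.
#'
#' @param net A [lag_network()].
#' @param seed Layout seed.
#' @return List with `nodes` (`node`, `x`, `y`) and `edges` (`origin`,
#'   `destination`, `weight`, `sign`, `color`, `width`, `curved`).
#' @export
network_layout <- function(net, seed = 1) {
  stopifnot(inherits(net, "lag_network"))
  g <- as_igraph(net)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, weights = abs(igraph::E(g)$weight))
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  list(nodes = data.frame(node = net$nodes, x = xy[, 1], y = xy[, 2],
                          stringsAsFactors = FALSE),
       edges = data.frame(origin = el[, 1], destination = el[, 2],
                          weight = w,
                          sign = ifelse(w > 0, "+", "-"),
                          color = ifelse(w > 0, "forestgreen", "firebrick"),
                          width = 1 + 6 * abs(w) / max(abs(w)),
                          curved = el[, 1] == el[, 2],
                          stringsAsFactors = FALSE))
}

#' Plot a lag network
#'
#' Draws the signed directed network with a force-directed layout: green
#' arrows for positive lag-1 relations, red for negative, width
#' proportional to strength, self-loops as loops.
#'
#' @param x A [lag_network()].
#' @param seed Layout seed.
#' @param vertex_size Node disc size.
#' @param ... Passed to `plot.igraph`.
#' @return The [network_layout()] metadata, invisibly.
#' @export
plot.lag_network <- function(x, seed = 1, vertex_size = 18, ...) {
  meta <- network_layout(x, seed = seed)
  g <- as_igraph(x)
  plot(g,
       layout = as.matrix(meta$nodes[c("x", "y")]),
       edge.color = meta$edges$color,
       edge.width = meta$edges$width,
       edge.arrow.size = 0.5,
       edge.curved = ifelse(meta$edges$curved, 0.8, 0.15),
       vertex.size = vertex_size,
       vertex.color = "grey92", vertex.frame.color = "grey40",
       vertex.label.color = "black", vertex.label.cex = 0.7, ...)
  invisible(meta)
}

#' Plot a fitted intraindividual network
#'
#' `type = "network"` draws the pruned lag-1 network (see
#' [plot.lag_network()]); `type = "centrality"` draws the three-panel
#' standardized centrality profile (outdegree, indegree, betweenness; one
#' row per node, z-score on the x-axis).
#'
#' @param x An `idna` fit.
#' @param type `"network"` or `"centrality"`.
#' @param seed Layout seed for the network plot.
#' @param ... Passed on to the underlying plot.
#' @return Layout metadata (network) or the centrality table
#'   (centrality), invisibly.
#' @export
plot.idna <- function(x, type = c("network", "centrality"), seed = 1, ...) {
  type <- match.arg(type)
  if (type == "network") return(plot.lag_network(x$pruned, seed = seed, ...))
  ct <- x$centrality
  if (is.null(ct)) stop("no centrality table (fewer than 2 retained nodes)")
  ord <- order(ct$node, decreasing = TRUE)
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 7, 2, 1))
  on.exit(graphics::par(old))
  panels <- c(outdegree_z = "Outdegree", indegree_z = "Indegree",
              betweenness_z = "Betweenness")
  for (cn in names(panels)) {
    graphics::plot(ct[[cn]][ord], seq_along(ord), yaxt = "n",
                   xlab = "z-score", ylab = "", main = panels[[cn]],
                   pch = 19, ...)
    graphics::abline(v = 0, lty = 3)
    graphics::axis(2, at = seq_along(ord), labels = ct$node[ord], las = 1,
                   cex.axis = 0.7)
  }
  invisible(ct)
}

#' Write a fitted network as a result bundle directory
#'
#' Exports every stage of an `idna` fit as plain-text files: the Table-1
#' style `detrend_report.csv`; the full `adjacency.csv` (rows = origin,
#' columns = destination, 0 = pruned) and `edges.csv`
#' (origin,destination,weight,lag); `centrality.csv`; `bivariate.csv`;
#' `communities.json`; `network.graphml`; `layout.csv` (plot metadata);
#' and `result.json` with counts, removed nodes, persistence, feedback
#' loops and all settings. Content is deterministic given the fit (no
#' timestamps), so re-running a seeded pipeline reproduces the bundle
#' byte for byte.
#'
#' @param fit An `idna` fit.
#' @param dir Output directory (created if needed).
#' @param layout_seed Seed for the exported layout.
#' @return `dir`, invisibly.
#' @export
write_idna_bundle <- function(fit, dir, layout_seed = 1) {
  stopifnot(inherits(fit, "idna"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  wcsv <- function(d, f) write.csv(d, fp(f), row.names = FALSE, quote = FALSE)

  wcsv(fit$detrend$report, "detrend_report.csv")
  adj <- data.frame(origin = rownames(fit$network$W), fit$network$W,
                    check.names = FALSE, stringsAsFactors = FALSE)
  wcsv(adj, "adjacency.csv")
  nz <- which(fit$network$W != 0, arr.ind = TRUE)
  edges <- data.frame(origin = fit$network$nodes[nz[, 1]],
                      destination = fit$network$nodes[nz[, 2]],
                      weight = fit$network$W[nz], lag = 1L,
                      stringsAsFactors = FALSE)
  wcsv(edges[order(edges$origin, edges$destination), ], "edges.csv")
  if (!is.null(fit$centrality)) wcsv(fit$centrality, "centrality.csv")
  wcsv(fit$bivariate, "bivariate.csv")
  if (!is.null(fit$community)) {
    comm <- fit$community
    jsonlite::write_json(
      list(membership = as.list(comm$membership),
           modularity = comm$modularity, hamiltonian = comm$hamiltonian,
           n_communities = comm$n_communities,
           gamma_pos = comm$gamma_pos, gamma_neg = comm$gamma_neg,
           seed = comm$seed, n_restarts = comm$n_restarts),
      fp("communities.json"), auto_unbox = TRUE, digits = NA)
  }
  write_graphml(fit$pruned, fp("network.graphml"))
  meta <- network_layout(fit$pruned, seed = layout_seed)
  wcsv(cbind(kind = "node", meta$nodes[1], round(meta$nodes[-1], 10)),
       "layout_nodes.csv")
  wcsv(meta$edges, "layout_edges.csv")
  jsonlite::write_json(
    list(counts = fit$counts, removed = fit$removed,
         persistence = fit$persistence, feedback_loops = fit$loops,
         settings = fit$settings),
    fp("result.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
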