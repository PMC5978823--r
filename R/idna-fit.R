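#' Fit an intraindividual dynamic network to daily ratings
#'
#' End-to-end estimation of a person-specific lag-1 symptom network from
#' one individual's daily multivariate ratings:
#' \enumerate{
#'   \item each item is polynomially detrended in week-time with the order
#'     chosen by corrected AIC ([detrend_all()]);
#'   \item day-to-day lag pairs are built from fully rated consecutive
#'     days and standardized ([build_lag_pairs()]);
#'   \item each symptom at day t is regressed on all symptoms (itself
#'     included) at day t-1 with the LASSO, the penalty tuned by corrected
#'     AIC ([estimate_network()]);
#'   \item dynamically isolated nodes are pruned
#'     ([prune_isolated_nodes()]); edge counts are reported on the full
#'     node set ([edge_counts()]);
#'   \item standardized strength and betweenness centralities
#'     ([centrality_table()]), signed spin-glass communities with
#'     modularity ([spinglass_communities()]), bivariate cross-checks
#'     ([bivariate_table()]), persistence (large autoregressive
#'     self-loops) and 2-cycle feedback loops
#'     ([detect_feedback_loops()]) are computed on the pruned network.
#' }
#'
#' @param data A wide data frame (date column plus one numeric column per
#'   item) or a [rating_matrix()].
#' @param date_col Name of the date column when `data` is a data frame.
#' @param max_order Highest polynomial detrending order (default 10).
#' @param policy Lag pairing policy: `"calendar"` (strict
#'   yesterday-to-today, default) or `"sequential"`.
#' @param lambda_grid_size,lambda_min_ratio LASSO penalty grid, see
#'   [fit_node_lasso()].
#' @param persistence_threshold Minimum `|self-loop|` for a symptom to be
#'   reported as persistent (default 0.3).
#' @param community Run community detection (default `TRUE`).
#' @param gamma_pos,gamma_neg,n_restarts Spin-glass parameters, see
#'   [spinglass_communities()].
#' @param seed Seed for the community search.
#'
#' @return An object of class `idna` with components `ratings`, `detrend`
#'   (report + per-item results), `residuals` (detrended
#'   [rating_matrix()]), `network` (the full p-node [lag_network()]),
#'   `pruned`, `removed`, `counts`, `centrality`,
#'   `community`, `bivariate`, `persistence`, `loops`, `settings`, `call`.
#'   Methods: [print.idna()], [summary.idna()], [coef.idna()],
#'   [residuals.idna()], [predict.idna()], [simulate.idna()],
#'   [plot.idna()].
#' @examples
#' A <- random_sparse_var(p = 4, n_edges = 4, strength = 0.4, seed = 2)
#' rm <- simulate_ratings(synthetic_spec(A, n_days = 150, seed = 2))
#' fit <- idna(rm, seed = 2)
#' fit
#' coef(fit)[1:4, 1:4]
#' @export
idna <- function(data, date_col = "date", max_order = 10,
                 policy = c("calendar", "sequential"),
                 lambda_grid_size = 100, lambda_min_ratio = 1e-3,
                 persistence_threshold = 0.3, community = TRUE,
                 gamma_pos = 1, gamma_neg = 1, n_restarts = 20, seed = 1) {
  policy <- match.arg(policy)
  rm <- as_rating_matrix(data, date_col)
  det <- detrend_all(rm, max_order = max_order)
  net <- estimate_network(det$residuals, policy = policy,
                          lambda_grid_size = lambda_grid_size,
                          lambda_min_ratio = lambda_min_ratio)
  counts <- edge_counts(net)
  pr <- prune_isolated_nodes(net)
  cent <- if (length(pr$network$nodes) >= 2) centrality_table(pr$network)
          else NULL
  comm <- if (community && length(pr$network$nodes) >= 2)
    spinglass_communities(pr$network, gamma_pos, gamma_neg,
                          seed = seed, n_restarts = n_restarts)
  else NULL
  biv <- bivariate_table(det$residuals, net, policy = policy)
  selfs <- diag(pr$network$W)
  persistence <- data.frame(node = pr$network$nodes, self_loop = selfs,
                            persistent = abs(selfs) >= persistence_threshold,
                            stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    ratings = rm,
    detrend = det[c("report", "results")],
    residuals = det$residuals,
    network = net,
    pruned = pr$network,
    removed = pr$removed,
    counts = counts,
    centrality = cent,
    community = comm,
    bivariate = biv,
    persistence = persistence,
    loops = detect_feedback_loops(pr$network),
    settings = list(max_order = max_order, policy = policy,
                    lambda_grid_size = lambda_grid_size,
                    lambda_min_ratio = lambda_min_ratio,
                    persistence_threshold = persistence_threshold,
                    gamma_pos = gamma_pos, gamma_neg = gamma_neg,
                    n_restarts = n_restarts, seed = seed),
    call = match.call()),
    class = "idna")
}

#' Print a fitted intraindividual network
#'
#' @param x An `idna` fit.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
print.idna <- function(x, ...) {
  cat("Intraindividual dynamic network (lag-1, LASSO/AICc)\n")
  cs <- coverage_summary(x$ratings)
  cat(sprintf("  data: %d items, %d observed days over a %d-day span\n",
              length(x$ratings$items), cs$observed_days, cs$span_days))
  cat(sprintf("  lag pairs: %d (%s policy)\n",
              x$network$provenance$n_pairs, x$settings$policy))
  cat(sprintf("  relations: %d of %d possible retained (%d zeroed)\n",
              x$counts$retained, x$counts$possible, x$counts$zeroed))
  if (length(x$removed))
    cat("  removed as dynamically isolated: ",
        paste(x$removed, collapse = ", "), "\n", sep = "")
  if (!is.null(x$community))
    cat(sprintf("  communities: %d (modularity %.3f)\n",
                x$community$n_communities, x$community$modularity))
  invisible(x)
}

#' Summary of a fitted intraindividual network
#'
#' @param object An `idna` fit.
#' @param n_top How many leading nodes to show per centrality index.
#' @param ... Unused.
#' @return A `summary.idna` object (list), printed with leading
#'   centralities, persistence and feedback loops.
#' @export
summary.idna <- function(object, n_top = 4, ...) {
  top <- function(col) {
    ct <- object$centrality
    if (is.null(ct)) return(NULL)
    ct <- ct[order(-ct[[col]]), c("node", col)]
    head(ct, n_top)
  }
  structure(list(fit = object,
                 top_out = top("outdegree_z"),
                 top_in = top("indegree_z"),
                 top_btw = top("betweenness_z"),
                 n_top = n_top),
            class = "summary.idna")
}

#' @param x A `summary.idna` object.
#' @rdname summary.idna
#' @export
print.summary.idna <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$top_out)) {
    cat("\nHighest standardized outdegree (influences tomorrow):\n")
    print(x$top_out, row.names = FALSE, digits = 3)
    cat("Highest standardized indegree (influenced by yesterday):\n")
    print(x$top_in, row.names = FALSE, digits = 3)
    cat("Highest standardized betweenness (on shortest lagged paths):\n")
    print(x$top_btw, row.names = FALSE, digits = 3)
  }
  pers <- x$fit$persistence
  pers <- pers[pers$persistent, ]
  if (nrow(pers)) {
    cat("\nPersistent symptoms (|self-loop| >= ",
        x$fit$settings$persistence_threshold, "):\n", sep = "")
    print(pers[c("node", "self_loop")], row.names = FALSE, digits = 3)
  }
  if (nrow(x$fit$loops)) {
    cat("\nLag-1 feedback loops:\n")
    print(x$fit$loops, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Extract the estimated adjacency matrix
#'
#' @param object An `idna` fit.
#' @param pruned Return the pruned network's matrix (default `FALSE`: the
#'   full p x p matrix, zeros included).
#' @param ... Unused.
#' @return Matrix with rows = origin (day t-1) and columns = destination
#'   (day t).
#' @export
coef.idna <- function(object, pruned = FALSE, ...) {
  if (pruned) object$pruned$W else object$network$W
}

#' Detrended residuals of a fitted intraindividual network
#'
#' @param object An `idna` fit.
#' @param ... Unused.
#' @return The day-by-item residual matrix (`NA` on unobserved days).
#' @export
residuals.idna <- function(object, ...) object$residuals$values

#' One-step-ahead predictions from the fitted network
#'
#' Predicts each symptom at day t from the standardized residuals at day
#' t-1 via the estimated coefficient matrix. With `newdata = NULL` the
#' predictions are over the training lag-pair set.
#'
#' @param object An `idna` fit.
#' @param newdata Optional matrix of standardized day t-1 residuals
#'   (columns in the fit's item order).
#' @param ... Unused.
#' @return Matrix of predicted standardized values at day t.
#' @export
predict.idna <- function(object, newdata = NULL, ...) {
  W <- object$network$W
  if (is.null(newdata)) {
    lp <- build_lag_pairs(object$residuals, object$settings$policy)
    newdata <- lp$X
  }
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == nrow(W))
  newdata %*% W
}

#' Simulate new rating series from a fitted network
#'
#' Treats the estimated coefficient matrix as the generating VAR(1) and
#' simulates new daily series with innovation SDs estimated from the
#' node-wise regression residuals — a parametric-bootstrap style check of
#' what data the fitted model implies.
#'
#' @param object An `idna` fit.
#' @param nsim Number of simulated series.
#' @param seed RNG seed.
#' @param n_days Span per series (default: the training span).
#' @param ... Unused.
#' @return A list of [rating_matrix()] objects (length `nsim`).
#' @export
simulate.idna <- function(object, nsim = 1, seed = 1, n_days = NULL, ...) {
  W <- object$network$W
  rad <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rad >= 1) stop("estimated network is non-stationary (spectral radius ",
                     round(rad, 3), "); cannot simulate")
  if (is.null(n_days)) n_days <- length(object$ratings$dates)
  lp <- build_lag_pairs(object$residuals, object$settings$policy)
  resid_sd <- vapply(seq_along(object$network$nodes), function(j) {
    pred <- lp$X %*% W[, j]
    stats::sd(lp$Y[, j] - pred)
  }, numeric(1))
  lapply(seq_len(nsim), function(i) {
    simulate_ratings(synthetic_spec(W, n_days = n_days,
                                    noise_sd = resid_sd,
                                    items = object$network$nodes,
                                    seed = seed + i - 1))
  })
}
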