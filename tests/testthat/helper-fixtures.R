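# Shared fixtures and independent oracles, all built in code.

# small rating matrix with explicit dates/values
toy_ratings <- function(values, start = "2020-01-01",
                        items = colnames(values)) {
  values <- as.matrix(values)
  rating_matrix(values, as.Date(start) + seq_len(nrow(values)) - 1, items)
}

# mask whole days of a fully observed matrix (1-based day positions)
mask_days <- function(rm, days) {
  v <- rm$values
  v[days, ] <- NA_real_
  rating_matrix(v, rm$dates, rm$items)
}

# exhaustive simple-path betweenness oracle (small graphs only):
# cost 1/|w|, fractional counting over co-minimal paths, self-loops ignored
brute_betweenness <- function(W, tol = 1e-9) {
  p <- nrow(W)
  C <- 1 / abs(W)
  C[W == 0] <- Inf
  diag(C) <- Inf
  btw <- setNames(rep(0, p), rownames(W))
  for (s in seq_len(p)) for (t in seq_len(p)) {
    if (s == t) next
    paths <- list()
    rec <- function(v, visited, cost, path) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(cost = cost, path = path)
        return(invisible())
      }
      for (u in seq_len(p)) {
        if (!visited[u] && is.finite(C[v, u]))
          rec(u, replace(visited, u, TRUE), cost + C[v, u], c(path, u))
      }
    }
    rec(s, replace(rep(FALSE, p), s, TRUE), 0, s)
    if (!length(paths)) next
    costs <- vapply(paths, `[[`, numeric(1), "cost")
    minimal <- paths[costs <= min(costs) + tol]
    sigma <- length(minimal)
    for (pp in minimal) {
      for (v in setdiff(pp$path, c(s, t)))
        btw[v] <- btw[v] + 1 / sigma
    }
  }
  btw
}

# random signed weight matrix over a small alphabet
random_signed_W <- function(p, prob = 0.4,
                            alphabet = c(-1, -0.5, -0.2, 0.2, 0.5, 1)) {
  W <- matrix(0, p, p, dimnames = list(paste0("n", 1:p), paste0("n", 1:p)))
  off <- which(row(W) != col(W))
  on <- off[runif(length(off)) < prob]
  W[on] <- sample(alphabet, length(on), replace = TRUE)
  W
}

# fully observed VAR(1) fixture with known A
var_fixture <- function(A, n_days, seed, noise_sd = 1) {
  simulate_ratings(synthetic_spec(A, n_days = n_days, noise_sd = noise_sd,
                                  seed = seed))
}
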