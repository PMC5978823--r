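#' Specify a synthetic intraindividual VAR(1) process
#'
#' Defines the ground-truth generative model the estimation pipeline
#' assumes: a stationary lag-1 vector autoregression around a (possibly
#' polynomial) mean trend, with Gaussian innovations and whole days missing
#' at random — the structure of a daily symptom diary with skipped days.
#'
#' @param A p x p lag-1 coefficient matrix in origin-to-destination
#'   orientation (`A[i, j]` = lagged effect of item i on item j, matching
#'   the estimated `W`); spectral radius must be < 1.
#' @param n_days Calendar span to simulate.
#' @param trend Optional list of per-item polynomial coefficient vectors in
#'   week-time (`c(intercept, linear, quadratic, ...)`); `NULL` means no
#'   trend.
#' @param noise_sd Innovation SD per item (recycled to p).
#' @param missing_prob Probability that a whole day is unrated (i.i.d.
#'   Bernoulli across days); must be in [0, 1).
#' @param gap_length If > 1, missing days are drawn as blocks of this
#'   length (stresses calendar pairing); default 1.
#' @param items Item labels.
#' @param seed RNG seed; `simulate_ratings()` is bit-reproducible given the
#'   spec.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(A, n_days, trend = NULL, noise_sd = 1,
                           missing_prob = 0, gap_length = 1,
                           items = NULL, seed = 1) {
  A <- as.matrix(A)
  p <- nrow(A)
  stopifnot(ncol(A) == p, n_days >= 2)
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1)
    stop("A must have spectral radius < 1 (stationarity)")
  if (missing_prob < 0 || missing_prob >= 1)
    stop("missing_prob must be in [0, 1)")
  noise_sd <- rep_len(noise_sd, p)
  stopifnot(all(noise_sd >= 0))
  if (is.null(items)) items <- paste0("item", seq_len(p))
  if (!is.null(trend)) {
    stopifnot(is.list(trend), length(trend) == p)
  }
  structure(list(p = p, A = A, n_days = as.integer(n_days), trend = trend,
                 noise_sd = noise_sd, missing_prob = missing_prob,
                 gap_length = as.integer(gap_length), items = items,
                 seed = seed),
            class = "synthetic_spec")
}

# evaluate per-item trend at week-times w; returns n x p matrix
eval_trend <- function(spec, w) {
  mu <- matrix(0, length(w), spec$p)
  if (is.null(spec$trend)) return(mu)
  for (j in seq_len(spec$p)) {
    co <- spec$trend[[j]]
    if (length(co)) mu[, j] <- outer(w, seq_along(co) - 1, "^") %*% co
  }
  mu
}

#' Simulate daily ratings from a synthetic specification
#'
#' Generates
#' \deqn{y_t = \mu(t) + A^\top (y_{t-1} - \mu(t-1)) + \epsilon_t,\qquad
#'   \epsilon_t \sim N(0, \mathrm{diag}(\sigma^2)),}
#' (the transpose because `A[i, j]` is stored origin-to-destination, like
#' the estimated network) with week-time trend \eqn{\mu}, after discarding
#' a 100-step burn-in so
#' the centered process starts at stationarity. The trend is injected on
#' the mean (added outside the recursion), so the ground-truth `A` is
#' unaffected by it and detrending plus estimation can be validated
#' jointly. Whole days are then masked at random.
#'
#' @param spec A [synthetic_spec()].
#' @param start_date First calendar date (default `"2000-01-01"`).
#' @return A [rating_matrix()] with attribute `"truth"` holding `spec$A`.
#' @export
simulate_ratings <- function(spec, start_date = as.Date("2000-01-01")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  p <- spec$p
  burn <- 100L
  n <- spec$n_days
  eps <- matrix(rnorm((burn + n) * p), burn + n, p) *
    rep(spec$noise_sd, each = burn + n)
  z <- matrix(0, burn + n, p)
  for (t in 2:(burn + n))   # A is origin -> destination, hence crossprod
    z[t, ] <- as.numeric(crossprod(spec$A, z[t - 1, ])) + eps[t, ]
  z <- z[burn + seq_len(n), , drop = FALSE]
  w <- (seq_len(n) - 1) / 7
  y <- z + eval_trend(spec, w)
  # whole-day missingness
  if (spec$missing_prob > 0) {
    if (spec$gap_length <= 1) {
      miss <- runif(n) < spec$missing_prob
    } else {
      starts <- runif(n) < spec$missing_prob / spec$gap_length
      miss <- rep(FALSE, n)
      for (s in which(starts))
        miss[s:min(n, s + spec$gap_length - 1)] <- TRUE
    }
    # keep the series usable: never mask everything
    if (sum(!miss) < 2) miss[seq_len(2)] <- FALSE
    y[miss, ] <- NA_real_
  }
  rm <- rating_matrix(y, start_date + (seq_len(n) - 1), spec$items)
  attr(rm, "truth") <- spec$A
  rm
}

#' Support-recovery metrics against a known coefficient matrix
#'
#' Compares an estimated lag-1 matrix with the generating one:
#' sensitivity and specificity of the off-diagonal support (is each true
#' edge found, is each true zero kept at zero), the fraction of true
#' nonzero entries recovered with the correct sign, and the RMSE of the
#' estimates over the true support.
#'
#' @param true_A Ground-truth p x p matrix.
#' @param estimated_W Estimated p x p matrix (same node order).
#' @return List `sensitivity`, `specificity`, `sign_accuracy`,
#'   `rmse_on_support`. Metrics that are undefined for the given truth
#'   (e.g. sensitivity with no true edges) are `NaN`.
#' @export
recovery_metrics <- function(true_A, estimated_W) {
  true_A <- as.matrix(true_A)
  estimated_W <- if (inherits(estimated_W, "lag_network")) estimated_W$W
                 else as.matrix(estimated_W)
  if (!all(dim(true_A) == dim(estimated_W)))
    stop("shape mismatch between true_A and estimated_W")
  off <- row(true_A) != col(true_A)
  ts_ <- true_A != 0
  es <- estimated_W != 0
  sens <- sum(es & ts_ & off) / sum(ts_ & off)
  spec <- sum(!es & !ts_ & off) / sum(!ts_ & off)
  sign_acc <- if (any(ts_)) sum(sign(estimated_W[ts_]) == sign(true_A[ts_])) / sum(ts_)
              else NaN
  rmse <- if (any(ts_)) sqrt(mean((estimated_W[ts_] - true_A[ts_])^2)) else NaN
  list(sensitivity = sens, specificity = spec, sign_accuracy = sign_acc,
       rmse_on_support = rmse)
}

#' Random sparse stable VAR(1) coefficient matrix
#'
#' Convenience generator for simulation studies: plants `n_edges` nonzero
#' off-diagonal coefficients of magnitude `strength` (random signs) plus
#' autoregressive diagonals, then rescales if needed to keep the spectral
#' radius below `radius_cap`.
#'
#' @param p Number of items.
#' @param n_edges Number of nonzero off-diagonal entries.
#' @param strength Absolute value of planted off-diagonal coefficients.
#' @param ar Diagonal (autoregressive) coefficient, recycled.
#' @param radius_cap Upper bound for the spectral radius (default 0.95).
#' @param seed RNG seed.
#' @return A p x p matrix.
#' @export
random_sparse_var <- function(p, n_edges, strength = 0.4, ar = 0.3,
                              radius_cap = 0.95, seed = 1) {
  set.seed(seed)
  A <- diag(rep_len(ar, p))
  off <- which(row(A) != col(A))
  stopifnot(n_edges <= length(off))
  idx <- sample(off, n_edges)
  A[idx] <- strength * sample(c(-1, 1), n_edges, replace = TRUE)
  rad <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rad >= radius_cap) A <- A * (radius_cap / rad)
  dimnames(A) <- list(paste0("item", seq_len(p)), paste0("item", seq_len(p)))
  A
}
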