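#' Build the lag-1 pair set from detrended residuals
#'
#' Assembles the predictor/outcome design for node-wise lagged regression.
#' A day counts as observed only when every item was rated (daily
#' questionnaires are completed or skipped as a unit); under the default
#' `calendar` policy day d is paired with day d+1 only when both are
#' observed, so every pair is a true yesterday-to-today transition. The
#' `sequential` policy pairs consecutive observations regardless of the gap
#' between them and is intended for sensitivity analysis only.
#'
#' Predictor and outcome columns are z-standardized per item over the pair
#' set (mean 0, SD 1 with the 1/n denominator), which puts all edge weights
#' on a common partial-correlation-like scale.
#'
#' @param residuals A [rating_matrix()] of detrended residuals.
#' @param policy `"calendar"` or `"sequential"`.
#' @param complete_days If `TRUE` (default) a day with any missing item is
#'   treated as wholly missing; if `FALSE` a day is usable when all items
#'   happen to be observed anyway (per-cell masks only matter for days that
#'   are partially rated).
#' @return A `lag_pairs` object: `X` (pairs x items, day t-1), `Y` (pairs x
#'   items, day t), `pairs` (day indices), `n_pairs`, `items`, plus the raw
#'   (unstandardized) `X_raw`, `Y_raw` used for bivariate cross-checks.
#' @export
build_lag_pairs <- function(residuals, policy = c("calendar", "sequential"),
                            complete_days = TRUE) {
  policy <- match.arg(policy)
  stopifnot(inherits(residuals, "rating_matrix"))
  p_items <- ncol(residuals$values)
  vals <- residuals$values
  if (complete_days) {
    obs_day <- rowSums(residuals$observed) == p_items
  } else {
    # per-cell mode: a partially rated day stays usable; unrated cells are
    # set to the item mean (0 for detrended residuals)
    obs_day <- rowSums(residuals$observed) > 0
    vals[is.na(vals) & obs_day] <- 0
  }
  days <- which(obs_day)
  if (policy == "calendar") {
    pred <- days[(days + 1) %in% days]
    out <- pred + 1L
  } else {
    if (length(days) < 2) stop("no lag pairs available")
    pred <- days[-length(days)]
    out <- days[-1]
  }
  if (length(pred) == 0) stop("no lag pairs available under policy '",
                              policy, "'")
  p <- ncol(residuals$values)
  if (length(pred) < p + 2)
    warning(sprintf("only %d lag pairs for %d items; estimates rely heavily on regularization",
                    length(pred), p))
  X_raw <- vals[pred, , drop = FALSE]
  Y_raw <- vals[out, , drop = FALSE]
  structure(list(X = scale_pop(X_raw), Y = scale_pop(Y_raw),
                 X_raw = X_raw, Y_raw = Y_raw,
                 pairs = data.frame(predictor_day = pred, outcome_day = out),
                 n_pairs = length(pred), items = residuals$items,
                 policy = policy),
            class = "lag_pairs")
}

# z-standardize columns with population (1/n) SD; zero-variance columns
# become all-zero and are flagged in attr "zero_var"
scale_pop <- function(M) {
  mu <- colMeans(M)
  sdev <- sqrt(colMeans(sweep(M, 2, mu)^2))
  zv <- sdev <= 0
  sdev[zv] <- 1
  Z <- sweep(sweep(M, 2, mu), 2, sdev, "/")
  Z[, zv] <- 0
  attr(Z, "zero_var") <- zv
  Z
}

#' Fit one node's L1-penalized lagged regression path
#'
#' Solves, for a single outcome,
#' \deqn{\min_\beta \|y - X\beta\|^2/(2n) + \lambda\|\beta\|_1}
#' over a log-spaced grid of 100 penalties from \eqn{\lambda_{max}} (the
#' smallest penalty with an all-zero solution) down to
#' \eqn{10^{-3}\lambda_{max}}, and selects the penalty minimizing the
#' corrected AIC with degrees of freedom equal to the number of nonzero
#' coefficients (the standard LASSO df estimate). The fit itself is done by
#' coordinate descent via \pkg{glmnet}; the intercept is unpenalized and
#' discarded.
#'
#' @param y Standardized outcome vector.
#' @param X Standardized predictor matrix (no missing entries).
#' @param lambda_grid_size Number of grid points (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of
#'   \eqn{\lambda_{max}} (default 1e-3).
#' @param criterion Penalty-selection criterion: `"aicc"` (default; the
#'   liberal choice that matches intensive single-subject practice) or
#'   `"bic"` for a sparser network.
#' @return A `lasso_path`: `lambdas`, `coefficients` (predictors x
#'   penalties, intercept excluded), `criterion_values`, `chosen_index`,
#'   and `chosen` (the selected coefficient vector).
#' @export
fit_node_lasso <- function(y, X, lambda_grid_size = 100,
                           lambda_min_ratio = 1e-3,
                           criterion = c("aicc", "bic")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, !anyNA(y), !anyNA(X))
  p <- ncol(X)
  sds <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  zv <- sds <= 0
  if (any(zv)) {
    warning("zero-variance predictor(s) forced to zero: ",
            paste(colnames(X)[zv], collapse = ", "))
    X[, zv] <- 0
  }
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  if (!is.finite(lambda_max) || lambda_max <= 0) {
    # outcome carries no linear signal: empty model at a token penalty
    co <- matrix(0, p, 1, dimnames = list(colnames(X), NULL))
    return(structure(list(lambdas = 1, coefficients = co,
                          criterion_values =
                            ic_gaussian(sum((y - mean(y))^2), n, 0, criterion),
                          chosen_index = 1L, chosen = co[, 1]),
                     class = "lasso_path"))
  }
  # start a hair above lambda_max so the first solution is exactly empty
  lambdas <- exp(seq(log(lambda_max * (1 + 1e-6)),
                     log(lambda_max * lambda_min_ratio),
                     length.out = lambda_grid_size))
  Xfit <- if (p == 1) cbind(X, pad__ = 0) else X  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(Xfit, y, family = "gaussian", alpha = 1,
                        lambda = lambdas, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12, maxit = 1e7)
  beta <- as.matrix(fit$beta)[seq_len(p), , drop = FALSE]  # p x nlambda
  rownames(beta) <- colnames(X)
  a0 <- fit$a0
  used <- fit$lambda                     # glmnet may stop early; align
  pred <- sweep(X %*% beta, 2, a0, "+")
  rss <- colSums((y - pred)^2)
  k <- colSums(beta != 0)
  vals <- mapply(ic_gaussian, rss, k = k,
                 MoreArgs = list(n = n, criterion = criterion))
  chosen <- which.min(vals)
  structure(list(lambdas = used, coefficients = beta,
                 criterion_values = vals, chosen_index = chosen,
                 chosen = beta[, chosen]),
            class = "lasso_path")
}

# information criterion for a Gaussian fit with k estimated coefficients
# (LASSO df estimate: the nonzero count)
ic_gaussian <- function(rss, n, k, criterion = "aicc") {
  rss <- max(rss, n * .Machine$double.xmin)
  if (n - k - 1 <= 0) return(Inf)
  dev <- n * log(rss / n)
  if (criterion == "bic") dev + k * log(n)
  else dev + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Estimate the regularized lag-1 network
#'
#' Runs [fit_node_lasso()] once per item, with all p items at day t-1
#' (including the outcome itself, capturing autoregression as a self-loop)
#' predicting that item at day t, and assembles the p x p signed weighted
#' adjacency matrix W with `W[i, j]` the selected standardized coefficient
#' of predictor i for outcome j. Because X and y are standardized, the
#' weights are on a partial-correlation-like scale and comparable across
#' edges.
#'
#' @param residuals A detrended residual [rating_matrix()].
#' @param policy Lag pairing policy, see [build_lag_pairs()].
#' @param criterion Penalty-selection criterion, see [fit_node_lasso()].
#' @param lambda_grid_size,lambda_min_ratio Penalty grid, see
#'   [fit_node_lasso()].
#' @return A [lag_network()] object.
#' @export
estimate_network <- function(residuals, policy = c("calendar", "sequential"),
                             criterion = c("aicc", "bic"),
                             lambda_grid_size = 100, lambda_min_ratio = 1e-3) {
  policy <- match.arg(policy)
  criterion <- match.arg(criterion)
  stopifnot(inherits(residuals, "rating_matrix"))
  p <- length(residuals$items)
  if (p < 2) stop("need at least 2 items to estimate a network")
  lp <- build_lag_pairs(residuals, policy)
  W <- matrix(0, p, p, dimnames = list(residuals$items, residuals$items))
  node_paths <- vector("list", p)
  for (j in seq_len(p)) {
    path <- tryCatch(
      fit_node_lasso(lp$Y[, j], lp$X, lambda_grid_size, lambda_min_ratio,
                     criterion),
      error = function(e) stop(sprintf("outcome item '%s': %s",
                                       residuals$items[j],
                                       conditionMessage(e)), call. = FALSE))
    W[, j] <- path$chosen
    node_paths[[j]] <- path
  }
  lag_network(W, residuals$items,
              provenance = list(policy = policy, n_pairs = lp$n_pairs,
                                criterion = criterion,
                                lambda_grid_size = lambda_grid_size,
                                lambda_min_ratio = lambda_min_ratio),
              node_paths = node_paths)
}
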