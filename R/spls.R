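#' Center (and optionally unit-scale) predictors and response
#'
#' Prepares a predictor matrix and response vector for sparse partial least
#' squares: every predictor column is mean-centered and, by default, divided
#' by its sample standard deviation; the response is centered. Columns with
#' zero sample variance carry no information and cannot be standardized, so
#' they are mapped to all-zero columns and flagged as degenerate — a flagged
#' column can never enter an active set downstream.
#'
#' @param X numeric matrix, observations in rows and predictors (genes) in
#'   columns. All entries must be finite and there must be at least two rows.
#' @param y numeric response vector, one value per row of `X`.
#' @param scale logical; divide each predictor column by its standard
#'   deviation (default `TRUE`). The response is centered but never scaled.
#' @return A list of class `"spls_data"` with elements `X` (standardized
#'   matrix), `y` (centered response), `col_means`, `col_scales`, `y_mean`,
#'   and `degenerate` (logical, `TRUE` for zero-variance columns).
#' @examples
#' d <- standardize_xy(matrix(rnorm(20), 10, 2), rnorm(10))
#' colMeans(d$X) # ~ 0
#' @export
standardize_xy <- function(X, y, scale = TRUE) {
  X <- as.matrix(X)
  if (!is.numeric(X) || !is.numeric(y)) {
    stop_input("`X` and `y` must be numeric.")
  }
  if (nrow(X) < 2L) {
    stop_input("At least 2 observations are required to standardize.")
  }
  if (length(y) != nrow(X)) {
    stop_input("Length of `y` must match the number of rows of `X`.")
  }
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_input("Non-finite entries found in `X` or `y`.")
  }
  col_means <- colMeans(X)
  Xc <- sweep(X, 2L, col_means, "-")
  sds <- apply(Xc, 2L, sd)
  degenerate <- sds == 0
  col_scales <- rep(1, ncol(X))
  if (scale) {
    col_scales[!degenerate] <- sds[!degenerate]
    Xc[, !degenerate] <- sweep(Xc[, !degenerate, drop = FALSE], 2L,
                               sds[!degenerate], "/")
  }
  # zero-variance columns are exactly zero after centering already; make sure
  Xc[, degenerate] <- 0
  y_mean <- mean(y)
  structure(
    list(X = Xc, y = y - y_mean, col_means = col_means,
         col_scales = col_scales, y_mean = y_mean, degenerate = degenerate),
    class = "spls_data"
  )
}

#' Sparse direction vector by fraction-of-maximum soft-thresholding
#'
#' The sparsity primitive of SPLS: given the covariance-direction vector
#' `z = X'y`, entries whose magnitude falls below a fraction `lambda` of the
#' largest magnitude are zeroed, and surviving entries are soft-shrunk by the
#' same threshold. The comparison is inclusive (`>=`), so the argmax always
#' survives and the support is never empty for a nonzero `z`; larger `lambda`
#' selects fewer variables.
#'
#' @param z numeric vector, not all zero.
#' @param lambda sparsity parameter in (0, 1): the threshold is
#'   `lambda * max(abs(z))`.
#' @return Numeric vector `w` of the same length,
#'   `w_j = sign(z_j) (|z_j| - lambda * max|z|)` where `|z_j|` meets the
#'   threshold and 0 elsewhere, with an integer attribute `"support"` holding
#'   the indices that meet the threshold.
#' @examples
#' sparse_direction(c(4, 1, -2), lambda = 0.4) # support 1 and 3
#' @export
sparse_direction <- function(z, lambda) {
  if (!is.numeric(z) || length(z) < 1L) stop_input("`z` must be numeric.")
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      lambda <= 0 || lambda >= 1) {
    stop_config("`lambda` must be a single value in (0, 1).")
  }
  az <- abs(z)
  zmax <- max(az)
  if (zmax == 0) {
    abort("All entries of `z` are zero: no direction can be extracted.",
          class = "splsnet_degenerate_direction")
  }
  thr <- lambda * zmax
  keep <- az >= thr
  w <- numeric(length(z))
  w[keep] <- sign(z[keep]) * (az[keep] - thr)
  attr(w, "support") <- which(keep)
  w
}

# plain PLS1 (NIPALS) on an already-standardized predictor block
# returns weights W (d x K), scores T (M x K), loadings P (d x K), q (K),
# and the coefficient vector beta = W (P'W)^-1 q
pls1 <- function(X, y, K) {
  d <- ncol(X)
  M <- nrow(X)
  W <- matrix(0, d, K)
  P <- matrix(0, d, K)
  Tm <- matrix(0, M, K)
  q <- numeric(K)
  E <- X
  f <- y
  for (k in seq_len(K)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw == 0) {
      # response residual orthogonal to the block: stop extracting
      W <- W[, seq_len(k - 1L), drop = FALSE]
      P <- P[, seq_len(k - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(k - 1L), drop = FALSE]
      q <- q[seq_len(k - 1L)]
      break
    }
    w <- w / nw
    t_k <- drop(E %*% w)
    tt <- sum(t_k^2)
    p_k <- drop(crossprod(E, t_k)) / tt
    q_k <- sum(f * t_k) / tt
    W[, k] <- w
    P[, k] <- p_k
    Tm[, k] <- t_k
    q[k] <- q_k
    E <- E - tcrossprod(t_k, p_k)
    f <- f - t_k * q_k
  }
  beta <- if (ncol(W) == 0L) numeric(d) else {
    drop(W %*% solve(crossprod(P, W), q))
  }
  list(W = W, P = P, T_scores = Tm, q = q, beta = beta)
}

#' Sparse partial least squares regression with one response
#'
#' Fits an SPLS model by iterative selection and refit: at each component the
#' covariance direction `z = X'y` is computed on the current predictor
#' residual, [sparse_direction()] selects the surviving variables, the active
#' set grows by those variables, an ordinary PLS1 model with the current
#' number of components is refit on the active predictors only, and the full
#' predictor block is deflated by the fitted score. With `K = 1` (the
#' default throughout network inference here) the active set is exactly the
#' fraction-of-maximum threshold support of `X'y`.
#'
#' @param data an `"spls_data"` object from [standardize_xy()].
#' @param K number of latent components, `K <= min(M - 1, D)`.
#' @param lambda sparsity parameter in (0, 1).
#' @return An object of class `"spls_fit"`: `active` (sorted indices of
#'   selected predictors), `W` (D x K direction matrix, zero rows off the
#'   active set), `T_scores` (M x K), `P_load` (D x K), `q_load` (length K),
#'   `beta` (length-D coefficients on the standardized scale, zero off the
#'   active set), `lambda`, `K`, and `empty` (`TRUE` when no direction could
#'   be extracted at the first component).
#' @examples
#' d <- standardize_xy(matrix(rnorm(60), 20, 3), rnorm(20))
#' fit <- spls_fit(d, K = 1, lambda = 0.5)
#' fit$active
#' @export
spls_fit <- function(data, K = 1L, lambda = 0.5) {
  if (!inherits(data, "spls_data")) {
    stop_input("`data` must come from standardize_xy().")
  }
  M <- nrow(data$X)
  D <- ncol(data$X)
  K <- as.integer(K)
  if (K < 1L || K > min(M - 1L, D)) {
    stop_config("`K` must satisfy 1 <= K <= min(M - 1, D).")
  }
  empty_fit <- function() {
    structure(
      list(active = integer(0), W = matrix(0, D, 0),
           T_scores = matrix(0, M, 0), P_load = matrix(0, D, 0),
           q_load = numeric(0), beta = numeric(D), lambda = lambda, K = K,
           empty = TRUE),
      class = "spls_fit"
    )
  }
  active <- integer(0)
  X1 <- data$X
  refit <- NULL
  for (k in seq_len(K)) {
    z <- drop(crossprod(X1, data$y))
    z[data$degenerate] <- 0
    if (max(abs(z)) == 0) {
      if (k == 1L) return(empty_fit())
      break
    }
    w <- sparse_direction(z, lambda)
    active <- sort(union(active, attr(w, "support")))
    refit <- pls1(data$X[, active, drop = FALSE], data$y, k)
    # deflate the full block by the fitted scores so the next direction is
    # computed on the predictor residual (the response is not deflated here)
    Tm <- refit$T_scores
    X1 <- data$X
    for (j in seq_len(ncol(Tm))) {
      t_j <- Tm[, j]
      p_full <- drop(crossprod(X1, t_j)) / sum(t_j^2)
      X1 <- X1 - tcrossprod(t_j, p_full)
    }
  }
  kk <- ncol(refit$W)
  W <- matrix(0, D, kk)
  P <- matrix(0, D, kk)
  beta <- numeric(D)
  W[active, ] <- refit$W
  P[active, ] <- refit$P
  beta[active] <- refit$beta
  structure(
    list(active = active, W = W, T_scores = refit$T_scores, P_load = P,
         q_load = refit$q, beta = beta, lambda = lambda, K = K,
         empty = FALSE),
    class = "spls_fit"
  )
}

#' @export
print.spls_fit <- function(x, ...) {
  cat("Sparse PLS fit (K = ", x$K, ", lambda = ", format(x$lambda), ")\n",
      sep = "")
  cat("  active predictors: ", length(x$active), " of ", length(x$beta),
      "\n", sep = "")
  invisible(x)
}

#' Coefficients of an SPLS fit on the original data scale
#'
#' @param object an `"spls_fit"` object.
#' @param data the `"spls_data"` object the model was fit to.
#' @param ... unused.
#' @return Named numeric vector with an `"(Intercept)"` entry followed by one
#'   coefficient per predictor (zero off the active set).
#' @export
coef.spls_fit <- function(object, data, ...) {
  b <- object$beta / data$col_scales
  intercept <- data$y_mean - sum(b * data$col_means)
  c("(Intercept)" = intercept, b)
}
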