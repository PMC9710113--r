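# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (explicit formulas, brute-force
# enumeration) and never call the code paths they check.

# explicit mean/SD standardization, column by column
oracle_standardize <- function(X, y, scale = TRUE) {
  Xs <- X
  for (j in seq_len(ncol(X))) {
    v <- X[, j] - mean(X[, j])
    s <- sqrt(sum(v^2) / (length(v) - 1))
    if (s == 0) {
      Xs[, j] <- 0
    } else {
      Xs[, j] <- if (scale) v / s else v
    }
  }
  list(X = Xs, y = y - mean(y))
}

# brute-force K = 1 selection: threshold |X'y| at lambda * max|X'y|
oracle_support <- function(X, y, lambda, scale = TRUE) {
  std <- oracle_standardize(X, y, scale)
  z <- as.numeric(t(std$X) %*% std$y)
  az <- abs(z)
  if (max(az) == 0) return(integer(0))
  which(az >= lambda * max(az))
}

# brute-force cutoff enumeration for ROC / PR areas: every distinct score
# is a cutoff, prediction is score >= cutoff, areas by trapezoid (ROC) and
# step interpolation (PR)
oracle_auroc_aupr <- function(scores, labels) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  tpr <- fpr <- prec <- rec <- numeric(length(cuts))
  for (k in seq_along(cuts)) {
    pred <- scores >= cuts[k]
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    tpr[k] <- tp / n_pos
    fpr[k] <- fp / n_neg
    prec[k] <- tp / (tp + fp)
    rec[k] <- tp / n_pos
  }
  fpr_full <- c(0, fpr)
  tpr_full <- c(0, tpr)
  auroc <- sum(diff(fpr_full) * (tpr_full[-length(tpr_full)] +
                                   tpr_full[-1]) / 2)
  rec_full <- c(0, rec)
  aupr <- sum(diff(rec_full) * prec)
  list(auroc = auroc, aupr = aupr)
}

# Mann-Whitney form of the AUROC with half credit for ties
oracle_auroc_rank <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# expression tibble from a plain matrix
as_expr_tibble <- function(m) {
  colnames(m) <- colnames(m) %||% paste0("g", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(cell = paste0("c", seq_len(nrow(m)))),
                   tibble::as_tibble(m))
}

# random regression instance for selection-oracle checks
random_instance <- function(seed) {
  set.seed(seed)
  M <- sample(5:50, 1)
  D <- sample(2:20, 1)
  X <- matrix(rnorm(M * D), M, D)
  y <- rnorm(M)
  list(X = X, y = y, M = M, D = D)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
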