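#' Min-max normalize a score vector to \[0, 1\]
#'
#' `(v - min) / (max - min)` elementwise. A constant vector carries no
#' ranking information, so it maps to all zeros rather than dividing by zero.
#'
#' @param v numeric vector.
#' @return Numeric vector in \[0, 1\] of the same length.
#' @examples
#' minmax_normalize(c(2, 6, 4)) # 0, 1, 0.5
#' @export
minmax_normalize <- function(v) {
  if (length(v) == 0L) return(numeric(0))
  rng <- range(v)
  if (rng[1] == rng[2]) return(numeric(length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Selection counts of candidate regulators for one target gene
#'
#' The per-target scoring sweep: for every sparsity value on the grid, an
#' SPLS model of the target on the candidate block is fit and, when the
#' selected set is non-trivial (more than zero but fewer than all `d`
#' candidates), each selected candidate's count is incremented by one. A
#' selection of all candidates or of none is uninformative and contributes
#' nothing. Counts are returned raw (un-normalized).
#'
#' With one latent component the active set at sparsity `lambda` is exactly
#' the fraction-of-maximum threshold support of `z = X'y` on the
#' standardized data, so the whole sweep is computed from a single `z`
#' vector; the general path fits one SPLS model per grid value. The two
#' routes agree exactly.
#'
#' @param X_cand numeric matrix of candidate-regulator expression
#'   (observations x candidates, `d >= 2` columns).
#' @param y_target numeric expression vector of the target gene.
#' @param control a [grn_control()] record.
#' @return Numeric vector of `d` selection counts (named after the columns
#'   of `X_cand` when present). A constant target yields all-zero counts
#'   with a warning.
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' score_target(X, X[, 1] + rnorm(20, sd = 0.1), grn_control())
#' @export
score_target <- function(X_cand, y_target, control = grn_control()) {
  X_cand <- as.matrix(X_cand)
  d <- ncol(X_cand)
  if (d < 2L) stop_input("At least 2 candidate regulators are required.")
  counts <- setNames(numeric(d), colnames(X_cand))
  if (sd(y_target) == 0) {
    warn("Target gene has constant expression; all scores are zero.")
    return(counts)
  }
  std <- standardize_xy(X_cand, y_target, scale = control$scale)
  grid <- lambda_grid(control)
  if (control$k_components == 1L) {
    z <- drop(crossprod(std$X, std$y))
    z[std$degenerate] <- 0
    az <- abs(z)
    zmax <- max(az)
    if (zmax == 0) return(counts)
    # selected[l, j]: candidate j survives threshold grid[l] * zmax
    selected <- outer(grid * zmax, az, FUN = "<=")
    n_sel <- rowSums(selected)
    informative <- n_sel > 0 & n_sel < d
    counts[] <- colSums(selected[informative, , drop = FALSE])
  } else {
    for (lam in grid) {
      fit <- spls_fit(std, K = min(control$k_components,
                                   nrow(X_cand) - 1L, d), lambda = lam)
      a <- fit$active
      if (length(a) > 0L && length(a) < d) counts[a] <- counts[a] + 1
    }
  }
  counts
}

#' One masked, permuted scoring pass for the dropout-robust mode
#'
#' Draws a random sample permutation (applied jointly to the candidate block
#' and the target, preserving sample pairing), then an independent Bernoulli
#' keep-mask over the candidate block with keep-probability `p`
#' (`P(delta_jk = 1) = p`); masked-out entries are set to zero. The target
#' vector is never masked. The masked copy is then scored with
#' [score_target()]. Fully deterministic given `iteration_seed`.
#'
#' @inheritParams score_target
#' @param iteration_seed integer seed for this copy's permutation and mask.
#' @return Numeric vector of `d` selection counts for this copy.
#' @export
dropout_iteration <- function(X_cand, y_target, control, iteration_seed) {
  X_cand <- as.matrix(X_cand)
  M <- nrow(X_cand)
  d <- ncol(X_cand)
  p <- control$keep_prob
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(iteration_seed))
  perm <- sample.int(M)
  Xm <- X_cand[perm, , drop = FALSE]
  ym <- y_target[perm]
  if (p < 1) {
    keep <- matrix(rbinom(M * d, 1L, p), M, d)
    Xm[keep == 0L] <- 0
  }
  if (p == 0) {
    warn("keep_prob = 0 zeroes the whole candidate block; scores are zero.")
  }
  withCallingHandlers(
    score_target(Xm, ym, control),
    warning = function(w) {
      # a fully-masked block makes candidates constant, which score_target
      # would flag per-target; the keep_prob = 0 warning above covers it
      if (p == 0) invokeRestart("muffleWarning")
    }
  )
}

# save/restore the global RNG state so engine seeding never disturbs the
# caller's random stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Infer a directed gene-network score matrix from expression data
#'
#' The main entry point. Every gene in turn is treated as the target and all
#' remaining genes as candidate regulators; candidates are scored by how
#' persistently SPLS selects them across the sparsity sweep (see
#' [score_target()]). With `dropout = TRUE` in the control, counts are
#' accumulated over `iterations` masked and permuted copies of the data
#' before normalization. Each target's cumulative counts are min-max
#' normalized into row `i` of a G x G score matrix `S` in \[0, 1\] whose
#' entry `S[i, j]` scores the directed edge *gene j regulates gene i*; the
#' diagonal is zero and the matrix is generally asymmetric.
#'
#' @param data expression data: a data frame whose first column holds sample
#'   identifiers and remaining columns one gene each (as produced by
#'   [read_expression()] or [sample_cells()]), or a numeric matrix
#'   (samples x genes) with gene column names.
#' @param control a [grn_control()] record; `...` overrides individual
#'   fields, e.g. `infer_network(expr, dropout = TRUE, keep_prob = 0.6)`.
#' @param ... named [grn_control()] fields overriding `control`.
#' @return An object of class `"grn_fit"`: `scores` (G x G numeric matrix
#'   with gene dimnames), `genes`, `n_samples`, and `control`. Use [tidy()]
#'   for a ranked edge-list tibble, [glance()] for a one-row summary,
#'   [autoplot()] for a heat map, and [scores_to_edges()] /
#'   [evaluate_network()] downstream.
#' @examples
#' net <- random_network(5, density = 0.3, seed = 1)
#' ts <- simulate_timeseries(net, n_series = 20, times = seq(0, 100, 10),
#'                           seed = 1)
#' expr <- sample_cells(ts, n_cells = 40, seed = 1)
#' fit <- infer_network(expr)
#' tidy(fit)
#' @export
infer_network <- function(data, control = grn_control(), ...) {
  control <- override_control(control, ...)
  m <- as_expression_matrix(data)
  genes <- colnames(m)
  G <- ncol(m)
  M <- nrow(m)
  if (G < 3L) stop_input("At least 3 genes are required to infer a network.")
  if (anyDuplicated(genes)) {
    stop_input(paste0("Duplicated gene identifiers: ",
                      paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  if (M < 2L) stop_input("At least 2 samples are required.")

  score_one <- function(i) {
    X_cand <- m[, -i, drop = FALSE]
    y <- m[, i]
    if (control$dropout) {
      counts <- numeric(G - 1L)
      for (it in seq_len(control$iterations)) {
        counts <- counts +
          dropout_iteration(X_cand, y, control,
                            derive_seed(control$seed, i, it))
      }
      counts
    } else {
      score_target(X_cand, y, control)
    }
  }

  rows <- if (control$workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(G), score_one, mc.cores = control$workers)
  } else {
    lapply(seq_len(G), score_one)
  }

  S <- matrix(0, G, G, dimnames = list(target = genes, regulator = genes))
  for (i in seq_len(G)) {
    S[i, -i] <- minmax_normalize(unname(rows[[i]]))
  }
  structure(
    list(scores = S, genes = genes, n_samples = M, control = control),
    class = "grn_fit"
  )
}

override_control <- function(control, ...) {
  dots <- list(...)
  if (length(dots) == 0L) return(control)
  bad <- setdiff(names(dots), names(unclass(control)))
  if (length(bad) > 0L || is.null(names(dots)) || any(names(dots) == "")) {
    stop_config(paste0("Unknown control field(s): ",
                       paste(bad, collapse = ", ")))
  }
  do.call(grn_control, modifyList(unclass(control), dots))
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("Inferred gene-network scores: ", length(x$genes), " genes, ",
      x$n_samples, " samples\n", sep = "")
  cat("  dropout mode: ", x$control$dropout,
      if (x$control$dropout) {
        sprintf(" (p = %g, %d iterations)", x$control$keep_prob,
                x$control$iterations)
      } else "",
      "\n", sep = "")
  top <- head(dplyr::arrange(tidy(x), dplyr::desc(.data$score)), 5L)
  cat("  top edges:\n")
  print(as.data.frame(top), row.names = FALSE)
  invisible(x)
}

#' @describeIn infer_network ranked edge list: one row per ordered gene pair
#'   (self-loops excluded) with columns `regulator`, `target`, `score`,
#'   sorted by decreasing score.
#' @param x,object a `"grn_fit"` object.
#' @export
tidy.grn_fit <- function(x, ...) {
  dplyr::arrange(scores_to_edges(x), dplyr::desc(.data$score))
}

#' @describeIn infer_network one-row summary: gene/sample counts, grid size
#'   and dropout settings.
#' @export
glance.grn_fit <- function(x, ...) {
  tibble(
    n_genes = length(x$genes),
    n_samples = x$n_samples,
    n_lambda = length(lambda_grid(x$control)),
    k_components = x$control$k_components,
    dropout = x$control$dropout,
    keep_prob = if (x$control$dropout) x$control$keep_prob else NA_real_,
    iterations = if (x$control$dropout) x$control$iterations else NA_integer_,
    seed = x$control$seed
  )
}

#' @describeIn infer_network score-matrix heat map (targets on rows,
#'   regulators on columns).
#' @export
autoplot.grn_fit <- function(object, ...) {
  df <- scores_to_edges(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$regulator, y = .data$target,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "regulator", y = "target", fill = "score",
                  title = "Inferred regulatory scores") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Tune the Bernoulli keep-probability of the dropout-robust mode
#'
#' Sweeps the keep-probability `p` over a grid, runs the full inference
#' `repeats` times per value with distinct derived seeds, scores each run by
#' AUROC against a reference network, and reports the profile of mean AUROC
#' per `p` together with the best value (ties broken toward the smaller
#' `p`). The published tuning protocol uses `p` from 0.1 to 1 in steps of
#' 0.1 with 10 repeats.
#'
#' @inheritParams infer_network
#' @param truth reference network: a [random_network()] object or an edge
#'   tibble/data frame with `regulator` and `target` columns.
#' @param p_grid numeric vector of keep-probabilities to try.
#' @param repeats runs averaged per grid value.
#' @return Object of class `"keep_prob_tuning"` with `best_p` and `profile`
#'   (a tibble of `keep_prob`, `mean_auroc`); `tidy()` returns the profile.
#' @export
tune_keep_prob <- function(data, truth, control = grn_control(dropout = TRUE),
                           p_grid = seq(0.1, 1, by = 0.1), repeats = 10L,
                           ...) {
  control <- override_control(control, ...)
  if (!control$dropout) control <- override_control(control, dropout = TRUE)
  p_grid <- sort(unique(p_grid))
  if (any(p_grid < 0 | p_grid > 1)) {
    stop_config("`p_grid` values must lie in [0, 1].")
  }
  means <- vapply(seq_along(p_grid), function(ip) {
    aurocs <- vapply(seq_len(repeats), function(r) {
      ctl <- override_control(control, keep_prob = p_grid[ip],
                              seed = derive_seed(control$seed, ip, r))
      fit <- infer_network(data, control = ctl)
      glance(evaluate_network(fit, truth))$auroc
    }, numeric(1))
    mean(aurocs)
  }, numeric(1))
  best <- p_grid[which.max(means)]
  structure(
    list(best_p = best,
         profile = tibble(keep_prob = p_grid, mean_auroc = means),
         repeats = as.integer(repeats)),
    class = "keep_prob_tuning"
  )
}

#' @export
print.keep_prob_tuning <- function(x, ...) {
  cat("Keep-probability tuning (", x$repeats, " repeats per value)\n",
      sep = "")
  cat("  best p:", x$best_p, "\n")
  print(as.data.frame(x$profile), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.keep_prob_tuning <- function(x, ...) x$profile

#' @export
autoplot.keep_prob_tuning <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$keep_prob, y = .data$mean_auroc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_p, linetype = 2) +
    ggplot2::labs(x = "keep-probability p", y = "mean AUROC") +
    ggplot2::theme_minimal()
}
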