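#' Convert a score matrix to a ranked directed edge list
#'
#' One row per ordered gene pair (self-loops excluded): the score of the
#' directed edge *regulator j -> target i* is entry `S[i, j]` of the score
#' matrix (targets on rows).
#'
#' @param x a `"grn_fit"` from [infer_network()] or a square numeric score
#'   matrix with gene dimnames.
#' @return Tibble with columns `regulator`, `target`, `score` and
#'   `G * (G - 1)` rows.
#' @export
scores_to_edges <- function(x) {
  S <- if (inherits(x, "grn_fit")) x$scores else as.matrix(x)
  genes <- colnames(S)
  if (is.null(genes) || nrow(S) != ncol(S)) {
    stop_input("A square score matrix with gene dimnames is required.")
  }
  G <- ncol(S)
  idx <- expand.grid(target = seq_len(G), regulator = seq_len(G))
  idx <- idx[idx$target != idx$regulator, , drop = FALSE]
  tibble(
    regulator = genes[idx$regulator],
    target = genes[idx$target],
    score = S[cbind(idx$target, idx$regulator)]
  )
}

#' Keep only edges outgoing from known transcription factors
#'
#' Evaluation on experimental single-cell data is restricted to
#' interactions whose regulator is a transcription factor; targets are
#' unrestricted and scores are untouched.
#'
#' @param edges edge tibble with a `regulator` column.
#' @param tf_ids non-empty character vector of TF identifiers.
#' @return The filtered edge tibble.
#' @export
restrict_to_tf <- function(edges, tf_ids) {
  if (length(tf_ids) == 0L) stop_input("`tf_ids` must be non-empty.")
  dplyr::filter(edges, .data$regulator %in% tf_ids)
}

# cutoff-sweep ROC / PR curves with tied scores grouped at one cutoff
sweep_curves <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group boundaries: last index of each distinct score
  grp_last <- which(!duplicated(rev(s)))
  grp_last <- length(s) + 1L - grp_last # indices from the front
  grp_last <- sort(grp_last)
  tp <- cumsum(l)[grp_last]
  fp <- grp_last - tp
  n_pos <- sum(l)
  n_neg <- length(l) - n_pos
  tibble(
    threshold = s[grp_last],
    tp = tp, fp = fp,
    tpr = tp / n_pos, fpr = fp / n_neg,
    precision = tp / (tp + fp), recall = tp / n_pos
  )
}

#' AUROC and AUPR of a ranked edge list against a reference network
#'
#' The inferred edge list and the reference are compared over the full
#' universe of ordered non-self gene pairs among the evaluated genes:
#' positives are reference edges, negatives all remaining pairs, and the
#' score cutoff is swept over every distinct score to trace the ROC and
#' precision–recall curves. Tied scores enter at a single cutoff (AUROC
#' gives trapezoidal half-credit across a tie, equaling the Mann–Whitney
#' rank statistic; AUPR uses conservative step interpolation, precision held
#' constant between recall points). Reference edges with an endpoint absent
#' from the evaluated genes are dropped — no method could recover them.
#'
#' @param x a `"grn_fit"`, a score matrix, or an edge tibble
#'   (`regulator`, `target`, `score`).
#' @param truth reference network: a `"grn_network"` or an edge
#'   tibble/data frame with `regulator` and `target` columns.
#' @param tf_ids optional transcription-factor identifiers; when given, only
#'   TF-outgoing edges are evaluated (see [restrict_to_tf()]).
#' @return Object of class `"grn_eval"` with fields `auroc`, `aupr`,
#'   `n_pos`, `n_neg` and the swept `curve` tibble. `glance()` returns the
#'   one-row metric summary, `tidy()` the curve points, `autoplot()` the
#'   ROC and PR curves.
#' @examples
#' net <- random_network(6, 0.25, seed = 2)
#' ts <- simulate_timeseries(net, n_series = 30, times = seq(0, 100, 10),
#'                           seed = 2)
#' fit <- infer_network(sample_cells(ts, 60, seed = 2))
#' glance(evaluate_network(fit, net))
#' @export
evaluate_network <- function(x, truth, tf_ids = NULL) {
  edges <- if (is.data.frame(x) && !inherits(x, "grn_fit")) {
    if (!all(c("regulator", "target", "score") %in% names(x))) {
      stop_input("Edge tibble needs regulator, target and score columns.")
    }
    as_tibble(x)
  } else {
    scores_to_edges(x)
  }
  if (!is.null(tf_ids)) edges <- restrict_to_tf(edges, tf_ids)
  if (nrow(edges) == 0L) {
    stop_eval("No edges left to evaluate after restriction.")
  }
  if (any(!is.finite(edges$score))) stop_input("Edge scores must be finite.")
  truth_edges <- as_truth_edges(truth)
  genes <- union(edges$regulator, edges$target)
  truth_edges <- dplyr::filter(truth_edges,
                               .data$regulator %in% genes &
                                 .data$target %in% genes)
  key <- function(r, t) paste(r, t, sep = "\r")
  labels <- as.integer(key(edges$regulator, edges$target) %in%
                         key(truth_edges$regulator, truth_edges$target))
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  if (n_pos == 0L || n_neg == 0L) {
    stop_eval(paste0("Metrics are undefined: ", n_pos, " positive and ",
                     n_neg, " negative pairs in the evaluated universe."))
  }
  curve <- sweep_curves(edges$score, labels)
  # trapezoid over (fpr, tpr) from (0, 0); the final point is (1, 1)
  fpr <- c(0, curve$fpr)
  tpr <- c(0, curve$tpr)
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  recall <- c(0, curve$recall)
  aupr <- sum(diff(recall) * curve$precision)
  structure(
    list(auroc = auroc, aupr = aupr, n_pos = n_pos, n_neg = n_neg,
         curve = curve),
    class = "grn_eval"
  )
}

#' @export
print.grn_eval <- function(x, ...) {
  cat(sprintf("Network evaluation: AUROC %.4f, AUPR %.4f (%d positives, %d negatives)\n",
              x$auroc, x$aupr, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
glance.grn_eval <- function(x, ...) {
  tibble(auroc = x$auroc, aupr = x$aupr, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
tidy.grn_eval <- function(x, ...) x$curve

#' @export
autoplot.grn_eval <- function(object, ...) {
  cv <- object$curve
  df <- dplyr::bind_rows(
    tibble(curve = "ROC", x = c(0, cv$fpr, 1), y = c(0, cv$tpr, 1)),
    tibble(curve = "Precision-recall", x = c(cv$recall),
           y = c(cv$precision))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step(data = ~ dplyr::filter(.x,
                                              .data$curve == "Precision-recall")) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$curve == "ROC")) +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(
      x = "false-positive rate / recall", y = "true-positive rate / precision",
      title = sprintf("AUROC %.3f, AUPR %.3f", object$auroc, object$aupr)) +
    ggplot2::theme_minimal()
}

#' Bonferroni-filtered top variable genes
#'
#' The preselection step for large single-cell matrices: per-gene variances
#' and raw P-values (computed upstream) are Bonferroni-corrected
#' (`p_adjusted = min(1, p * n_genes)`), genes with `p_adjusted < alpha`
#' are kept, and of those the `top_n` largest-variance genes are returned
#' (fewer when not enough pass). The published settings are
#' `top_n` of 500 or 1000 with `alpha = 0.01`.
#'
#' @param stats data frame with columns `gene`, `variance`, `p_value`.
#' @param top_n maximum number of genes returned (positive).
#' @param alpha significance threshold on the corrected P-value.
#' @return Tibble of the selected genes with `p_adjusted` added, sorted by
#'   decreasing variance.
#' @export
select_variable_genes <- function(stats, top_n = 500L, alpha = 0.01) {
  if (top_n <= 0L) stop_config("`top_n` must be positive.")
  if (!all(c("gene", "variance", "p_value") %in% names(stats))) {
    stop_input("`stats` needs gene, variance and p_value columns.")
  }
  if (any(stats$p_value < 0 | stats$p_value > 1, na.rm = TRUE)) {
    stop_input("P-values must lie in [0, 1].")
  }
  stats |>
    as_tibble() |>
    dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value,
                                               method = "bonferroni")) |>
    dplyr::filter(.data$p_adjusted < alpha) |>
    dplyr::arrange(dplyr::desc(.data$variance)) |>
    dplyr::slice_head(n = as.integer(top_n))
}
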