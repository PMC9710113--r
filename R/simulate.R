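#' Random directed signed gene network
#'
#' Draws an Erdős–Rényi-style directed network: each ordered non-self gene
#' pair becomes an edge independently with probability `density`, and each
#' edge carries a signed weight drawn uniformly from
#' \[-1, -0.25\] U \[0.25, 1\] (so no edge is vanishingly weak).
#'
#' @param n_genes number of genes (>= 2).
#' @param density edge probability in (0, 1).
#' @param n_tfs optionally, the number of genes (taken from the front of the
#'   gene list) marked as transcription factors.
#' @param seed integer seed; the draw is fully deterministic per seed.
#' @return A `"grn_network"` tibble with columns `regulator`, `target`,
#'   `weight` and attributes `gene_ids` (all genes, including isolated ones)
#'   and `tf_ids`.
#' @examples
#' net <- random_network(10, density = 0.2, seed = 7)
#' nrow(net)
#' @export
random_network <- function(n_genes, density = 0.15, n_tfs = NULL, seed = 1L) {
  if (n_genes < 2L) stop_input("`n_genes` must be at least 2.")
  if (!is.numeric(density) || density <= 0 || density >= 1) {
    stop_config("`density` must lie strictly between 0 and 1.")
  }
  genes <- paste0("G", seq_len(n_genes))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  pairs <- expand.grid(regulator = genes, target = genes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]
  keep <- runif(nrow(pairs)) < density
  edges <- pairs[keep, , drop = FALSE]
  n_e <- nrow(edges)
  sign <- ifelse(runif(n_e) < 0.5, -1, 1)
  edges$weight <- sign * runif(n_e, 0.25, 1)
  tf_ids <- if (!is.null(n_tfs)) genes[seq_len(min(n_tfs, n_genes))] else NULL
  new_grn_network(as_tibble(edges), genes, tf_ids)
}

#' Construct a directed signed network from an edge table
#'
#' @param edges data frame with columns `regulator`, `target` and
#'   optionally `weight` (defaults to +1); self-loops are rejected.
#' @param gene_ids gene universe; defaults to the genes mentioned in
#'   `edges`, but should be given explicitly when isolated genes exist.
#' @param tf_ids optional transcription-factor subset.
#' @return A `"grn_network"` tibble.
#' @examples
#' grn_network(data.frame(regulator = "A", target = "B"),
#'             gene_ids = c("A", "B", "C"))
#' @export
grn_network <- function(edges, gene_ids = NULL, tf_ids = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("regulator", "target") %in% names(edges))) {
    stop_input("`edges` needs `regulator` and `target` columns.")
  }
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (any(!is.finite(edges$weight)) || any(edges$weight == 0)) {
    stop_input("Edge weights must be finite and nonzero.")
  }
  if (any(edges$regulator == edges$target)) {
    stop_input("Self-loop edges are not allowed.")
  }
  mentioned <- union(edges$regulator, edges$target)
  gene_ids <- gene_ids %||% mentioned
  if (!all(mentioned %in% gene_ids)) {
    stop_input("Every edge endpoint must be in `gene_ids`.")
  }
  new_grn_network(as_tibble(edges[c("regulator", "target", "weight")]),
                  gene_ids, tf_ids)
}

new_grn_network <- function(edges, gene_ids, tf_ids = NULL) {
  out <- as_tibble(edges)
  attr(out, "gene_ids") <- gene_ids
  attr(out, "tf_ids") <- tf_ids
  class(out) <- c("grn_network", class(tibble()))
  out
}

#' Genes / transcription factors of a network object
#'
#' @param net a `"grn_network"` object.
#' @return Character vector of identifiers.
#' @export
network_genes <- function(net) {
  attr(net, "gene_ids") %||% union(net$regulator, net$target)
}

#' @rdname network_genes
#' @export
network_tfs <- function(net) attr(net, "tf_ids")

#' @export
tidy.grn_network <- function(x, ...) {
  as_tibble(unclass(x)[c("regulator", "target", "weight")[
    c("regulator", "target", "weight") %in% names(x)]])
}

# coerce a network-like input (grn_network or plain edge table) to a
# two-column regulator/target tibble plus gene universe
as_truth_edges <- function(truth) {
  if (inherits(truth, "grn_network") || is.data.frame(truth)) {
    df <- as.data.frame(truth)
    if (!all(c("regulator", "target") %in% names(df))) {
      if (ncol(df) >= 2L) names(df)[1:2] <- c("regulator", "target")
      else stop_input("Edge table needs `regulator` and `target` columns.")
    }
    df <- df[df$regulator != df$target, c("regulator", "target")]
    as_tibble(df)
  } else {
    stop_input("`truth` must be a grn_network or an edge data frame.")
  }
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# dense regulator -> target weight matrix of a network
weight_matrix <- function(net) {
  genes <- network_genes(net)
  W <- matrix(0, length(genes), length(genes),
              dimnames = list(regulator = genes, target = genes))
  if (nrow(net) > 0L) {
    W[cbind(match(net$regulator, genes), match(net$target, genes))] <-
      net$weight
  }
  W
}

# activation thresholds that place every gene at the sensitive midpoint of
# its sigmoid when all regulators sit at the isolated-gene equilibrium;
# without this, genes with several regulators saturate and become
# insensitive to all of them
centered_basal <- function(Wm, production, decay) {
  -colSums(Wm) * production / (2 * decay)
}

# one Euler-Maruyama step for all series at once; states is n_series x G
em_step <- function(states, Wm, production, decay, basal, slope, dt,
                    noise_sd) {
  drive <- sigmoid(slope * sweep(states %*% Wm, 2L, basal, "+"))
  drift <- production * drive - decay * states
  states <- states + drift * dt
  if (noise_sd > 0) {
    states <- states +
      noise_sd * sqrt(dt) * matrix(rnorm(length(states)), nrow(states))
  }
  pmax(states, 0)
}

#' Stochastic expression time series from a known network
#'
#' Integrates, per series, the stochastic kinetic model
#' `dx_g = (production * sigmoid(slope * (sum_j w_jg x_j + basal_g))
#' - decay * x_g) dt + noise_sd dW` by Euler–Maruyama with internal step
#' `dt`, recording the state at the requested times; expression is clipped
#' at zero and each series starts from an independent random state
#' (Uniform between 0 and twice the isolated-gene equilibrium).
#'
#' The defaults are chosen so that sampled "cells" carry recoverable
#' regulatory signal, emulating benchmark-generator time courses: the
#' isolated-gene equilibrium `production / (2 * decay)` is 1; the
#' relaxation timescale `1 / decay` (500 time units) spans the default
#' 0–1000 recording window, so trajectories are still relaxing from their
#' random initial states when cells are sampled and regulator–target
#' dependence is visible along the shared transients; and each gene's
#' activation threshold is auto-centered (`basal = NULL`) at its typical
#' input so no target saturates into insensitivity.
#'
#' @param net a `"grn_network"` from [random_network()] (or built by hand).
#' @param n_series number of independent stochastic series (each series
#'   plays the role of one replicate experiment; 1000 matches the benchmark
#'   protocol and supports every single-cell sampling scheme).
#' @param times strictly increasing recording times starting at 0.
#' @param noise_sd diffusion coefficient of the driving Brownian noise.
#' @param production,decay kinetic rates (maximal production and
#'   first-order decay).
#' @param slope steepness of the sigmoidal regulation function.
#' @param basal per-gene activation threshold offset; `NULL` (default)
#'   auto-centers each gene's sigmoid at the input it receives when all
#'   regulators sit at the isolated-gene equilibrium.
#' @param dt internal integration step.
#' @param seed integer seed (initial states and noise).
#' @return Object of class `"grn_timeseries"`: `values` (array
#'   n_series x length(times) x G), `times`, `genes`.
#' @examples
#' net <- random_network(5, 0.3, seed = 1)
#' ts <- simulate_timeseries(net, n_series = 10, times = seq(0, 200, 50),
#'                           seed = 1)
#' dim(ts$values)
#' @export
simulate_timeseries <- function(net, n_series = 1000L,
                                times = seq(0, 1000, by = 50),
                                noise_sd = 0.02, production = 0.004,
                                decay = 0.002, slope = 6, basal = NULL,
                                dt = 2, seed = 1L) {
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop_config("`times` must start at 0 and be strictly increasing.")
  }
  genes <- network_genes(net)
  G <- length(genes)
  Wm <- weight_matrix(net)
  equilibrium <- production / (2 * decay)
  basal <- if (is.null(basal)) centered_basal(Wm, production, decay) else
    rep(basal, length.out = G)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  states <- matrix(runif(n_series * G, 0, 2 * equilibrium), n_series, G)
  values <- array(NA_real_, dim = c(n_series, length(times), G),
                  dimnames = list(NULL, NULL, genes))
  t_now <- 0
  for (ti in seq_along(times)) {
    n_sub <- round((times[ti] - t_now) / dt)
    for (s in seq_len(n_sub)) {
      states <- em_step(states, Wm, production, decay, basal, slope, dt,
                        noise_sd)
    }
    t_now <- t_now + n_sub * dt
    values[, ti, ] <- states
  }
  structure(list(values = values, times = times, genes = genes),
            class = "grn_timeseries")
}

#' @export
print.grn_timeseries <- function(x, ...) {
  cat("Simulated expression time series: ", dim(x$values)[1], " series x ",
      length(x$times), " time points x ", length(x$genes), " genes\n",
      sep = "")
  invisible(x)
}

#' Single-cell sampling scheme for a requested cell count
#'
#' The benchmark protocol draws each cell as one time point of one series.
#' The six published cell counts map to fixed schemes (cells per time point
#' / time-step between sampled points, from time 0): 5000 -> 250/50,
#' 1000 -> 50/50, 500 -> 50/100, 100 -> 10/100, 50 -> 25/500, 10 -> 5/500.
#' Any other count falls back to spreading cells as evenly as possible over
#' all recorded time points, earliest points first.
#'
#' @param n_cells requested number of cells.
#' @param times recorded time points available in the series set.
#' @return A tibble with one row per sampled time point: `time`,
#'   `n_at_point`.
#' @export
sampling_scheme <- function(n_cells, times = seq(0, 1000, by = 50)) {
  schemes <- list(`5000` = c(250, 50), `1000` = c(50, 50),
                  `500` = c(50, 100), `100` = c(10, 100),
                  `50` = c(25, 500), `10` = c(5, 500))
  key <- as.character(n_cells)
  if (key %in% names(schemes)) {
    per <- schemes[[key]][1]
    step <- schemes[[key]][2]
    pts <- seq(0, by = step, length.out = n_cells / per)
    missing <- setdiff(pts, times)
    if (length(missing) > 0L) {
      stop_input(paste0("Sampling scheme needs time points not present in ",
                        "the series: ", paste(missing, collapse = ", ")))
    }
    return(tibble(time = pts, n_at_point = rep(per, length(pts))))
  }
  # generic rule: even spread over all recorded points, earliest first
  n_t <- length(times)
  base <- n_cells %/% n_t
  extra <- n_cells %% n_t
  n_at <- rep(base, n_t) + c(rep(1L, extra), rep(0L, n_t - extra))
  keep <- n_at > 0L
  tibble(time = times[keep], n_at_point = n_at[keep])
}

#' Sample single cells from simulated time series
#'
#' Implements the "one cell = one time point of one series" sampling: at
#' each time point of the scheme for `n_cells` (see [sampling_scheme()]),
#' cells are drawn from distinct series without replacement.
#'
#' @param ts a `"grn_timeseries"` from [simulate_timeseries()].
#' @param n_cells number of cells to draw.
#' @param seed integer seed.
#' @return Expression tibble: first column `cell` (identifier), one column
#'   per gene; `n_cells` rows ordered by sampling time.
#' @export
sample_cells <- function(ts, n_cells, seed = 1L) {
  stopifnot(inherits(ts, "grn_timeseries"))
  scheme <- sampling_scheme(n_cells, ts$times)
  n_series <- dim(ts$values)[1]
  if (any(scheme$n_at_point > n_series)) {
    stop_input(paste0("Scheme needs up to ", max(scheme$n_at_point),
                      " distinct series per time point but only ", n_series,
                      " are available."))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  blocks <- lapply(seq_len(nrow(scheme)), function(k) {
    ti <- match(scheme$time[k], ts$times)
    series <- sample.int(n_series, scheme$n_at_point[k])
    ts$values[series, ti, , drop = FALSE]
  })
  m <- do.call(rbind, lapply(blocks, function(b) {
    matrix(b, nrow = dim(b)[1], dimnames = list(NULL, ts$genes))
  }))
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(cell = paste0("cell", seq_len(nrow(m)))),
                          out)
  out
}

#' Induce dropout events in an expression matrix
#'
#' Emulates single-cell dropout on dense simulated data: for every gene, the
#' entries in the lowest `rate` fraction (exactly `ceiling(rate * M)`
#' entries, ties broken by order of appearance) are eligible, and each
#' eligible entry is independently replaced by zero with probability
#' `bern_prob`. Entries above the gene's quantile are never touched. The
#' published protocol uses rates 0.2 / 0.5 / 0.7 with `bern_prob = 0.5`.
#'
#' @param data expression tibble (leading `cell` column) or numeric matrix,
#'   samples x genes.
#' @param rate fraction in \[0, 1\] of each gene's lowest values eligible
#'   for dropout.
#' @param bern_prob probability that an eligible entry is zeroed.
#' @param seed integer seed.
#' @return Same shape and type as the input.
#' @export
induce_dropout <- function(data, rate, bern_prob = 0.5, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    stop_config("`rate` must lie in [0, 1].")
  }
  if (!is.numeric(bern_prob) || bern_prob < 0 || bern_prob > 1) {
    stop_config("`bern_prob` must lie in [0, 1].")
  }
  is_df <- is.data.frame(data)
  m <- as_expression_matrix(data)
  if (rate == 0 || bern_prob == 0) return(data)
  M <- nrow(m)
  n_elig <- ceiling(rate * M)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  for (g in seq_len(ncol(m))) {
    eligible <- order(m[, g])[seq_len(n_elig)]
    zeroed <- eligible[rbinom(n_elig, 1L, bern_prob) == 1L]
    m[zeroed, g] <- 0
  }
  if (is_df) {
    out <- as_tibble(m)
    dplyr::bind_cols(data[, 1, drop = FALSE], out)
  } else {
    m
  }
}

#' Noise-free wild-type and single-gene knockout steady states
#'
#' Integrates the deterministic kinetic model to its fixed point, once
#' unperturbed and once per gene with that gene's expression clamped to
#' zero throughout — the in-silico analogue of null-mutant knockout
#' experiments.
#'
#' @inheritParams simulate_timeseries
#' @param tol convergence tolerance on the largest per-step state change.
#' @param max_time integration horizon; failing to converge (or a diverging
#'   state) raises a simulation error with diagnostics.
#' @return Numeric matrix of shape (G + 1) x G: row `"wildtype"` then one
#'   row `"ko_<gene>"` per knockout, columns named by gene.
#' @export
simulate_knockouts <- function(net, production = 0.004, decay = 0.002,
                               slope = 6, basal = NULL, dt = 2, tol = 1e-9,
                               max_time = 20000, seed = 1L) {
  genes <- network_genes(net)
  G <- length(genes)
  if (G < 2L) stop_input("At least 2 genes are required.")
  Wm <- weight_matrix(net)
  equilibrium <- production / (2 * decay)
  basal <- if (is.null(basal)) centered_basal(Wm, production, decay) else
    rep(basal, length.out = G)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  x0 <- runif(G, 0, 2 * equilibrium)

  settle <- function(clamp = NULL) {
    x <- matrix(x0, 1L, G)
    if (!is.null(clamp)) x[, clamp] <- 0
    n_steps <- ceiling(max_time / dt)
    for (s in seq_len(n_steps)) {
      x_new <- em_step(x, Wm, production, decay, basal, slope, dt,
                       noise_sd = 0)
      if (!is.null(clamp)) x_new[, clamp] <- 0
      if (any(!is.finite(x_new)) || max(abs(x_new)) > 1e6) {
        abort(paste0("Knockout integration diverged (max state ",
                     format(max(abs(x_new))), " at step ", s, ")."),
              class = "splsnet_simulation_error")
      }
      delta <- max(abs(x_new - x))
      x <- x_new
      if (delta < tol) return(drop(x))
    }
    abort(paste0("Knockout integration did not converge within max_time = ",
                 max_time, " (last step change ", format(delta), ")."),
          class = "splsnet_simulation_error")
  }

  out <- matrix(NA_real_, G + 1L, G,
                dimnames = list(c("wildtype", paste0("ko_", genes)), genes))
  out["wildtype", ] <- settle()
  for (g in seq_len(G)) {
    out[g + 1L, ] <- settle(clamp = g)
  }
  out
}

#' @export
autoplot.grn_network <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$regulator, y = .data$target,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = "Network adjacency (signed weights)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
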