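#' Hyperparameters for recursive sparse-PLS network inference
#'
#' Collects every tunable of the inference engine in one validated record.
#' Defaults follow the method's published tuning: one latent component, a
#' sparsity sweep from 0.01 to 0.99 in steps of 0.01, and, when the
#' dropout-robust mode is on, ten masked data copies.
#'
#' @param k_components number of SPLS latent components (default 1, the
#'   value found optimal for network inference).
#' @param lambda_min,lambda_max,lambda_step arithmetic grid of the sparsity
#'   parameter, `0 < lambda_min <= lambda_max < 1`, `lambda_step > 0`.
#' @param dropout logical; turn on the robustness mode for zero-inflated
#'   (single-cell) data: each of `iterations` data copies has its samples
#'   jointly permuted and its predictor entries kept independently with
#'   probability `keep_prob`, and selection counts are accumulated across
#'   copies before normalization.
#' @param keep_prob Bernoulli keep-probability `p` in \[0, 1\] for the mask
#'   (only used when `dropout = TRUE`); `p = 1` keeps every entry, making the
#'   mode equivalent to the deterministic sweep.
#' @param iterations number of masked copies accumulated (default 10).
#' @param seed integer base seed; every random draw in the engine derives
#'   deterministically from it, the target index and the copy index.
#' @param scale logical; unit-scale predictor columns before SPLS
#'   (default `TRUE`).
#' @param workers number of worker processes for parallelizing over target
#'   genes; results are identical for every worker count.
#' @return A list of class `"grn_control"`.
#' @examples
#' grn_control(dropout = TRUE, keep_prob = 0.6)
#' @export
grn_control <- function(k_components = 1L,
                        lambda_min = 0.01, lambda_max = 0.99,
                        lambda_step = 0.01,
                        dropout = FALSE, keep_prob = 1, iterations = 10L,
                        seed = 1L, scale = TRUE, workers = 1L) {
  k_components <- as.integer(k_components)
  iterations <- as.integer(iterations)
  workers <- as.integer(workers)
  if (is.na(k_components) || k_components < 1L) {
    stop_config("`k_components` must be a positive integer.")
  }
  if (!is.numeric(lambda_min) || !is.numeric(lambda_max) ||
      !is.numeric(lambda_step) ||
      lambda_min <= 0 || lambda_max >= 1 || lambda_min > lambda_max ||
      lambda_step <= 0) {
    stop_config(
      "Sparsity grid must satisfy 0 < lambda_min <= lambda_max < 1 with a positive step.")
  }
  if (!is.logical(dropout) || length(dropout) != 1L || is.na(dropout)) {
    stop_config("`dropout` must be TRUE or FALSE.")
  }
  if (!is.numeric(keep_prob) || keep_prob < 0 || keep_prob > 1) {
    stop_config("`keep_prob` must lie in [0, 1].")
  }
  if (is.na(iterations) || iterations < 1L) {
    stop_config("`iterations` must be a positive integer.")
  }
  if (is.na(workers) || workers < 1L) {
    stop_config("`workers` must be a positive integer.")
  }
  structure(
    list(k_components = k_components, lambda_min = lambda_min,
         lambda_max = lambda_max, lambda_step = lambda_step,
         dropout = dropout, keep_prob = keep_prob, iterations = iterations,
         seed = as.integer(seed), scale = isTRUE(scale), workers = workers),
    class = "grn_control"
  )
}

#' @export
print.grn_control <- function(x, ...) {
  cat("Network-inference control:\n")
  cat("  components K      :", x$k_components, "\n")
  cat(sprintf("  lambda grid       : %g to %g, step %g (%d values)\n",
              x$lambda_min, x$lambda_max, x$lambda_step,
              length(lambda_grid(x))))
  cat("  dropout mode      :", x$dropout, "\n")
  if (x$dropout) {
    cat("  keep_prob (p)     :", x$keep_prob, "\n")
    cat("  iterations        :", x$iterations, "\n")
  }
  cat("  seed              :", x$seed, "\n")
  cat("  scale predictors  :", x$scale, "\n")
  cat("  workers           :", x$workers, "\n")
  invisible(x)
}

#' The sparsity-parameter grid of a control record
#'
#' Arithmetic sequence `lambda_min, lambda_min + lambda_step, ...` truncated
#' at `lambda_max`; both endpoints are included whenever the step divides the
#' range (a 1e-9 tolerance absorbs floating-point drift, so the default grid
#' has exactly 99 values: 0.01, 0.02, ..., 0.99).
#'
#' @param control a [grn_control()] record.
#' @return Increasing numeric vector of sparsity values.
#' @examples
#' length(lambda_grid(grn_control())) # 99
#' @export
lambda_grid <- function(control = grn_control()) {
  stopifnot(inherits(control, "grn_control"))
  n_steps <- floor((control$lambda_max - control$lambda_min) /
                     control$lambda_step + 1e-9)
  grid <- control$lambda_min + (0:n_steps) * control$lambda_step
  grid <- grid[grid <= control$lambda_max + 1e-9]
  if (length(grid) == 0L) stop_config("Empty sparsity grid.")
  grid
}
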