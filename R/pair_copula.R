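#' Fitted bivariate copula density models
#'
#' A `pair_copula` object represents a non-parametric estimate of a bivariate
#' copula density on the unit square. Three kinds exist: `"flow"`
#' (rational-quadratic spline normalizing flow), `"histogram_fallback"`
#' (smoothed, renormalized 2-D histogram) and `"independence"` (constant 1).
#' All kinds expose the same surface: [density_grid()], [dpair_copula()] and
#' [h_function()].
#'
#' @name pair_copula
NULL

new_pair_copula <- function(kind, grid, G, fit = NULL, meta = list()) {
  structure(list(kind = kind, grid = grid, G = G, fit = fit, meta = meta),
            class = "pair_copula")
}

#' @export
print.pair_copula <- function(x, ...) {
  cat(sprintf("pair_copula [%s], grid %d x %d", x$kind, x$G, x$G))
  if (!is.null(x$meta$n)) cat(sprintf(", fitted on n = %d", x$meta$n))
  cat("\n")
  invisible(x)
}

#' Independence pair-copula model
#' @param G grid size.
#' @return a `pair_copula` of kind `"independence"`.
#' @export
independence_copula <- function(G = 100) {
  new_pair_copula("independence", matrix(1, G, G), G)
}

#' Smoothed-histogram copula density estimator
#'
#' Bins pseudo-observations on a `G x G` grid, smooths with a separable
#' Gaussian kernel (edge-renormalized) and rescales the result to mean 1 so
#' that it integrates to 1 on the unit square. A fast, deterministic
#' estimator behind the same contract as the flow.
#'
#' @param pairs n x 2 matrix of pseudo-observations in (0, 1).
#' @param G grid size (default 100).
#' @param bandwidth Gaussian kernel standard deviation in grid bins.
#' @return a `pair_copula` of kind `"histogram_fallback"`.
#' @export
fit_copula_fallback <- function(pairs, G = 100, bandwidth = 1) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 10) stop("need at least 10 observations")
  if (any(pairs <= 0 | pairs >= 1)) stop("pseudo-observations must lie in (0, 1)")
  iu <- pmin(pmax(ceiling(pairs[, 1] * G), 1L), G)
  iv <- pmin(pmax(ceiling(pairs[, 2] * G), 1L), G)
  counts <- matrix(0, G, G)
  tab <- table(factor(iu, levels = 1:G), factor(iv, levels = 1:G))
  counts <- matrix(as.numeric(tab), G, G)
  if (max(counts) == nrow(pairs)) {
    warning("all mass in a single grid cell: near-delta density")
  }
  dens <- gaussian_smooth(counts, bandwidth)
  dens <- dens / mean(dens)
  new_pair_copula("histogram_fallback", dens, G,
                  meta = list(n = nrow(pairs), bandwidth = bandwidth))
}

#' Flow-based copula density estimator with random hyperparameter search
#'
#' Fits a rational-quadratic spline coupling flow (uniform base) to
#' pseudo-observations by maximum likelihood. Hyperparameters (spline knots,
#' coupling layers, hidden units) are drawn at random from `search_space`;
#' each candidate is trained on a `train_fraction` split and scored by
#' log-likelihood on the held-out remainder (10 percent by default), and the
#' best-scoring model is returned. Samples smaller than `min_n` are routed
#' to [fit_copula_fallback()] (flows overfit tiny conditional strata).
#'
#' @param pairs n x 2 matrix of pseudo-observations in (0, 1).
#' @param search_space named list of candidate values for `n_knots`,
#'   `n_layers`, `hidden_units`.
#' @param n_trials number of random-search draws.
#' @param seed integer seed (initialization, splits, batching).
#' @param G grid size of the cached density grid.
#' @param config a [flow_config()] supplying the remaining training
#'   settings.
#' @param min_n routing threshold below which the fallback estimator is
#'   used.
#' @return a `pair_copula` of kind `"flow"` (or `"histogram_fallback"` for
#'   small samples).
#' @export
fit_copula_flow <- function(pairs,
                            search_space = list(n_knots = c(4, 8, 16),
                                                n_layers = c(2, 4),
                                                hidden_units = c(32, 64)),
                            n_trials = 10, seed = NULL, G = 100,
                            config = flow_config(), min_n = 200) {
  pairs <- as.matrix(pairs)
  n <- nrow(pairs)
  if (n < min_n) {
    return(fit_copula_fallback(pairs, G = G))
  }
  if (any(pairs <= 0 | pairs >= 1)) stop("pseudo-observations must lie in (0, 1)")
  if (!is.null(seed)) local_seed(seed)
  idx <- sample.int(n)
  n_train <- max(1, floor(config$train_fraction * n))
  train <- pairs[idx[seq_len(n_train)], , drop = FALSE]
  valid <- pairs[idx[-seq_len(n_train)], , drop = FALSE]
  best <- NULL
  for (trial in seq_len(max(1, n_trials))) {
    cfg <- config
    pick <- function(x) if (length(x) == 1) x else sample(x, 1)
    cfg$n_knots <- pick(search_space$n_knots %||% config$n_knots)
    cfg$n_layers <- pick(search_space$n_layers %||% config$n_layers)
    cfg$hidden_units <- pick(search_space$hidden_units %||% config$hidden_units)
    fit <- train_flow_safe(train, valid, cfg)
    if (is.null(best) || fit$val_ll > best$val_ll) best <- fit
  }
  ctr <- grid_centers(G)
  uu <- rep(ctr, times = G)
  vv <- rep(ctr, each = G)
  grid <- matrix(flow_density(best, uu, vv), G, G)
  grid <- grid / mean(grid)   # absorb discretization error
  new_pair_copula("flow", grid, G, fit = best,
                  meta = list(n = n, val_ll = best$val_ll,
                              n_knots = best$config$n_knots,
                              n_layers = best$config$n_layers,
                              hidden_units = best$config$hidden_units))
}

#' Fit a bivariate copula density
#'
#' Front-end that routes to the requested estimator. `"auto"` uses the flow
#' for large samples and the histogram fallback below the routing threshold.
#'
#' @param pairs n x 2 matrix of pseudo-observations.
#' @param estimator `"auto"`, `"flow"`, `"fallback"` or `"independence"`.
#' @param G grid size.
#' @param ... passed to the underlying estimator.
#' @return a `pair_copula`.
#' @export
fit_pair_copula <- function(pairs,
                            estimator = c("fallback", "flow", "auto",
                                          "independence"),
                            G = 100, ...) {
  estimator <- match.arg(estimator)
  switch(estimator,
    independence = independence_copula(G),
    fallback = fit_copula_fallback(pairs, G = G, ...),
    flow = ,
    auto = fit_copula_flow(pairs, G = G, ...))
}

#' Density grid of a fitted pair copula
#'
#' @param model a `pair_copula`.
#' @param G grid size; must equal the cached grid's size for grid-backed
#'   models.
#' @return `G x G` matrix of non-negative densities at cell centers, mean 1.
#' @export
density_grid <- function(model, G = model$G) {
  stopifnot(inherits(model, "pair_copula"))
  if (G == model$G) return(model$grid)
  if (model$kind == "independence") return(matrix(1, G, G))
  if (model$kind == "flow") {
    ctr <- grid_centers(G)
    g <- matrix(flow_density(model$fit, rep(ctr, times = G),
                             rep(ctr, each = G)), G, G)
    return(g / mean(g))
  }
  stop("histogram models are bound to their fitting grid (G = ", model$G, ")")
}

#' Pointwise density of a fitted pair copula
#'
#' Flow models evaluate the flow exactly; grid-backed models look up the
#' enclosing cell.
#'
#' @param model a `pair_copula`.
#' @param u,v coordinates in (0, 1).
#' @return density values.
#' @export
dpair_copula <- function(model, u, v) {
  stopifnot(inherits(model, "pair_copula"))
  if (model$kind == "independence") return(rep(1, max(length(u), length(v))))
  if (model$kind == "flow") return(flow_density(model$fit, u, v))
  G <- model$G
  iu <- pmin(pmax(ceiling(u * G), 1L), G)
  iv <- pmin(pmax(ceiling(v * G), 1L), G)
  model$grid[cbind(iu, iv)]
}

#' Conditional CDF (h-function) of a fitted pair copula
#'
#' Evaluates \eqn{h(x|y) = \partial C(x, y)/\partial y}, the CDF of one
#' coordinate given the other, by numeric integration of the model's density
#' grid along the free coordinate at the conditioning value, normalized by
#' the full conditional mass. This route is estimator-agnostic and is
#' validated against closed-form parametric h-functions. `direction =
#' "forward"` conditions on the second coordinate (`h(x|y)`); `"backward"`
#' conditions on the first (`h(y|x)`, arguments in the same order).
#'
#' @param model a `pair_copula`.
#' @param x evaluated coordinate(s) in (0, 1).
#' @param y conditioning coordinate(s) in (0, 1).
#' @param direction `"forward"` or `"backward"`.
#' @return values in `[0, 1]`, non-decreasing in `x` at fixed `y`.
#' @export
h_function <- function(model, x, y, direction = c("forward", "backward")) {
  stopifnot(inherits(model, "pair_copula"))
  direction <- match.arg(direction)
  nn <- max(length(x), length(y))
  x <- rep_len(x, nn); y <- rep_len(y, nn)
  if (any(x <= 0 | x >= 1 | y <= 0 | y >= 1)) {
    stop("h-function arguments must lie in (0, 1)")
  }
  if (model$kind == "independence") return(x)
  G <- model$G
  grid <- model$grid
  # conditioning coordinate: interpolate linearly between the two nearest
  # cell-center slices (clamped at the boundary cells)
  pos_y <- pmin(pmax(y * G + 0.5, 1), G)
  b_lo <- pmin(pmax(floor(pos_y), 1L), G - 1L)
  wy <- pos_y - b_lo
  slice_cdf <- function(b) {
    slice <- if (direction == "forward") grid[, b] else grid[b, ]
    c(0, cumsum(slice)) / sum(slice)  # conditional CDF at cell right edges
  }
  eval_at <- function(cum, xs) {
    pos <- xs * G
    j <- pmin(pmax(floor(pos), 0), G - 1)
    frac <- pos - j
    cum[j + 1] + frac * (cum[j + 2] - cum[j + 1])
  }
  out <- numeric(nn)
  for (b in unique(b_lo)) {
    sel <- which(b_lo == b)
    h_lo <- eval_at(slice_cdf(b), x[sel])
    h_hi <- eval_at(slice_cdf(b + 1L), x[sel])
    out[sel] <- (1 - wy[sel]) * h_lo + wy[sel] * h_hi
  }
  pmin(pmax(out, 0), 1)
}

#' Read and write density archives
#'
#' Stores a list of density grids with metadata (pair labels, tree level,
#' estimator kind, grid size) in a single RDS container.
#'
#' @param grids named list of `G x G` matrices.
#' @param meta data.frame of per-grid metadata (one row per grid).
#' @param path file path (`.rds`).
#' @return `read_density_archive` returns `list(grids, meta, G)`.
#' @export
write_density_archive <- function(grids, meta, path) {
  stopifnot(is.list(grids), nrow(meta) == length(grids))
  G <- if (length(grids)) nrow(grids[[1]]) else NA_integer_
  saveRDS(list(grids = grids, meta = meta, G = G), path)
  invisible(path)
}

#' @rdname write_density_archive
#' @export
read_density_archive <- function(path) {
  readRDS(path)
}
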