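#' Benchmark specification for the copula-module validation study
#'
#' Defines the parametric ground-truth study: matrices whose rows are
#' estimated copula densities of Poisson-margin pairs coupled by known
#' parametric copulas. The three cases hold 2, 4 or 6 distinct densities
#' (20 rows each): case 2 is Frank(6) and Clayton(5); case 4 adds their
#' 90-degree rotations; case 6 further adds Clayton rotated 180 and 270
#' degrees.
#'
#' @param case 2, 4 or 6 distinct copula densities.
#' @param rows_per_family rows per density (default 20).
#' @param samples_per_copula pairs sampled per row (default 20000).
#' @param grid_size density grid size (default 100).
#' @param poisson_rate shared Poisson margin rate (default 2).
#' @return a `benchmark_spec` list (with the ordered family list).
#' @export
benchmark_spec <- function(case = c(2, 4, 6), rows_per_family = 20,
                           samples_per_copula = 20000, grid_size = 100,
                           poisson_rate = 2) {
  case <- match.arg(as.character(case[1]), c("2", "4", "6"))
  case <- as.integer(case)
  fams <- list(
    parametric_copula("frank", 6),
    parametric_copula("clayton", 5),
    parametric_copula("frank", 6, rotation = 90),
    parametric_copula("clayton", 5, rotation = 90),
    parametric_copula("clayton", 5, rotation = 180),
    parametric_copula("clayton", 5, rotation = 270))[seq_len(case)]
  structure(list(case = case, families = fams,
                 rows_per_family = rows_per_family,
                 samples_per_copula = samples_per_copula,
                 grid_size = grid_size, poisson_rate = poisson_rate),
            class = "benchmark_spec")
}

#' Generate a copula-density benchmark matrix
#'
#' For every row: sample the row's parametric copula, push both coordinates
#' through Poisson quantiles to obtain dependent counts, map the counts back
#' to copula space with the distributional transform (empirical margins),
#' estimate the copula density, and vectorize the grid. Ground truths are
#' the analytic densities on the same grid.
#'
#' @param spec a [benchmark_spec()].
#' @param estimator `"fallback"` (fast, default) or `"flow"`.
#' @param seed integer seed; rows get derived seeds.
#' @param ... passed to the density estimator.
#' @return list with `X` (rows x G^2 density matrix), `V` (tail-emphasis
#'   weights from each row's empirical count margins, see
#'   [copula_weights()]), `truth` (list of analytic grids, one per family),
#'   `labels` (family label per row) and `G`.
#' @examples
#' \donttest{
#' bench <- make_benchmark(benchmark_spec(2, samples_per_copula = 2000),
#'                         seed = 1)
#' dim(bench$X)  # 40 x 10000
#' }
#' @export
make_benchmark <- function(spec, estimator = c("fallback", "flow"),
                           seed = 1, ...) {
  stopifnot(inherits(spec, "benchmark_spec"))
  estimator <- match.arg(estimator)
  G <- spec$grid_size
  n_rows <- spec$case * spec$rows_per_family
  X <- matrix(0, n_rows, G * G)
  V <- matrix(0, n_rows, G * G)
  labels <- character(n_rows)
  row <- 0L
  for (f in seq_along(spec$families)) {
    fam <- spec$families[[f]]
    for (r in seq_len(spec$rows_per_family)) {
      row <- row + 1L
      rs <- child_seed(seed, row)
      uv <- rcopula(fam, spec$samples_per_copula, seed = rs)
      local_seed(child_seed(rs, 1))
      counts <- cbind(qpois(uv[, 1], spec$poisson_rate),
                      qpois(uv[, 2], spec$poisson_rate))
      U <- pseudo_obs(counts)
      margins <- attr(U, "margins")
      model <- fit_pair_copula(U, estimator = estimator, G = G, ...)
      X[row, ] <- as.vector(density_grid(model, G))
      V[row, ] <- as.vector(build_weight_row(margins[[1]], margins[[2]],
                                             G = G))
      labels[row] <- format(fam)
    }
  }
  truth <- lapply(spec$families, density_parametric, G = G)
  names(truth) <- vapply(spec$families, format, "")
  # discretization-matched ground truth: what estimates of count-derived
  # pseudo-observations converge to (see discretized_density_parametric)
  truth_disc <- lapply(spec$families, discretized_density_parametric,
                       rate = spec$poisson_rate, G = G)
  names(truth_disc) <- names(truth)
  rownames(X) <- paste0(labels, "_", seq_len(n_rows))
  list(X = X, V = V, truth = truth, truth_disc = truth_disc,
       labels = labels, G = G, spec = spec)
}

#' Synthetic count population specification
#'
#' Describes a hub-structured population of count variables: listed pairs
#' are coupled through parametric copulas (a forest oriented away from hub
#' roots, consistent with a C-vine surface tree); unlisted pairs are
#' independent. Margins are Poisson.
#'
#' @param d number of variables.
#' @param n_obs number of observations (trial bins).
#' @param edges list of `list(i, j, copula)` entries
#'   ([parametric_copula()] objects); default empty (all independent).
#' @param rates Poisson rate per variable (recycled; default 2).
#' @return a `population_spec` list.
#' @export
synthetic_population_spec <- function(d, n_obs, edges = list(),
                                      rates = 2) {
  stopifnot(d >= 1, n_obs >= 2)
  for (e in edges) {
    if (length(e) < 3 || !inherits(e[[3]], "parametric_copula")) {
      stop("each edge must be list(i, j, parametric_copula)")
    }
    if (any(c(e[[1]], e[[2]]) < 1) || any(c(e[[1]], e[[2]]) > d)) {
      stop("edge references a variable outside 1..d")
    }
  }
  structure(list(d = d, n_obs = n_obs, edges = edges,
                 rates = rep_len(rates, d)),
            class = "population_spec")
}

#' Generate a synthetic count population
#'
#' Samples the dependence graph on the unit hypercube by conditional
#' inversion: each connected component of the edge graph must be a tree
#' (cycles are rejected: they cannot be realized by a C-vine surface
#' structure); the component is rooted at its highest-degree node and
#' children are drawn from the inverse h-function of their edge copula
#' given the parent. Counts are Poisson quantiles of the uniform
#' coordinates.
#'
#' @param spec a [synthetic_population_spec()].
#' @param seed integer seed.
#' @return `n_obs x d` integer count matrix.
#' @examples
#' spec <- synthetic_population_spec(3, 500, edges = list(
#'   list(1, 2, parametric_copula("clayton", 5))))
#' x <- generate_population(spec, seed = 1)
#' @export
generate_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) local_seed(seed)
  d <- spec$d; n <- spec$n_obs
  adj <- vector("list", d)
  for (e in spec$edges) {
    i <- e[[1]]; j <- e[[2]]
    adj[[i]] <- c(adj[[i]], list(list(to = j, cop = e[[3]], flip = FALSE)))
    adj[[j]] <- c(adj[[j]], list(list(to = i, cop = e[[3]], flip = TRUE)))
  }
  if (length(spec$edges)) {
    n_comp <- components_count(d, spec$edges)
    if (length(spec$edges) != d - n_comp) {
      stop("dependence graph contains a cycle: not a C-vine-consistent forest")
    }
  }
  U <- matrix(NA_real_, n, d)
  visited <- rep(FALSE, d)
  deg <- vapply(adj, length, 1L)
  for (root in order(-deg)) {
    if (visited[root]) next
    visited[root] <- TRUE
    U[, root] <- stats::runif(n)
    queue <- list(root)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (ed in adj[[v]]) {
        if (visited[[ed$to]]) next
        visited[[ed$to]] <- TRUE
        U[, ed$to] <- hinv_copula(ed$cop, stats::runif(n), U[, v],
                                  conditioned_on = if (ed$flip) "second" else "first")
        queue <- c(queue, list(ed$to))
      }
    }
  }
  counts <- vapply(seq_len(d), function(j) qpois(U[, j], spec$rates[j]),
                   numeric(n))
  storage.mode(counts) <- "integer"
  colnames(counts) <- paste0("v", seq_len(d))
  counts
}

# Number of connected components of the edge graph on d nodes (union-find).
components_count <- function(d, edges) {
  parent <- seq_len(d)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (e in edges) {
    a <- find(e[[1]]); b <- find(e[[2]])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(d), find, numeric(1))))
}
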