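#' Number of pair copulas in a d-dimensional vine
#'
#' A full vine on `d` variables contains `d(d-1)/2` bivariate (conditional)
#' copulas.
#'
#' @param d number of variables (>= 2).
#' @return integer count.
#' @examples
#' count_pair_copulas(102)  # 5151
#' @export
count_pair_copulas <- function(d) {
  if (any(d < 2) || any(d != round(d))) stop("d must be an integer >= 2")
  d * (d - 1) / 2
}

#' C-vine root ordering by Kendall tau sums
#'
#' Orders variables by descending \eqn{\sum_j |\tau_{ij}|}: the variable
#' most strongly rank-correlated with the rest becomes the first root, the
#' hub of the surface tree. Ties are broken by original column index. The
#' ordering is computed once on the raw pseudo-observations and fixed across
#' trees.
#'
#' @param u n x d matrix of pseudo-observations.
#' @return integer permutation of `1:d`.
#' @export
order_variables <- function(u) {
  u <- as.matrix(u)
  d <- ncol(u)
  if (d < 2) stop("need at least 2 variables")
  tausum <- numeric(d)
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      tau <- .kendall_tau_cpp(u[, i], u[, j])
      if (is.na(tau)) tau <- 0
      tausum[i] <- tausum[i] + abs(tau)
      tausum[j] <- tausum[j] + abs(tau)
    }
  }
  order(-tausum, seq_len(d))
}

#' Two-sample 2-D Kolmogorov-Smirnov independence test
#'
#' Compares an empirical copula sample against `m_uniform` seeded uniform
#' draws on the unit square with the two-sample Fasano-Franceschini
#' statistic (the largest discrepancy between the two samples' empirical
#' fractions over the four quadrants anchored at every pooled point), with a
#' label-permutation p-value. A pair is deemed independent when the test
#' does not reject at level `alpha`.
#'
#' @param pairs n x 2 matrix of pseudo-observations (n >= 20).
#' @param alpha significance level (default 0.05).
#' @param m_uniform size of the uniform reference sample (default `n`).
#' @param n_perm number of label permutations (default 199).
#' @param seed integer seed for the reference draws and permutations.
#' @param reference optional explicit reference sample (n x 2) replacing the
#'   uniform draws.
#' @return list with `statistic`, `p_value`, `is_independent`.
#' @export
independence_test <- function(pairs, alpha = 0.05, m_uniform = nrow(pairs),
                              n_perm = 199, seed = NULL, reference = NULL) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 20) stop("need at least 20 observations")
  if (!is.null(seed)) local_seed(seed)
  if (is.null(reference)) {
    reference <- cbind(stats::runif(m_uniform), stats::runif(m_uniform))
  }
  res <- .ks2d_perm_cpp(c(pairs[, 1], reference[, 1]),
                        c(pairs[, 2], reference[, 2]),
                        nrow(pairs), n_perm)
  list(statistic = res$statistic, p_value = res$p_value,
       is_independent = res$p_value > alpha)
}

# Enumerate the edges of a C-vine with the given root sequence: tree t links
# the t-th root to every later variable, conditioned on the first t-1 roots.
cvine_edges <- function(d) {
  edges <- vector("list", count_pair_copulas(d))
  e <- 0L
  for (t in seq_len(d - 1)) {
    for (j in (t + 1):d) {
      e <- e + 1L
      edges[[e]] <- list(tree = t, root = t, partner = j,
                         conditioning = if (t > 1) seq_len(t - 1) else integer(0))
    }
  }
  edges
}

#' Fit a C-vine copula with independence pruning
#'
#' Sequential tree-by-tree estimation on the unit hypercube. Variables are
#' ordered once by [order_variables()]; tree 1 fits each (root, partner)
#' pair on the raw pseudo-observations; for deeper trees, conditional
#' pseudo-observations are produced by the h-functions of the previous
#' tree's models (the simplifying assumption pools all observations, so the
#' sample size never shrinks). Every edge is first screened with
#' [independence_test()]; edges that pass are assigned the independence
#' copula, whose h-function is the identity, so their arguments pass through
#' unchanged and no density is estimated for them.
#'
#' @param u n x d matrix of pseudo-observations (n >= 100, d >= 2).
#' @param alpha independence-test level (default 0.05; per-edge, no
#'   multiple-testing correction).
#' @param estimator `"fallback"` or `"flow"` (see [fit_pair_copula()]).
#' @param G density grid size.
#' @param n_perm permutations for the independence test.
#' @param m_uniform uniform reference sample size (default `n`).
#' @param seed integer seed; per-edge seeds are derived deterministically.
#' @param max_trees optionally stop after this many trees (deeper edges are
#'   then marked independent without testing); `NULL` fits the full vine.
#' @param ... passed on to the pair-copula estimator.
#' @return An object of class `cvine` with the root ordering, per-edge
#'   records (tree, variables, conditioning set, p-value, independence
#'   flag) and fitted `pair_copula` models for non-independent edges.
#' @examples
#' \donttest{
#' x <- generate_population(synthetic_population_spec(d = 4, n_obs = 400),
#'                          seed = 1)
#' fit <- fit_cvine(pseudo_obs(x, seed = 2), seed = 3)
#' summary(fit)
#' }
#' @export
fit_cvine <- function(u, alpha = 0.05, estimator = c("fallback", "flow"),
                      G = 100, n_perm = 199, m_uniform = nrow(u),
                      seed = NULL, max_trees = NULL, ...) {
  u <- as.matrix(u)
  estimator <- match.arg(estimator)
  n <- nrow(u); d <- ncol(u)
  if (d < 2) stop("need at least 2 variables")
  if (n < 100) stop("need at least 100 observations")
  if (is.null(seed)) seed <- floor(stats::runif(1, 1, 2^30))
  labels <- colnames(u) %||% paste0("v", seq_len(d))
  ord <- order_variables(u)
  ucur <- u[, ord, drop = FALSE]
  edges <- cvine_edges(d)
  models <- vector("list", length(edges))
  max_trees <- max_trees %||% (d - 1)
  e <- 0L
  for (t in seq_len(d - 1)) {
    unext <- ucur
    for (j in (t + 1):d) {
      e <- e + 1L
      pair <- cbind(ucur[, t], ucur[, j])
      if (t > max_trees) {
        edges[[e]]$p_value <- NA_real_
        edges[[e]]$independent <- TRUE
        models[[e]] <- independence_copula(G)
        next
      }
      it <- independence_test(pair, alpha = alpha, m_uniform = m_uniform,
                              n_perm = n_perm, seed = child_seed(seed, e))
      edges[[e]]$p_value <- it$p_value
      edges[[e]]$independent <- it$is_independent
      if (it$is_independent) {
        models[[e]] <- independence_copula(G)
        # h(x, y) = x: conditional values pass through unchanged
      } else {
        models[[e]] <- fit_pair_copula(pair, estimator = estimator, G = G,
                                       ...)
        hval <- h_function(models[[e]], x = pair[, 2], y = pair[, 1],
                           direction = "backward")
        bad <- hval <= 0 | hval >= 1
        if (any(bad)) {
          warning(sum(bad), " conditional pseudo-observations clipped into (0,1)")
          hval <- pmin(pmax(hval, 1e-6), 1 - 1e-6)
        }
        # re-uniformize: estimator bias in h leaves the conditional margin
        # slightly non-uniform, which deeper-tree independence tests would
        # mistake for dependence; the rank transform removes it
        unext[, j] <- rank(hval, ties.method = "average") / (n + 1)
      }
    }
    ucur <- unext
  }
  structure(list(order = ord, labels = labels, edges = edges,
                 models = models, d = d, n = n, alpha = alpha,
                 estimator = estimator, G = G, seed = seed),
            class = "cvine")
}

#' @export
print.cvine <- function(x, ...) {
  n_indep <- sum(vapply(x$edges, `[[`, TRUE, "independent"))
  cat(sprintf("C-vine on %d variables (%d observations): %d pair copulas, %d independent, %d fitted [%s]\n",
              x$d, x$n, length(x$edges), n_indep,
              length(x$edges) - n_indep, x$estimator))
  invisible(x)
}

#' @export
summary.cvine <- function(object, ...) {
  tr <- vapply(object$edges, `[[`, 1L, "tree")
  ind <- vapply(object$edges, `[[`, TRUE, "independent")
  tab <- data.frame(tree = sort(unique(tr)),
                    edges = as.vector(table(tr)),
                    independent = as.vector(tapply(ind, tr, sum)))
  print(object)
  print(tab, row.names = FALSE)
  invisible(tab)
}

# Human-readable edge label in original variable names.
edge_label <- function(fit, edge) {
  vars <- fit$labels[fit$order]
  lab <- paste0(vars[edge$root], ",", vars[edge$partner])
  if (length(edge$conditioning)) {
    lab <- paste0(lab, "|", paste(vars[edge$conditioning], collapse = ","))
  }
  lab
}

#' Density matrix of the non-independent vine copulas
#'
#' Vectorizes (column-major) the density grid of every non-independent edge
#' into the rows of a matrix, the input of the factorization stage.
#'
#' @param fit a [fit_cvine()] object.
#' @return list with `X` (n_pairs x G^2 matrix, with edge labels as row
#'   names), `meta` (data.frame: edge index, tree, root/partner in original
#'   labels), and `G`.
#' @export
density_matrix <- function(fit) {
  stopifnot(inherits(fit, "cvine"))
  keep <- which(!vapply(fit$edges, `[[`, TRUE, "independent"))
  G <- fit$G
  X <- matrix(0, length(keep), G * G)
  meta <- data.frame(edge = keep,
                     tree = vapply(fit$edges[keep], `[[`, 1L, "tree"),
                     label = vapply(keep, function(e)
                       edge_label(fit, fit$edges[[e]]), ""),
                     root = vapply(fit$edges[keep], function(e)
                       fit$order[e$root], 1L),
                     partner = vapply(fit$edges[keep], function(e)
                       fit$order[e$partner], 1L))
  for (i in seq_along(keep)) {
    X[i, ] <- as.vector(density_grid(fit$models[[keep[i]]], G))
  }
  rownames(X) <- meta$label
  list(X = X, meta = meta, G = G)
}

#' Serialize a fitted C-vine to JSON
#'
#' Writes the ordering, edge records and test results (not the density
#' models; use [write_density_archive()] for grids) following the schema in
#' `inst/schema/vine.schema.json`.
#'
#' @param fit a `cvine` object.
#' @param path output path.
#' @export
vine_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "cvine"))
  doc <- list(
    d = fit$d, n = fit$n, alpha = fit$alpha, estimator = fit$estimator,
    grid_size = fit$G, order = fit$order, labels = fit$labels,
    edges = lapply(seq_along(fit$edges), function(e) {
      ed <- fit$edges[[e]]
      list(index = e, tree = ed$tree, root = fit$order[ed$root],
           partner = fit$order[ed$partner],
           conditioning = as.integer(fit$order[ed$conditioning]),
           p_value = ed$p_value, independent = ed$independent,
           label = edge_label(fit, ed))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
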