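#' Tail-emphasis profile of a count margin
#'
#' The absolute gap between a margin's quantile function and the uniform
#' quantile, \eqn{g(u) = |F^{-1}(u) - u|}, evaluated at the grid cell
#' centers. For skewed count margins the gap grows towards the probability
#' range occupied by rare large counts, so the outer product of two profiles
#' (summed with its rotations) concentrates weight in the corners of copula
#' space. A continuous-uniform margin gives the identically zero profile.
#' The quantile is taken in count units; the final weight row is normalized
#' to maximum 1, so the profile's scale drops out.
#'
#' @param margin an [empirical_margin()], or a quantile function `Q(u)`.
#' @param G grid size.
#' @return numeric vector of length `G`.
#' @export
weight_profile_quantile <- function(margin, G = 100) {
  u <- grid_centers(G)
  q <- if (is.function(margin)) margin(u) else margin_quantile(margin, u)
  abs(q - u)
}

#' Tail-emphasis weight row for a neuron pair
#'
#' Builds the per-pair weight matrix used by [wnmf()] from the two count
#' margins: the outer product of the margins' tail profiles is summed with
#' its 90/180/270-degree rotations (so all four corners of copula space are
#' emphasized), smoothed with a Gaussian window (`sigma` bins, so weights
#' transition smoothly between high- and low-importance regions), floored
#' at a small positive fraction of the maximum (keeping multiplicative
#' updates well-defined everywhere) and normalized to maximum 1.
#'
#' @param margin_x,margin_y [empirical_margin()] objects (or quantile
#'   functions) of the two variables.
#' @param G grid size (>= 8).
#' @param sigma Gaussian window standard deviation in grid bins (default 5).
#' @param floor_frac strictly positive baseline, as a fraction of the row
#'   maximum (default `1e-3`).
#' @param profile profile hook: a function `(margin, G) -> numeric(G)`
#'   (default [weight_profile_quantile()]).
#' @return `G x G` matrix with entries in `(0, 1]`, maximum exactly 1. For
#'   identical margins the matrix is symmetric and invariant under
#'   90-degree rotation.
#' @export
build_weight_row <- function(margin_x, margin_y, G = 100, sigma = 5,
                             floor_frac = 1e-3,
                             profile = weight_profile_quantile) {
  stopifnot(G >= 8, sigma > 0)
  degenerate <- function(m) {
    inherits(m, "empirical_margin") && length(m$support) == 1
  }
  if (degenerate(margin_x) || degenerate(margin_y)) {
    warning("degenerate margin (single support point): flat weight row")
    return(matrix(1, G, G))
  }
  gx <- profile(margin_x, G)
  gy <- profile(margin_y, G)
  M <- outer(gx, gy)
  S <- M
  A <- M
  for (r in 1:3) {
    A <- rot90_grid(A)
    S <- S + A
  }
  S <- gaussian_smooth(S, sigma)
  if (max(S) <= 0) return(matrix(1, G, G))  # uniform-like margins
  S <- pmax(S, floor_frac * max(S))
  S / max(S)
}

#' Weight matrix aligned with a density matrix
#'
#' One vectorized weight row per density row, built with
#' [build_weight_row()] from the margins of the two variables in each pair.
#'
#' @param margins list of [empirical_margin()] objects, indexed by variable.
#' @param pairs two-column matrix (or data.frame) of variable indices, one
#'   row per density row.
#' @param G grid size.
#' @param ... passed to [build_weight_row()].
#' @return n_pairs x G^2 matrix of strictly positive weights.
#' @export
copula_weights <- function(margins, pairs, G = 100, ...) {
  pairs <- as.matrix(pairs)
  V <- matrix(0, nrow(pairs), G * G)
  for (i in seq_len(nrow(pairs))) {
    V[i, ] <- as.vector(build_weight_row(margins[[pairs[i, 1]]],
                                         margins[[pairs[i, 2]]], G = G, ...))
  }
  V
}

nmf_init <- function(X, k, seed) {
  local_seed(seed)
  scale <- sqrt(mean(X) / k)
  list(W = matrix(stats::runif(nrow(X) * k), nrow(X), k) * scale,
       H = matrix(stats::runif(k * ncol(X)), k, ncol(X)) * scale)
}

new_nmf_fit <- function(core, X, k, weighted, alpha1, alpha2, seed) {
  W <- core$W; H <- core$H
  rownames(W) <- rownames(X)
  structure(list(W = W, H = H, objective = core$objective,
                 iterations = core$iterations, k = k, weighted = weighted,
                 alpha1 = alpha1, alpha2 = alpha2, seed = seed,
                 dims = dim(X)),
            class = "nmf_fit")
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `X` (rows = vectorized copula densities)
#' into non-negative coefficients `W` (`n x k`) and modules `H` (`k x G^2`)
#' by minimizing the Frobenius reconstruction error with the classical
#' multiplicative update rules, from a seeded random initialization.
#' `n_restarts > 1` reruns from different seeded initializations and keeps
#' the fit with the lowest final objective.
#'
#' @param X non-negative matrix.
#' @param k factorization rank.
#' @param max_iter maximum update iterations.
#' @param tol relative objective change for early stopping.
#' @param seed integer seed.
#' @param n_restarts number of seeded restarts (default 1).
#' @return An object of class `nmf_fit` with `W`, `H`, the per-iteration
#'   `objective` trace, and the fitting configuration. Methods: `print`,
#'   `summary`, `coef` (returns `W`), `fitted` (returns `WH`), `residuals`,
#'   `predict` (reconstruction for new coefficient rows), `plot` (module
#'   heatmaps).
#' @examples
#' X <- matrix(runif(200), 20, 10)
#' f <- nmf(X, k = 2, seed = 1)
#' dim(coef(f))
#' @export
nmf <- function(X, k, max_iter = 500, tol = 1e-6, seed = 1, n_restarts = 1) {
  wnmf(X, V = NULL, k = k, alpha1 = 0, alpha2 = 0, max_iter = max_iter,
       tol = tol, seed = seed, n_restarts = n_restarts)
}

#' Weighted non-negative matrix factorization
#'
#' Multiplicative updates in which every entry of the reconstruction error
#' is scaled by a strictly positive weight matrix `V` (here: tail-emphasis
#' weights from [copula_weights()]), with optional L1/L2 regularization of
#' both factors: numerators and denominators of the update rules carry `V`
#' elementwise, and the denominators additionally receive
#' `alpha1 + alpha2 * entry`. With `V` identically 1 and zero penalties the
#' iterates coincide with [nmf()]. `mask` entries equal to 0 are treated as
#' missing (speckled holdout): they are removed from both the weights and
#' the residual.
#'
#' @param X non-negative matrix (n_pairs x G^2).
#' @param V strictly positive weights, same shape as `X`; `NULL` for
#'   all-ones (unweighted).
#' @param k rank.
#' @param alpha1 L1 penalty strength.
#' @param alpha2 L2 penalty strength.
#' @param mask optional 0/1 matrix, 0 = held out.
#' @param max_iter,tol,seed,n_restarts as in [nmf()].
#' @param obj_every record the objective (and test convergence) every this
#'   many iterations; 1 evaluates it after every update pair. Larger strides
#'   skip the objective's full reconstruction pass and speed up long runs;
#'   `tol` then refers to the relative change across the stride.
#' @return an object of class `nmf_fit`; its `objective` trace is the
#'   weighted, penalized objective
#'   \eqn{\sum V (X - WH)^2 + \alpha_1(|W|+|H|) + \alpha_2(\|W\|^2+\|H\|^2)/2}.
#' @export
wnmf <- function(X, V, k, alpha1 = 0, alpha2 = 0, mask = NULL,
                 max_iter = 500, tol = 1e-6, seed = 1, n_restarts = 1,
                 obj_every = 1) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  if (k < 1 || k > min(dim(X))) stop("k must lie in 1..min(dim(X))")
  weighted <- !is.null(V)
  if (is.null(V)) {
    V <- matrix(1, nrow(X), ncol(X))
  } else {
    V <- as.matrix(V)
    if (!all(dim(V) == dim(X))) stop("V must match X in shape")
    if (any(V <= 0)) stop("V must be strictly positive")
  }
  M <- if (is.null(mask)) matrix(numeric(0), 0, 0) else as.matrix(mask)
  best <- NULL
  for (r in seq_len(max(1, n_restarts))) {
    init <- nmf_init(X, k, child_seed(seed, r - 1))
    core <- .nmf_core_cpp(X, V, M, init$W, init$H, alpha1, alpha2,
                          as.integer(max_iter), tol, 1e-12,
                          as.integer(obj_every))
    if (is.null(best) ||
        utils::tail(core$objective, 1) < utils::tail(best$objective, 1)) {
      best <- core
    }
  }
  new_nmf_fit(best, X, k, weighted, alpha1, alpha2, seed)
}

# Pure-R reference of the multiplicative update rules (used in tests as an
# independent route for the compiled core).
nmf_updates_r <- function(X, W, H, V = NULL, alpha1 = 0, alpha2 = 0,
                          n_iter = 1, eps = 1e-12) {
  if (is.null(V)) V <- matrix(1, nrow(X), ncol(X))
  for (i in seq_len(n_iter)) {
    W <- W * ((V * X) %*% t(H)) /
      ((V * (W %*% H)) %*% t(H) + alpha1 + alpha2 * W + eps)
    H <- H * (t(W) %*% (V * X)) /
      (t(W) %*% (V * (W %*% H)) + alpha1 + alpha2 * H + eps)
  }
  list(W = W, H = H)
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("%s fit: rank %d on a %d x %d matrix, %d iterations, final objective %.6g\n",
              if (x$weighted) "WNMF" else "NMF", x$k, x$dims[1], x$dims[2],
              x$iterations, utils::tail(x$objective, 1)))
  invisible(x)
}

#' @export
summary.nmf_fit <- function(object, ...) {
  print(object)
  dom <- apply(object$W, 1, which.max)
  cat("rows per dominant module:",
      paste(sprintf("%d:%d", seq_len(object$k), tabulate(dom, object$k)),
            collapse = "  "), "\n")
  invisible(object)
}

#' @export
coef.nmf_fit <- function(object, ...) object$W

#' @export
fitted.nmf_fit <- function(object, ...) object$W %*% object$H

#' @export
residuals.nmf_fit <- function(object, X, ...) X - fitted(object)

#' @export
predict.nmf_fit <- function(object, newcoef = NULL, ...) {
  if (is.null(newcoef)) return(fitted(object))
  as.matrix(newcoef) %*% object$H
}

#' @export
plot.nmf_fit <- function(x, G = NULL, ...) {
  G <- G %||% as.integer(round(sqrt(ncol(x$H))))
  op <- graphics::par(mfrow = c(1, x$k), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  for (m in seq_len(x$k)) {
    graphics::image(matrix(x$H[m, ], G, G), main = paste("module", m),
                    useRaster = TRUE, ...)
  }
  invisible(x)
}

#' Group coefficient rows by dominant module
#'
#' Orders the rows of a coefficient matrix by their argmax module, and
#' within each group by descending coefficient; all-zero rows go last. Ties
#' keep original order.
#'
#' @param W non-negative coefficient matrix.
#' @return integer row ordering.
#' @export
sort_coefficients <- function(W) {
  W <- as.matrix(W)
  zero <- rowSums(W) == 0
  dom <- apply(W, 1, which.max)
  val <- W[cbind(seq_len(nrow(W)), dom)]
  grp <- ifelse(zero, ncol(W) + 1L, dom)
  order(grp, ifelse(zero, 0, -val), seq_len(nrow(W)))
}

#' Match factorization modules to ground-truth densities
#'
#' Finds the one-to-one assignment between the rows of `H` (reshaped,
#' rescaled to mean 1 as copula densities are) and a list of ground-truth
#' density grids that minimizes the total mean squared error; the assignment
#' is solved exactly by enumeration (`k <= 9`).
#'
#' @param H k x G^2 module matrix.
#' @param truth list of `k` ground-truth `G x G` grids.
#' @param rescale rescale modules (and truths) to mean 1 before comparison,
#'   absorbing the scale indeterminacy of the factorization (default TRUE).
#' @return list with `assignment` (module index per truth), `mse`
#'   (per-truth MSE under the optimal assignment) and `total_mse`.
#' @export
match_modules_to_truth <- function(H, truth, rescale = TRUE) {
  H <- as.matrix(H)
  k <- length(truth)
  if (nrow(H) != k) stop("number of modules must equal number of truths")
  if (k > 9) stop("exact assignment supported for k <= 9")
  scale_mean1 <- function(v) {
    m <- mean(v)
    if (rescale && m > 0) v / m else v
  }
  cost <- matrix(0, k, k)  # truth x module
  for (i in seq_len(k)) {
    tv <- scale_mean1(as.vector(truth[[i]]))
    for (j in seq_len(k)) {
      cost[i, j] <- mean((tv - scale_mean1(H[j, ]))^2)
    }
  }
  perms <- permutations_of(k)
  totals <- vapply(seq_len(nrow(perms)), function(p)
    sum(cost[cbind(seq_len(k), perms[p, ])]), 0)
  best <- perms[which.min(totals), ]
  list(assignment = best, mse = cost[cbind(seq_len(k), best)],
       total_mse = min(totals))
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  dimnames(out) <- NULL
  out
}
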