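#' Speckled cross-validation for factorization rank and regularization
#'
#' Holds out scattered random entries of the matrix ("speckles") in each
#' fold, treating them as missing during the multiplicative updates (the
#' holdout mask multiplies both the weights and the residual), and scores
#' the unweighted reconstruction MSE on the held-out entries. Holdout sets
#' are disjoint across folds, so each entry is held out at most once.
#' Candidate `(alpha1, alpha2)` pairs are tuned on the same folds; the
#' reported rank curve and selected rank use the best penalty pair.
#'
#' @param X non-negative matrix.
#' @param V strictly positive weight matrix or `NULL` for unweighted
#'   factorization.
#' @param ranks integer vector of candidate ranks.
#' @param n_folds number of folds (default 5).
#' @param holdout_frac fraction of entries held out per fold, in (0, 0.5)
#'   (default 0.1).
#' @param alphas list of `c(alpha1, alpha2)` candidates (default only
#'   `c(0, 0)`).
#' @param max_iter,tol,seed passed to [wnmf()]; fold masks derive from
#'   `seed`. The defaults demand near-convergence (relative objective change
#'   below `1e-6`): under-converged fits at the true rank inflate its
#'   validation error relative to higher ranks and bias rank selection
#'   upward.
#' @return An object of class `speckled_cv`: arrays `train_mse` and
#'   `val_mse` indexed `[alpha, rank, fold]`, the selected `best_alpha`,
#'   `selected_rank` (argmin of the mean validation MSE) and `plateau_rank`
#'   (the smallest rank whose mean validation MSE is within 1 percent of the
#'   minimum — the onset of the curve's plateau, which is stable when the
#'   curve is nearly flat to the right of the structural rank and the
#'   literal argmin is not), and the fold masks' seed. Methods: `print`,
#'   `plot` (rank curves).
#' @examples
#' W0 <- matrix(runif(60), 30, 2); H0 <- matrix(runif(50), 2, 25)
#' cv <- speckled_cv(W0 %*% H0, NULL, ranks = 1:4, seed = 1)
#' cv$selected_rank
#' @export
speckled_cv <- function(X, V = NULL, ranks, n_folds = 5, holdout_frac = 0.1,
                        alphas = list(c(0, 0)), max_iter = 1000, tol = 1e-6,
                        seed = 1) {
  X <- as.matrix(X)
  if (length(ranks) < 1) stop("ranks must be non-empty")
  if (holdout_frac <= 0 || holdout_frac >= 0.5) {
    stop("holdout_frac must lie in (0, 0.5)")
  }
  if (n_folds * holdout_frac > 1) stop("folds would overlap: reduce holdout_frac")
  masks <- speckle_masks(dim(X), n_folds, holdout_frac, seed)
  n_alpha <- length(alphas)
  dn <- list(alpha = vapply(alphas, paste, "", collapse = ","),
             rank = as.character(ranks), fold = as.character(seq_len(n_folds)))
  train_mse <- array(NA_real_, c(n_alpha, length(ranks), n_folds), dn)
  val_mse <- array(NA_real_, c(n_alpha, length(ranks), n_folds), dn)
  for (a in seq_len(n_alpha)) {
    for (r in seq_along(ranks)) {
      for (f in seq_len(n_folds)) {
        # stride-10 objective evaluation: the tolerance is rescaled so the
        # stopping rule matches the per-iteration tol semantics
        fit <- wnmf(X, V, k = ranks[r], alpha1 = alphas[[a]][1],
                    alpha2 = alphas[[a]][2], mask = masks[[f]],
                    max_iter = max_iter, tol = tol * 10, obj_every = 10,
                    seed = child_seed(seed, (a * length(ranks) + r) * n_folds + f))
        R2 <- (X - fit$W %*% fit$H)^2
        train_mse[a, r, f] <- mean(R2[masks[[f]] == 1])
        val_mse[a, r, f] <- mean(R2[masks[[f]] == 0])
      }
    }
  }
  mean_val <- apply(val_mse, c(1, 2), mean)
  best_a <- which.min(apply(mean_val, 1, min))
  structure(list(ranks = ranks, alphas = alphas, n_folds = n_folds,
                 holdout_frac = holdout_frac, seed = seed,
                 train_mse = train_mse, val_mse = val_mse,
                 best_alpha = alphas[[best_a]],
                 rank_curve = mean_val[best_a, ],
                 selected_rank = ranks[which.min(mean_val[best_a, ])],
                 plateau_rank = ranks[which(
                   mean_val[best_a, ] <= 1.01 * min(mean_val[best_a, ]))[1]],
                 weighted = !is.null(V)),
            class = "speckled_cv")
}

# Disjoint random entry masks (1 = observed, 0 = held out). Guards against
# any row losing all of its entries (resampled if that happens); fully
# masked columns are tolerated — with few rows and G^2 columns they are
# unavoidable, and they affect only the handful of grid cells concerned.
speckle_masks <- function(dims, n_folds, holdout_frac, seed) {
  local_seed(seed)
  N <- prod(dims)
  n_hold <- round(holdout_frac * N)
  for (attempt in 1:100) {
    perm <- sample.int(N)
    masks <- vector("list", n_folds)
    ok <- TRUE
    for (f in seq_len(n_folds)) {
      hold <- perm[((f - 1) * n_hold + 1):(f * n_hold)]
      m <- matrix(1, dims[1], dims[2])
      m[hold] <- 0
      if (any(rowSums(m) == 0)) { ok <- FALSE; break }
      masks[[f]] <- m
    }
    if (ok) return(masks)
  }
  stop("could not draw speckle masks leaving every row observed")
}

#' @export
print.speckled_cv <- function(x, ...) {
  cat(sprintf("Speckled %d-fold CV (%s, holdout %.0f%%): ranks %s\n",
              x$n_folds, if (x$weighted) "WNMF" else "NMF",
              100 * x$holdout_frac,
              paste(range(x$ranks), collapse = "-")))
  cat(sprintf("selected rank: %d (plateau onset: %d; alpha1 = %g, alpha2 = %g)\n",
              x$selected_rank, x$plateau_rank, x$best_alpha[1], x$best_alpha[2]))
  curve <- x$rank_curve
  cat("mean validation MSE by rank:\n")
  print(stats::setNames(signif(curve, 4), x$ranks))
  invisible(x)
}

#' @export
plot.speckled_cv <- function(x, ...) {
  a <- which.min(apply(apply(x$val_mse, c(1, 2), mean), 1, min))
  tr <- apply(x$train_mse, c(1, 2), mean)[a, ]
  va <- x$rank_curve
  graphics::matplot(x$ranks, cbind(tr, va), type = "b", pch = c(1, 19),
                    lty = 1, xlab = "rank", ylab = "MSE", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 19),
                   col = 1:2, lty = 1)
  graphics::abline(v = x$selected_rank, lty = 3)
  invisible(x)
}
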