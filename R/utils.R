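#' @useDynLib copulamodules, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rgamma qpois ppois setNames median
#' @importFrom utils head modifyList
NULL

# Set the RNG seed for the remainder of the calling function, restoring the
# caller's RNG state on exit.
local_seed <- function(seed, env = parent.frame()) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  do.call(on.exit,
          list(bquote(assign(".Random.seed", .(old), globalenv())),
               add = TRUE),
          envir = env)
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

# Derive a reproducible child seed from a base seed and a stream index.
child_seed <- function(seed, stream) {
  (as.double(seed) * 69069 + 12345 * as.double(stream)) %% 2147483647
}

# Rotate a square matrix by 90 degrees, consistent with the sample-space
# rotation (u, v) -> (v, 1 - u): cell (i, j) moves to (j, G + 1 - i).
rot90_grid <- function(A) t(A[nrow(A):1, , drop = FALSE])

# Separable Gaussian smoothing on a grid with kernel renormalization at the
# edges (no mass attenuation near borders).
gaussian_smooth <- function(A, sigma) {
  if (sigma <= 0) return(A)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  smooth_1d <- function(M) {
    G <- nrow(M)
    out <- matrix(0, G, ncol(M))
    wsum <- numeric(G)
    for (o in -r:r) {
      w <- k[o + r + 1]
      src <- (1:G) - o
      ok <- src >= 1 & src <= G
      out[ok, ] <- out[ok, ] + w * M[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + w
    }
    out / wsum
  }
  t(smooth_1d(t(smooth_1d(A))))
}

# Cell-center coordinates of a G x G grid on the unit square.
grid_centers <- function(G) (seq_len(G) - 0.5) / G

`%||%` <- function(a, b) if (is.null(a)) b else a
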