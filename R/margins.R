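#' Empirical margin of a count variable
#'
#' Tabulates the empirical distribution of a non-negative integer sample and
#' returns an object exposing the CDF \eqn{F(x) = \Pr(X \le x)}, its
#' left-continuous version \eqn{F^-(x) = \Pr(X < x)}, and the generalized
#' inverse quantile function \eqn{F^{-1}(u) = \min\{x : F(x) \ge u\}}. These
#' are the ingredients of the distributional transform that maps discrete
#' counts to uniform pseudo-observations.
#'
#' @param x integer vector of counts (length >= 2, all entries >= 0).
#' @return An object of class `empirical_margin` with elements `support`
#'   (sorted distinct values), `prob`, `cdf`, `cdf_left` and `n`.
#' @seealso [distributional_transform()], [pseudo_obs()]
#' @examples
#' m <- empirical_margin(c(0, 0, 1, 1))
#' margin_cdf(m, 0)       # 0.5
#' margin_quantile(m, 0.75)
#' @export
empirical_margin <- function(x) {
  if (length(x) < 2) stop("need at least 2 observations to fit a margin")
  if (anyNA(x)) stop("counts must not contain NA")
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  support <- sort(unique(x))
  prob <- as.vector(tabulate(match(x, support), nbins = length(support)))
  prob <- prob / length(x)
  cdf <- cumsum(prob)
  cdf[length(cdf)] <- 1  # guard against rounding drift
  structure(
    list(support = support, prob = prob, cdf = cdf,
         cdf_left = c(0, cdf[-length(cdf)]), n = length(x)),
    class = "empirical_margin"
  )
}

#' @export
print.empirical_margin <- function(x, ...) {
  cat("Empirical count margin: ", length(x$support), " support points in [",
      min(x$support), ", ", max(x$support), "], n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Empirical CDF, left-limit CDF and quantile function
#'
#' `margin_cdf` evaluates \eqn{F(x)=\Pr(X \le x)}, `margin_cdf_left`
#' evaluates \eqn{F^-(x)=\Pr(X < x)}, and `margin_quantile` evaluates the
#' generalized inverse \eqn{F^{-1}(u)=\min\{x : F(x) \ge u\}}.
#'
#' @param margin an [empirical_margin()] object.
#' @param x numeric vector of evaluation points.
#' @param u probabilities in `[0, 1]`.
#' @return numeric vector.
#' @export
margin_cdf <- function(margin, x) {
  idx <- findInterval(x, margin$support)
  c(0, margin$cdf)[idx + 1]
}

#' @rdname margin_cdf
#' @export
margin_cdf_left <- function(margin, x) {
  # Pr(X < x): count support strictly below x
  idx <- findInterval(x, margin$support, left.open = TRUE)
  c(0, margin$cdf)[idx + 1]
}

#' @rdname margin_cdf
#' @export
margin_quantile <- function(margin, u) {
  if (any(u < 0 | u > 1)) stop("probabilities must lie in [0, 1]")
  # smallest support value whose cdf >= u
  idx <- findInterval(u, margin$cdf, left.open = TRUE) + 1
  idx[idx > length(margin$support)] <- length(margin$support)
  margin$support[idx]
}

#' Distributional transform of discrete counts
#'
#' Maps counts to the unit interval by
#' \eqn{G(x, V) = F^-(x) + V\,(F(x) - F^-(x))} with independent uniform
#' jitters \eqn{V}: each observation is placed uniformly inside the CDF jump
#' of its value, so the output of a sample transformed with its own empirical
#' margin is uniform on (0, 1). Results are clipped to
#' `[clip, 1 - clip]` so downstream density estimators never see exact 0/1.
#'
#' @param x integer vector of counts; every value must belong to the margin's
#'   support.
#' @param margin an [empirical_margin()].
#' @param jitter uniform draws in `[0, 1)`, same length as `x`; drawn
#'   internally when `NULL` (use `set.seed()` or the `seed` argument of
#'   [pseudo_obs()] for reproducibility).
#' @param clip interior clipping margin (default `1e-6`).
#' @return numeric vector strictly inside (0, 1).
#' @export
distributional_transform <- function(x, margin, jitter = NULL, clip = 1e-6) {
  if (!inherits(margin, "empirical_margin")) stop("margin must be an empirical_margin")
  if (!all(x %in% margin$support)) {
    stop("values outside the margin's support: ",
         paste(utils::head(setdiff(x, margin$support), 5), collapse = ", "))
  }
  if (is.null(jitter)) jitter <- stats::runif(length(x))
  if (length(jitter) != length(x)) stop("jitter must match x in length")
  if (any(jitter < 0 | jitter >= 1)) stop("jitter entries must lie in [0, 1)")
  lo <- margin_cdf_left(margin, x)
  hi <- margin_cdf(margin, x)
  pmin(pmax(lo + jitter * (hi - lo), clip), 1 - clip)
}

#' Pseudo-observations of a count matrix
#'
#' Applies the distributional transform column-wise, fitting an empirical
#' margin per column. The fitted margins are attached as the `"margins"`
#' attribute for reuse (e.g., by [copula_weights()]).
#'
#' @param counts matrix of non-negative integers, rows = observations.
#' @param seed optional integer controlling the jitter stream.
#' @param clip interior clipping margin.
#' @return numeric matrix of the same shape with entries in (0, 1).
#' @examples
#' x <- matrix(rpois(200, 2), ncol = 2)
#' u <- pseudo_obs(x, seed = 1)
#' @export
pseudo_obs <- function(counts, seed = NULL, clip = 1e-6) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 observations")
  if (!is.null(seed)) local_seed(seed)
  margins <- vector("list", ncol(counts))
  U <- matrix(NA_real_, nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    margins[[j]] <- empirical_margin(counts[, j])
    U[, j] <- distributional_transform(counts[, j], margins[[j]], clip = clip)
  }
  attr(U, "margins") <- margins
  U
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall rank correlation, computed in O(n log n). Constant
#' inputs return 0 with a warning (such columns carry no dependence
#' information and are pruned by the independence test anyway).
#'
#' @param u,v numeric vectors of equal length (>= 2).
#' @return tau in `[-1, 1]`.
#' @export
kendall_tau <- function(u, v) {
  tau <- .kendall_tau_cpp(as.numeric(u), as.numeric(v))
  if (is.na(tau)) {
    warning("constant input: Kendall's tau undefined, returning 0")
    tau <- 0
  }
  tau
}

#' Read a trials-by-variables count matrix
#'
#' Accepts delimited text (`.csv`, `.tsv`/`.txt`, header row with variable
#' labels) or an RDS file containing an integer matrix. Entries are validated
#' to be non-negative integers.
#'
#' @param path file path.
#' @return integer matrix with column names.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    m <- readRDS(path)
    m <- as.matrix(m)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE)
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop("count matrix must contain only non-negative integers")
  }
  storage.mode(m) <- "integer"
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  m
}
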