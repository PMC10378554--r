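#' Pipeline configuration
#'
#' Collects every stage parameter of the counts-to-copula-modules pipeline
#' in one serializable list. A run is reproducible from its configuration
#' plus seed. Configurations round-trip through YAML via
#' [read_run_config()] / [write_run_config()].
#'
#' @param input path to a count matrix (see [read_counts()]), or `NULL`
#'   when a matrix is passed to [run_pipeline()] directly.
#' @param output directory for stage artifacts; `NULL` keeps everything in
#'   memory.
#' @param seed master seed; all stage seeds derive from it.
#' @param alpha independence-test level.
#' @param estimator `"fallback"` or `"flow"`.
#' @param grid_size density grid size.
#' @param n_perm independence-test permutations.
#' @param ranks candidate factorization ranks.
#' @param n_folds speckled CV folds.
#' @param holdout_frac held-out entry fraction per fold.
#' @param alphas list of `c(alpha1, alpha2)` penalty candidates.
#' @param n_restarts restarts for the final factorization.
#' @param weighted use tail-emphasis weights (WNMF) rather than plain NMF.
#' @param max_iter factorization iteration cap.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, output = NULL, seed = 1, alpha = 0.05,
                       estimator = "fallback", grid_size = 100,
                       n_perm = 199, ranks = 1:8, n_folds = 5,
                       holdout_frac = 0.1, alphas = list(c(0, 0)),
                       n_restarts = 10, weighted = TRUE, max_iter = 300) {
  structure(list(input = input, output = output, seed = seed, alpha = alpha,
                 estimator = estimator, grid_size = grid_size,
                 n_perm = n_perm, ranks = ranks, n_folds = n_folds,
                 holdout_frac = holdout_frac, alphas = alphas,
                 n_restarts = n_restarts, weighted = weighted,
                 max_iter = max_iter),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$ranks <- if (!is.null(raw$ranks)) as.integer(unlist(raw$ranks))
  raw$alphas <- if (!is.null(raw$alphas)) lapply(raw$alphas, as.numeric)
  raw <- raw[!vapply(raw, is.null, TRUE)]
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_log <- function(quiet, ...) {
  if (!quiet) message(sprintf(...))
}

#' Run the counts-to-copula-modules pipeline
#'
#' Chains all stages: counts are mapped to pseudo-observations with the
#' distributional transform; a C-vine is fitted with independence pruning;
#' the density grids of the non-independent copulas are stacked into a
#' matrix; tail-emphasis weights are built from the pair margins; speckled
#' cross-validation selects the factorization rank (and penalties); the
#' final weighted factorization is fitted at the selected rank and its
#' coefficient rows are grouped by dominant module. Stage counts (pairs
#' total, pruned, retained, selected rank) are logged and returned.
#'
#' @param config a [run_config()].
#' @param counts optional count matrix, overriding `config$input`.
#' @param quiet suppress progress messages.
#' @return An object of class `pipeline_result`: the fitted `cvine`, the
#'   density matrix, weights, `speckled_cv` report, final `nmf_fit`,
#'   row ordering from [sort_coefficients()] and a `counts` summary list.
#'   When `config$output` is set, artifacts are also written there (vine
#'   JSON, density archive, coefficient table, CV report JSON, config).
#' @export
run_pipeline <- function(config = run_config(), counts = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(counts)) {
    if (is.null(config$input)) stop("no input: set config$input or pass counts")
    counts <- read_counts(config$input)
  }
  counts <- as.matrix(counts)
  d <- ncol(counts)
  pipeline_log(quiet, "pipeline: %d observations x %d variables", nrow(counts), d)
  U <- pseudo_obs(counts, seed = child_seed(config$seed, 1))
  margins <- attr(U, "margins")
  fit <- fit_cvine(U, alpha = config$alpha, estimator = config$estimator,
                   G = config$grid_size, n_perm = config$n_perm,
                   seed = child_seed(config$seed, 2))
  n_edges <- length(fit$edges)
  dm <- density_matrix(fit)
  pipeline_log(quiet, "vine: %d pair copulas, %d independent (pruned), %d retained",
               n_edges, n_edges - nrow(dm$X), nrow(dm$X))
  result <- list(config = config, vine = fit, density = dm,
                 counts = list(n_obs = nrow(counts), d = d,
                               pairs_total = n_edges,
                               pairs_pruned = n_edges - nrow(dm$X),
                               pairs_retained = nrow(dm$X)))
  class(result) <- "pipeline_result"
  if (nrow(dm$X) == 0) {
    pipeline_log(quiet, "no modules: every pair copula is independent")
    result$counts$selected_rank <- 0L
    return(write_pipeline_artifacts(result, quiet))
  }
  V <- if (config$weighted) {
    copula_weights(margins, cbind(dm$meta$root, dm$meta$partner),
                   G = config$grid_size)
  } else NULL
  ranks <- config$ranks[config$ranks <= nrow(dm$X)]
  cv <- speckled_cv(dm$X, V, ranks = ranks, n_folds = config$n_folds,
                    holdout_frac = config$holdout_frac,
                    alphas = config$alphas, max_iter = config$max_iter,
                    seed = child_seed(config$seed, 3))
  pipeline_log(quiet, "speckled CV: selected rank %d", cv$selected_rank)
  fac <- wnmf(dm$X, V, k = cv$selected_rank,
              alpha1 = cv$best_alpha[1], alpha2 = cv$best_alpha[2],
              max_iter = config$max_iter, seed = child_seed(config$seed, 4),
              n_restarts = config$n_restarts)
  result$weights <- V
  result$cv <- cv
  result$fit <- fac
  result$row_order <- sort_coefficients(fac$W)
  result$counts$selected_rank <- cv$selected_rank
  write_pipeline_artifacts(result, quiet)
}

write_pipeline_artifacts <- function(result, quiet) {
  out <- result$config$output
  if (is.null(out)) return(result)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_run_config(result$config, file.path(out, "config.yaml"))
  vine_to_json(result$vine, file.path(out, "vine.json"))
  dm <- result$density
  grids <- lapply(seq_len(nrow(dm$X)), function(i) matrix(dm$X[i, ], dm$G, dm$G))
  write_density_archive(grids, dm$meta, file.path(out, "densities.rds"))
  if (!is.null(result$fit)) {
    W <- coef(result$fit)[result$row_order, , drop = FALSE]
    tab <- cbind(dm$meta[result$row_order, c("label", "tree")], W)
    colnames(tab) <- c("pair", "tree", paste0("module", seq_len(ncol(W))))
    utils::write.csv(tab, file.path(out, "coefficients.csv"),
                     row.names = FALSE)
    saveRDS(result$fit, file.path(out, "factorization.rds"))
    jsonlite::write_json(
      list(ranks = result$cv$ranks, rank_curve = result$cv$rank_curve,
           selected_rank = result$cv$selected_rank,
           best_alpha = result$cv$best_alpha),
      file.path(out, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$counts, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log(quiet, "artifacts written to %s", out)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cc <- x$counts
  cat(sprintf("pipeline result: %d pairs (%d pruned, %d retained), selected rank %d\n",
              cc$pairs_total, cc$pairs_pruned, cc$pairs_retained,
              cc$selected_rank %||% NA))
  invisible(x)
}

#' Per-tree module report
#'
#' Cross-tabulates retained neuron pairs by vine tree and dominant module,
#' the table behind per-tree module-usage summaries.
#'
#' @param result a [run_pipeline()] result with a factorization.
#' @return a contingency table (tree x dominant module).
#' @export
report_by_tree <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  if (is.null(result$fit)) stop("pipeline produced no factorization")
  dom <- apply(coef(result$fit), 1, which.max)
  table(tree = result$density$meta$tree, module = dom)
}
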