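test_that("weight profile vanishes for uniform margins and flags degenerate ones", {
  expect_equal(weight_profile_quantile(function(u) u, G = 50), rep(0, 50))
  row <- build_weight_row(function(u) u, function(u) u, G = 20)
  expect_equal(row, matrix(1, 20, 20))  # flat baseline
  m1 <- empirical_margin(c(4L, 4L, 4L))
  m2 <- empirical_margin(rpois(100, 2))
  expect_warning(flat <- build_weight_row(m1, m2, G = 20), "degenerate")
  expect_equal(flat, matrix(1, 20, 20))
})

test_that("weight rows are positive, symmetric for identical margins, corner-heavy", {
  set.seed(71)
  m <- empirical_margin(rpois(5000, 2))
  row <- build_weight_row(m, m, G = 100, sigma = 5)
  expect_true(all(row > 0))
  expect_equal(max(row), 1)
  expect_equal(row, t(row), tolerance = 1e-12)
  expect_equal(row, copulamodules:::rot90_grid(row), tolerance = 1e-12)
  # corners outweigh the center for skewed Poisson margins
  corner <- mean(c(row[1:10, 1:10], row[1:10, 91:100],
                   row[91:100, 1:10], row[91:100, 91:100]))
  center <- mean(row[41:60, 41:60])
  expect_gt(corner, center)
})

test_that("copula_weights aligns weight rows with pair indices", {
  set.seed(72)
  margins <- list(empirical_margin(rpois(500, 1)),
                  empirical_margin(rpois(500, 3)),
                  empirical_margin(rpois(500, 5)))
  V <- copula_weights(margins, rbind(c(1, 2), c(2, 3)), G = 30)
  expect_equal(dim(V), c(2, 900))
  expect_true(all(V > 0))
  direct <- build_weight_row(margins[[2]], margins[[3]], G = 30)
  expect_equal(V[2, ], as.vector(direct))
})

test_that("nmf solves the exact rank-1 case and keeps factors non-negative", {
  set.seed(73)
  X <- outer(runif(20) + 0.5, runif(50) + 0.5)
  f <- nmf(X, 1, max_iter = 500, seed = 1)
  expect_lt(norm(X - fitted(f), "F") / norm(X, "F"), 1e-4)
  expect_true(all(coef(f) >= 0) && all(f$H >= 0))
  # overcomplete: near-zero training error at k = n_rows
  X2 <- matrix(runif(20 * 30), 20, 30)
  f2 <- nmf(X2, 20, max_iter = 2000, seed = 2)
  expect_lt(mean((X2 - fitted(f2))^2) / mean(X2^2), 0.01)
})

test_that("nmf objective is non-increasing and matches the pure-R updates", {
  set.seed(74)
  X <- matrix(runif(30 * 40), 30, 40)
  f <- nmf(X, 3, max_iter = 200, tol = 0, seed = 3)
  expect_true(all(diff(f$objective) <= 1e-8))
  # compiled core against the reference update rules, iteration by iteration
  init <- copulamodules:::nmf_init(X, 3, copulamodules:::child_seed(3, 0))
  ref <- copulamodules:::nmf_updates_r(X, init$W, init$H, n_iter = 25)
  core <- .nmf_core_cpp(X, matrix(1, 30, 40), matrix(numeric(0), 0, 0),
                        init$W, init$H, 0, 0, 25L, 0, 1e-12)
  expect_equal(core$W, ref$W, tolerance = 1e-10)
  expect_equal(core$H, ref$H, tolerance = 1e-10)
})

test_that("nmf separates Frank and Clayton rows into matching factors", {
  toy <- toy_density_matrix(n_per = 20, G = 40, noise = 0.05, seed = 75)
  f <- nmf(toy$X, 2, max_iter = 400, seed = 4)
  dom <- apply(coef(f), 1, which.max)
  # dominant factor agrees with family label for at least 38/40 rows
  agree <- max(sum(dom == rep(c(1, 2), each = 20)),
               sum(dom == rep(c(2, 1), each = 20)))
  expect_gte(agree, 38)
})

test_that("wnmf with unit weights reduces exactly to nmf", {
  set.seed(76)
  X <- matrix(runif(25 * 30), 25, 30)
  V1 <- matrix(1, 25, 30)
  init <- copulamodules:::nmf_init(X, 4, copulamodules:::child_seed(9, 0))
  a <- .nmf_core_cpp(X, V1, matrix(numeric(0), 0, 0), init$W, init$H,
                     0, 0, 50L, 0, 1e-12)
  b <- .nmf_core_cpp(X, matrix(1, 25, 30), matrix(numeric(0), 0, 0),
                     init$W, init$H, 0, 0, 50L, 0, 1e-12)
  expect_lt(max(abs(a$W - b$W)), 1e-10)
  fa <- nmf(X, 4, max_iter = 50, tol = 0, seed = 9)
  fb <- wnmf(X, V1, 4, max_iter = 50, tol = 0, seed = 9)
  expect_lt(max(abs(fa$W - fb$W)), 1e-10)
  expect_lt(max(abs(fa$H - fb$H)), 1e-10)
  expect_equal(fa$objective, fb$objective, tolerance = 1e-12)
})

test_that("weighted objective is non-increasing after burn-in", {
  set.seed(77)
  toy <- toy_density_matrix(n_per = 10, G = 30, noise = 0.05, seed = 77)
  m <- empirical_margin(rpois(2000, 2))
  V <- matrix(rep(as.vector(build_weight_row(m, m, G = 30)), each = 20),
              20, 900)
  f <- wnmf(toy$X, V, 2, alpha1 = 0.01, alpha2 = 0.01, max_iter = 200,
            tol = 0, seed = 5)
  tr <- f$objective
  expect_true(all(diff(tr[-(1:5)]) <= 1e-8 * abs(tr[-(1:5)])[-1] + 1e-10))
  expect_true(all(coef(f) >= 0) && all(f$H >= 0))
})

test_that("L1 regularization increases module sparsity", {
  toy <- toy_density_matrix(n_per = 15, G = 30, noise = 0.1, seed = 78)
  V <- matrix(1, 30, 900)
  f0 <- wnmf(toy$X, V, 2, alpha1 = 0, max_iter = 300, seed = 6)
  f1 <- wnmf(toy$X, V, 2, alpha1 = 10 * mean(toy$X), max_iter = 300, seed = 6)
  sparsity <- function(f) mean(f$H < 1e-6)
  expect_gt(sparsity(f1), sparsity(f0))
})

test_that("sort_coefficients groups by dominant module with stable ties", {
  W <- rbind(c(0, 1), c(1, 0), c(0, 0.5), c(2, 0), c(0, 0))
  ord <- sort_coefficients(W)
  expect_equal(ord, c(4, 2, 1, 3, 5))  # module 1 desc, module 2 desc, zero last
  # known 4-group synthetic coefficients with noise: group recovery
  set.seed(79)
  truthgrp <- rep(1:4, each = 25)
  W2 <- matrix(runif(100 * 4, 0, 0.2), 100, 4)
  W2[cbind(seq_len(100), truthgrp)] <- runif(100, 0.8, 1.5)
  ord2 <- sort_coefficients(W2)
  recovered <- truthgrp[ord2]
  expect_gte(sum(recovered == rep(1:4, each = 25)), 95)
})

test_that("match_modules_to_truth finds the exact assignment", {
  toy <- toy_density_matrix(n_per = 2, G = 20, noise = 0, seed = 80)
  H <- rbind(as.vector(toy$truth$clayton), as.vector(toy$truth$frank))
  res <- match_modules_to_truth(H, toy$truth)  # truths: frank, clayton
  expect_equal(res$assignment, c(2, 1))
  expect_equal(res$total_mse, 0, tolerance = 1e-20)
  # scale invariance: modules rescaled to mean 1 before comparison
  res2 <- match_modules_to_truth(H * 7, toy$truth)
  expect_equal(res2$total_mse, 0, tolerance = 1e-20)
  # noise oracle: uniform(0, eps) noise adds MSE ~ eps^2 / 3 per cell
  # (raw-scale comparison isolates the noise second moment)
  set.seed(81)
  eps <- 0.05
  Hn <- H + matrix(runif(length(H), 0, eps), nrow(H))
  res3 <- match_modules_to_truth(Hn, toy$truth, rescale = FALSE)
  for (msei in res3$mse) {
    expect_lt(msei, 2 * eps^2 / 3)
    expect_gt(msei, eps^2 / 6)
  }
  expect_error(match_modules_to_truth(H, toy$truth[1]), "must equal")
})

test_that("speckled masks are disjoint and cover the expected fraction", {
  masks <- copulamodules:::speckle_masks(c(40, 50), 5, 0.1, seed = 82)
  held <- lapply(masks, function(m) which(m == 0))
  allheld <- unlist(held)
  expect_equal(length(allheld), length(unique(allheld)))  # disjoint
  expect_equal(length(allheld) / 2000, 0.5, tolerance = 0.01)
  for (m in masks) expect_true(all(rowSums(m) > 0))
  # tiny-row guard: masks exist even when full columns must be sacrificed
  m2 <- copulamodules:::speckle_masks(c(2, 2500), 5, 0.1, seed = 83)
  for (m in m2) expect_true(all(rowSums(m) > 0))
})

test_that("speckled CV recovers the rank of a noisy low-rank matrix", {
  set.seed(83)
  W0 <- matrix(runif(40 * 3, 0.2, 1), 40, 3)
  H0 <- matrix(runif(3 * 60, 0.2, 1), 3, 60)
  X <- W0 %*% H0 + matrix(rnorm(40 * 60, 0, 0.02), 40, 60)
  X[X < 0] <- 0
  cv <- speckled_cv(X, NULL, ranks = 1:6, max_iter = 1000, seed = 84)
  expect_equal(cv$selected_rank, 3)
  expect_equal(cv$plateau_rank, 3)
  expect_lte(cv$plateau_rank, cv$selected_rank)
  expect_s3_class(cv, "speckled_cv")
  expect_output(print(cv), "selected rank")
  # validation error computed only on held-out entries; train < val at truth
  expect_lt(mean(cv$train_mse[1, 3, ]), mean(cv$val_mse[1, 3, ]))
})

test_that("wnmf beats nmf at recovering the Frank module from overlapping tails", {
  toy <- toy_density_matrix(n_per = 20, G = 40, noise = 0.05, seed = 85)
  m <- empirical_margin(rpois(5000, 2))
  vrow <- as.vector(build_weight_row(m, m, G = 40))
  V <- matrix(rep(vrow, each = 40), 40, 1600)
  frank_mse <- function(H) {
    res <- match_modules_to_truth(H, toy$truth)
    res$mse[1]  # truths: frank first
  }
  w_mse <- n_mse <- numeric(6)
  for (s in 1:6) {
    w_mse[s] <- frank_mse(wnmf(toy$X, V, 2, max_iter = 300, seed = s)$H)
    n_mse[s] <- frank_mse(nmf(toy$X, 2, max_iter = 300, seed = s)$H)
  }
  expect_lt(median(w_mse), median(n_mse))
})
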