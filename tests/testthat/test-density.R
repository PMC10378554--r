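test_that("fallback estimator renormalizes, is deterministic, finds tails", {
  set.seed(21)
  u <- cbind(runif(20000), runif(20000))
  m <- fit_copula_fallback(u)
  expect_s3_class(m, "pair_copula")
  expect_equal(m$kind, "histogram_fallback")
  expect_equal(mean(density_grid(m)), 1, tolerance = 1e-12)
  expect_true(all(density_grid(m) >= 0))
  # determinism: same input, same grid
  expect_identical(density_grid(fit_copula_fallback(u)), density_grid(m))
  # Clayton tail mass: corner cell among the top 1% of cells
  ucl <- rcopula(parametric_copula("clayton", 5), 20000, seed = 22)
  g <- density_grid(fit_copula_fallback(ucl))
  expect_gte(g[1, 1], quantile(g, 0.99))
  # near-delta input warns
  x <- matrix(0.5 + 1e-4 * runif(40), 20, 2)
  expect_warning(fit_copula_fallback(x, G = 10), "single grid cell")
})

test_that("fallback discriminates Clayton from Frank by grid MSE", {
  gcl <- analytic_grid(parametric_copula("clayton", 5))
  gfr <- analytic_grid(parametric_copula("frank", 6))
  ucl <- rcopula(parametric_copula("clayton", 5), 20000, seed = 23)
  ufr <- rcopula(parametric_copula("frank", 6), 20000, seed = 24)
  g1 <- density_grid(fit_copula_fallback(ucl))
  g2 <- density_grid(fit_copula_fallback(ufr))
  expect_lt(mean((g1 - gcl)^2), mean((g1 - gfr)^2))
  expect_lt(mean((g2 - gfr)^2), mean((g2 - gcl)^2))
})

test_that("analytic spline gradients match the central-difference route", {
  set.seed(24)
  n <- 300; K <- 8; P <- 3 * K + 1
  x <- runif(n)
  Theta <- matrix(rnorm(n * P, 0, 0.7), n, P)
  gy <- rnorm(n)
  a <- copulamodules:::.rqs_grad_cpp(x, Theta, K, gy)
  b <- copulamodules:::.rqs_grad_fd_cpp(x, Theta, K, gy, 1e-5)
  expect_lt(max(abs(a$Gtheta - b$Gtheta)), 1e-4)
  expect_lt(median(abs(a$gx - b$gx)), 1e-5)
})

test_that("flow spline backward pass matches finite differences of the loss", {
  uv <- rcopula(parametric_copula("clayton", 3), 64, seed = 25)
  cfg <- flow_config(n_layers = 2, hidden_units = 4, n_knots = 4)
  set.seed(26)
  layers <- copulamodules:::init_flow_layers(cfg)
  K <- cfg$n_knots
  loss_fn <- function(ls) -sum(copulamodules:::flow_forward(uv, ls, K)$logc)
  fw <- copulamodules:::flow_forward(uv, layers, K)
  grads <- copulamodules:::flow_backward(layers, fw$cache, K)
  h <- 1e-5
  for (l in 1:2) {
    for (nm in c("A1", "b1", "A2", "b2")) {
      for (i in sample(length(layers[[l]][[nm]]),
                       min(4, length(layers[[l]][[nm]])))) {
        lp <- layers; lp[[l]][[nm]][i] <- lp[[l]][[nm]][i] + h
        lm <- layers; lm[[l]][[nm]][i] <- lm[[l]][[nm]][i] - h
        g_num <- (loss_fn(lp) - loss_fn(lm)) / (2 * h)
        g_ana <- grads[[l]][[nm]][i]
        expect_lt(abs(g_num - g_ana) / (abs(g_num) + abs(g_ana) + 1e-6),
                  1e-4)
      }
    }
  }
})

test_that("flow density integrates to one by construction", {
  # untrained (random-init) flows already satisfy normalization: the map is
  # a bijection of the unit square with uniform base
  cfg <- flow_config(n_layers = 3, hidden_units = 8, n_knots = 8)
  set.seed(27)
  layers <- copulamodules:::init_flow_layers(cfg)
  for (l in seq_along(layers)) {  # perturb away from identity
    layers[[l]]$A2 <- layers[[l]]$A2 + rnorm(length(layers[[l]]$A2), 0, 0.3)
  }
  fitlike <- list(layers = layers, config = cfg)
  ctr <- (seq_len(200) - 0.5) / 200
  vals <- copulamodules:::flow_density(fitlike, rep(ctr, 200),
                                       rep(ctr, each = 200))
  expect_equal(mean(vals), 1, tolerance = 0.01)
  expect_true(all(vals >= 0))
})

test_that("flow fit recovers independence and routes small samples", {
  set.seed(28)
  u <- cbind(runif(5000), runif(5000))
  m <- fit_copula_flow(u, search_space = list(), n_trials = 1, seed = 29,
                       config = test_flow_config())
  expect_equal(m$kind, "flow")
  g <- density_grid(m)
  expect_lt(mean(abs(g - 1)), 0.15)
  expect_equal(mean(g), 1, tolerance = 0.02)
  # identical seed -> identical grid
  m2 <- fit_copula_flow(u, search_space = list(), n_trials = 1, seed = 29,
                        config = test_flow_config())
  expect_identical(density_grid(m2), g)
  # small-sample routing
  msmall <- fit_copula_flow(matrix(runif(100, 0.2, 0.8), 50, 2))
  expect_equal(msmall$kind, "histogram_fallback")
})

test_that("flow fit discriminates Clayton from Frank and keeps margins uniform", {
  ucl <- rcopula(parametric_copula("clayton", 5), 20000, seed = 30)
  m <- fit_copula_flow(ucl, search_space = list(), n_trials = 1, seed = 31,
                       config = test_flow_config())
  g <- density_grid(m)
  gcl <- analytic_grid(parametric_copula("clayton", 5))
  gfr <- analytic_grid(parametric_copula("frank", 6))
  expect_lt(mean((g - gcl)^2), mean((g - gfr)^2))
  expect_equal(mean(g), 1, tolerance = 0.02)
  # margin uniformity: row/column sums over G within 0.1 of 1 on average
  expect_lt(mean(abs(rowSums(g) / nrow(g) - 1)), 0.1)
  expect_lt(mean(abs(colSums(g) / ncol(g) - 1)), 0.1)
})

test_that("h-functions: identity under independence, CDF endpoints, Clayton oracle", {
  ind <- independence_copula(50)
  x <- seq(0.05, 0.95, 0.1)
  expect_equal(h_function(ind, x, rep(0.3, length(x))), x)
  gm <- analytic_grid(parametric_copula("clayton", 5))
  pc <- copulamodules:::new_pair_copula("histogram_fallback", gm, 100)
  expect_lt(h_function(pc, 1e-4, 0.5), 0.01)
  expect_gt(h_function(pc, 1 - 1e-4, 0.5), 0.99)
  # closed-form Clayton conditional CDF on a 9 x 9 probe grid
  probe <- (1:9) / 10
  for (y in probe) {
    h_num <- h_function(pc, probe, rep(y, 9), direction = "forward")
    expect_lt(max(abs(h_num - clayton_h_closed_form(probe, y))), 0.02)
  }
  # monotone in x at fixed y
  hh <- h_function(pc, seq(0.01, 0.99, length.out = 60), rep(0.25, 60))
  expect_true(all(diff(hh) >= 0))
})

test_that("h-function is consistent with the numeric copula CDF derivative", {
  gm <- analytic_grid(parametric_copula("frank", 6), 200)
  pc <- copulamodules:::new_pair_copula("histogram_fallback", gm, 200)
  # C(x, y) from the same grid by double cumulative sum
  Cgrid <- apply(apply(gm, 2, cumsum), 1, cumsum) / 200^2
  Cfun <- function(x, y) Cgrid[round(y * 200), round(x * 200)]
  delta <- 1 / 200
  for (pt in list(c(0.3, 0.5), c(0.6, 0.2), c(0.8, 0.8))) {
    h_fd <- (Cfun(pt[1], pt[2] + 2 * delta) - Cfun(pt[1], pt[2] - 2 * delta)) /
      (4 * delta)
    expect_equal(h_function(pc, pt[1], pt[2]), h_fd, tolerance = 0.02)
  }
})

test_that("density archives round-trip", {
  g1 <- matrix(runif(25), 5, 5)
  g2 <- matrix(runif(25), 5, 5)
  meta <- data.frame(label = c("a,b", "a,c"), tree = c(1L, 1L),
                     kind = "histogram_fallback")
  f <- tempfile(fileext = ".rds")
  write_density_archive(list(g1, g2), meta, f)
  back <- read_density_archive(f)
  expect_equal(back$grids[[2]], g2)
  expect_equal(back$meta, meta)
  expect_equal(back$G, 5)
})
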