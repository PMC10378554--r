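# Shared fixtures and small configurations used across test files.

# Flow training configuration for tests: small but sufficient for the
# estimator-consistency checks.
test_flow_config <- function(...) {
  flow_config(n_layers = 4, hidden_units = 16, n_knots = 16,
              max_epochs = 60, batch_size = 1024, learning_rate = 1e-2, ...)
}

# Analytic grids rescaled to mean 1 (matching estimator normalization).
analytic_grid <- function(copula, G = 100) {
  g <- density_parametric(copula, G)
  g / mean(g)
}

# Closed-form Clayton h-function h(x | y), written out independently of the
# package's parametric machinery (oracle for numeric h-functions).
clayton_h_closed_form <- function(x, y, theta = 5) {
  y^(-theta - 1) * (x^(-theta) + y^(-theta) - 1)^(-1 / theta - 1)
}

# Small two-family density matrix (Frank + Clayton rows) built from analytic
# grids plus seeded noise: a fast stand-in for the full benchmark where
# estimation error is not the point.
toy_density_matrix <- function(n_per = 20, G = 40, noise = 0.05, seed = 1) {
  set.seed(seed)
  gf <- analytic_grid(parametric_copula("frank", 6), G)
  gc <- analytic_grid(parametric_copula("clayton", 5), G)
  X <- rbind(
    t(replicate(n_per, pmax(as.vector(gf) + rnorm(G * G, 0, noise), 0))),
    t(replicate(n_per, pmax(as.vector(gc) + rnorm(G * G, 0, noise), 0))))
  list(X = X, truth = list(frank = gf, clayton = gc),
       labels = rep(c("frank", "clayton"), each = n_per), G = G)
}
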