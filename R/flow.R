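# Bivariate normalizing flow on the unit square: a composition of
# rational-quadratic spline coupling layers with a uniform base density.
# Each layer transforms one coordinate with a monotone RQ spline
# [0,1] -> [0,1] whose parameters are produced by a one-hidden-layer tanh
# conditioner network of the other coordinate. The copula density is the
# Jacobian of the data->base map. Training is maximum likelihood with Adam;
# gradients are analytic through the conditioner and central-difference
# through the spline's per-sample parameters and inputs (parameter counts
# per spline are small, 3K+1 for K bins), which tests verify against full
# finite differences of the loss.

#' Flow estimator configuration
#'
#' @param n_layers number of coupling layers (alternating coordinates).
#' @param hidden_units hidden width of the conditioner network.
#' @param n_knots number of spline bins K (the spline has K+1 knots).
#' @param train_fraction fraction of the data used for training; the
#'   remainder is the validation split scored during hyperparameter search.
#' @param max_epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization, split and batching.
#' @return a `flow_config` list.
#' @export
flow_config <- function(n_layers = 4, hidden_units = 32, n_knots = 16,
                        train_fraction = 0.9, max_epochs = 60,
                        batch_size = 1024, learning_rate = 1e-2,
                        seed = NULL) {
  stopifnot(n_layers >= 1, hidden_units >= 1, n_knots >= 2,
            train_fraction > 0, train_fraction < 1, max_epochs >= 1)
  structure(list(n_layers = n_layers, hidden_units = hidden_units,
                 n_knots = n_knots, train_fraction = train_fraction,
                 max_epochs = max_epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed),
            class = "flow_config")
}

# Monotone rational-quadratic spline evaluation (compiled): returns the
# transformed value and the log-derivative for each sample. Raw parameters
# decode to softmax widths/heights and softplus knot derivatives in C++.
rqs_eval <- function(x, Theta, K) {
  .rqs_eval_cpp(as.numeric(x), Theta, as.integer(K))
}

MIN_DERIV <- 1e-3

# Conditioner network: scalar input -> hidden tanh -> raw spline parameters.
mlp_forward <- function(cond, layer) {
  z <- tanh(outer(cond, layer$A1) +
            matrix(layer$b1, length(cond), length(layer$b1), byrow = TRUE))
  Theta <- z %*% t(layer$A2) +
    matrix(layer$b2, length(cond), length(layer$b2), byrow = TRUE)
  list(z = z, Theta = Theta)
}

init_flow_layers <- function(cfg) {
  K <- cfg$n_knots
  P <- 3 * K + 1
  hid <- cfg$hidden_units
  lapply(seq_len(cfg$n_layers), function(l) {
    b2 <- numeric(P)
    b2[(2 * K + 1):P] <- log(expm1(1 - MIN_DERIV))  # derivatives start at 1
    list(which = if (l %% 2 == 1) 1L else 2L,
         A1 = stats::rnorm(hid, 0, 0.5),
         b1 = stats::rnorm(hid, 0, 0.5),
         A2 = matrix(stats::rnorm(P * hid, 0, 0.01), P, hid),
         b2 = b2)
  })
}

# Forward pass: returns per-layer inputs (for backprop), final coordinates
# and the accumulated log-density log c(u, v) per sample.
flow_forward <- function(uv, layers, K) {
  u <- uv[, 1]; v <- uv[, 2]
  logc <- numeric(length(u))
  cache <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    xin <- if (ly$which == 1L) u else v
    cond <- if (ly$which == 1L) v else u
    mf <- mlp_forward(cond, ly)
    ev <- rqs_eval(xin, mf$Theta, K)
    cache[[l]] <- list(xin = xin, cond = cond, z = mf$z, Theta = mf$Theta,
                       y = ev$y)
    logc <- logc + ev$logdet
    if (ly$which == 1L) u <- ev$y else v <- ev$y
  }
  list(u = u, v = v, logc = logc, cache = cache)
}

# Backward pass: gradients of sum(-log c) over the batch w.r.t. all layer
# parameters. Spline partials of gy*y - logdet are analytic (compiled),
# as is the MLP chain.
flow_backward <- function(layers, cache, K) {
  L <- length(layers)
  n <- length(cache[[1]]$xin)
  gu <- numeric(n)  # grad w.r.t. current u (output side)
  gv <- numeric(n)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    ly <- layers[[l]]
    ca <- cache[[l]]
    gy <- if (ly$which == 1L) gu else gv
    gr <- .rqs_grad_cpp(ca$xin, ca$Theta, as.integer(K), gy)
    Gtheta <- gr$Gtheta
    gx <- gr$gx
    # MLP chain
    back <- (Gtheta %*% ly$A2) * (1 - ca$z^2)       # n x hidden
    grads[[l]] <- list(
      A1 = as.vector(crossprod(back, ca$cond)),
      b1 = colSums(back),
      A2 = crossprod(Gtheta, ca$z),
      b2 = colSums(Gtheta))
    gcond <- as.vector(back %*% ly$A1)
    if (ly$which == 1L) { gu <- gx; gv <- gv + gcond }
    else { gv <- gx; gu <- gu + gcond }
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    lapply(ly[c("A1", "b1", "A2", "b2")], function(p) {
      list(m = p * 0, v = p * 0)
    })
  })
}

adam_step <- function(layers, grads, state, lr, t, clip = 10,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(unlist(g)^2), 0)))
  scale <- if (gn > clip) clip / gn else 1
  for (l in seq_along(layers)) {
    for (nm in c("A1", "b1", "A2", "b2")) {
      g <- grads[[l]][[nm]] * scale
      st <- state[[l]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[l]][[nm]] <- layers[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Train one flow on `train`; returns the layers of the best-validation epoch
# and that epoch's mean validation log-likelihood.
train_flow <- function(train, valid, cfg, lr = cfg$learning_rate) {
  layers <- init_flow_layers(cfg)
  state <- adam_init(layers)
  K <- cfg$n_knots
  n <- nrow(train)
  bs <- min(cfg$batch_size, n)
  t <- 0
  score_set <- if (nrow(valid) > 0) valid else train
  best_ll <- -Inf
  best_layers <- layers
  for (ep in seq_len(cfg$max_epochs)) {
    # constant rate for the first half, then exponential decay to lr/10
    progress <- (ep - 1) / max(1, cfg$max_epochs - 1)
    lr_ep <- if (progress < 0.5) lr else lr * 0.1^((progress - 0.5) / 0.5)
    ord <- sample.int(n)
    for (b in seq_len(ceiling(n / bs))) {
      rows <- ord[((b - 1) * bs + 1):min(b * bs, n)]
      fw <- flow_forward(train[rows, , drop = FALSE], layers, K)
      loss <- -mean(fw$logc)
      if (!is.finite(loss)) return(NULL)
      grads <- flow_backward(layers, fw$cache, K)
      # average over the batch
      grads <- lapply(grads, function(g) lapply(g, function(p) p / length(rows)))
      t <- t + 1
      up <- adam_step(layers, grads, state, lr_ep, t)
      layers <- up$layers
      state <- up$state
    }
    # epoch-level validation snapshot: keep the best-scoring parameters
    ll <- mean(flow_forward(score_set, layers, K)$logc)
    if (is.finite(ll) && ll > best_ll) {
      best_ll <- ll
      best_layers <- layers
    }
  }
  if (!is.finite(best_ll)) return(NULL)
  list(layers = best_layers, val_ll = best_ll, config = cfg)
}

# Train with one retry at halved learning rate on divergence.
train_flow_safe <- function(train, valid, cfg) {
  fit <- train_flow(train, valid, cfg)
  if (is.null(fit)) fit <- train_flow(train, valid, cfg,
                                      lr = cfg$learning_rate / 2)
  if (is.null(fit)) stop("flow training diverged (non-finite loss) even after halving the learning rate")
  fit
}

# Density of a trained flow at arbitrary points.
flow_density <- function(fit, u, v) {
  fw <- flow_forward(cbind(pmin(pmax(u, 1e-9), 1 - 1e-9),
                           pmin(pmax(v, 1e-9), 1 - 1e-9)),
                     fit$layers, fit$config$n_knots)
  exp(fw$logc)
}
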