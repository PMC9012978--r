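# Multilayer perceptrons for the classifier benchmark: a fixed
# input -> 15 -> 10 -> 5 -> 3 architecture in two flavours.
#  * classic: logistic activations throughout, summed cross-entropy on
#    logistic outputs, trained full-batch by resilient backpropagation with
#    weight backtracking (Rprop+; eta+ 1.2, eta- 0.5, Delta0 0.1, Dmax 50).
#    Training stops on a gradient threshold, a loss plateau, or at `stepmax`
#    steps; hitting the cap warns and returns the (possibly unconverged)
#    model.
#  * modern: ReLU hidden layers, softmax output, categorical cross-entropy,
#    Adam with minibatches of 32.
# No installed package provides multi-hidden-layer nets with these training
# rules, so they are implemented directly with base matrix operations.

sigm <- function(x) 1 / (1 + exp(-x))

mlp_init <- function(p, hidden, n_out, seed, scheme = c("uniform", "he")) {
  scheme <- match.arg(scheme)
  sizes <- c(p, hidden, n_out)
  with_seed(seed, lapply(seq_len(length(sizes) - 1), function(l) {
    fanin <- sizes[l] + 1
    if (scheme == "uniform")
      matrix(stats::runif(fanin * sizes[l + 1], -0.5, 0.5), fanin)
    else
      matrix(stats::rnorm(fanin * sizes[l + 1], 0, sqrt(2 / sizes[l])), fanin)
  }))
}

mlp_forward <- function(W, X, act) {
  A <- list(X)
  L <- length(W)
  for (l in seq_len(L)) {
    Z <- cbind(1, A[[l]]) %*% W[[l]]
    A[[l + 1]] <- if (l < L) act(Z)
                  else Z  # output pre-activation; caller applies link
  }
  A
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Backprop for both flavours. `dZ_out` is dLoss/dZ at the output layer.
mlp_grads <- function(W, A, dZ_out, act_grad) {
  L <- length(W)
  G <- vector("list", L)
  dZ <- dZ_out
  for (l in L:1) {
    G[[l]] <- crossprod(cbind(1, A[[l]]), dZ)
    if (l > 1) {
      dA <- dZ %*% t(W[[l]][-1, , drop = FALSE])
      dZ <- dA * act_grad(A[[l]])
    }
  }
  G
}

train_mlp_classic_core <- function(X, Y, hidden = c(15, 10, 5),
                                   stepmax = 1e5, threshold = 0.01,
                                   seed = 1L) {
  W <- mlp_init(ncol(X), hidden, ncol(Y), seed, "uniform")
  L <- length(W)
  delta <- lapply(W, function(w) matrix(0.1, nrow(w), ncol(w)))
  gprev <- lapply(W, function(w) matrix(0, nrow(w), ncol(w)))
  upd_prev <- lapply(W, function(w) matrix(0, nrow(w), ncol(w)))
  loss_fun <- function(W) {
    A <- mlp_forward(W, X, sigm)
    O <- sigm(A[[L + 1]])
    O <- pmin(pmax(O, 1e-12), 1 - 1e-12)
    list(loss = -sum(Y * log(O) + (1 - Y) * log(1 - O)), A = A, O = O)
  }
  f <- loss_fun(W)
  e_prev <- f$loss
  best <- f$loss; best_step <- 0L
  converged <- FALSE
  step <- 0L
  while (step < stepmax) {
    step <- step + 1L
    G <- mlp_grads(W, f$A, f$O - Y, function(a) a * (1 - a))
    gmax <- max(vapply(G, function(g) max(abs(g)), 0))
    if (gmax < threshold) { converged <- TRUE; break }
    for (l in seq_len(L)) {
      s <- sign(G[[l]] * gprev[[l]])
      delta[[l]][s > 0] <- pmin(delta[[l]][s > 0] * 1.2, 50)
      delta[[l]][s < 0] <- pmax(delta[[l]][s < 0] * 0.5, 1e-6)
      upd <- -sign(G[[l]]) * delta[[l]]
      if (f$loss > e_prev) upd[s < 0] <- -upd_prev[[l]][s < 0]  # backtrack
      else upd[s < 0] <- 0
      W[[l]] <- W[[l]] + upd
      upd_prev[[l]] <- upd
      gnew <- G[[l]]
      gnew[s < 0] <- 0
      gprev[[l]] <- gnew
    }
    e_prev <- f$loss
    f <- loss_fun(W)
    if (f$loss < best - abs(best) * 1e-6) { best <- f$loss; best_step <- step }
    if (step - best_step > 1000) break  # loss plateau
  }
  if (!converged && step >= stepmax)
    warning("classic MLP reached stepmax without converging; returning model")
  list(weights = W, steps = step, converged = converged, loss = f$loss)
}

train_mlp_modern_core <- function(X, Y, hidden = c(15, 10, 5),
                                  epochs = 200, batch_size = 32,
                                  lr = 1e-3, patience = 20, seed = 1L) {
  W <- mlp_init(ncol(X), hidden, ncol(Y), seed, "he")
  L <- length(W)
  mth <- lapply(W, function(w) matrix(0, nrow(w), ncol(w)))
  vth <- lapply(W, function(w) matrix(0, nrow(w), ncol(w)))
  relu <- function(z) pmax(z, 0)
  relu_grad <- function(a) (a > 0) * 1
  n <- nrow(X)
  t_adam <- 0
  best <- Inf; best_epoch <- 0L
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        A <- mlp_forward(W, X[b, , drop = FALSE], relu)
        P <- softmax_rows(A[[L + 1]])
        dZ <- (P - Y[b, , drop = FALSE]) / length(b)
        G <- mlp_grads(W, A, dZ, relu_grad)
        t_adam <- t_adam + 1
        for (l in seq_len(L)) {
          mth[[l]] <- 0.9 * mth[[l]] + 0.1 * G[[l]]
          vth[[l]] <- 0.999 * vth[[l]] + 0.001 * G[[l]]^2
          mhat <- mth[[l]] / (1 - 0.9^t_adam)
          vhat <- vth[[l]] / (1 - 0.999^t_adam)
          W[[l]] <- W[[l]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      P <- softmax_rows(mlp_forward(W, X, relu)[[L + 1]])
      loss <- -mean(rowSums(Y * log(pmax(P, 1e-12))))
      if (loss < best - 1e-5) { best <- loss; best_epoch <- ep }
      if (loss < 1e-5 || ep - best_epoch >= patience) break
    }
  })
  list(weights = W, loss = best)
}

predict_mlp <- function(fit, X, flavour) {
  L <- length(fit$weights)
  if (flavour == "classic") {
    O <- sigm(mlp_forward(fit$weights, X, sigm)[[L + 1]])
    O / pmax(rowSums(O), 1e-12)  # normalized logistic outputs
  } else {
    softmax_rows(mlp_forward(fit$weights, X, function(z) pmax(z, 0))[[L + 1]])
  }
}
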