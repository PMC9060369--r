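# Feedforward softmax network internals: forward pass, analytic gradients,
# and ADAM updates.  Parameters are lists of weight matrices W[[l]]
# (n_in x n_out) and bias vectors b[[l]].  The loss is the mean multinomial
# cross-entropy plus lambda * sum of squared weights (biases unpenalised).

nn_init <- function(n_in, hidden_sizes, n_out) {
  sizes <- c(n_in, hidden_sizes, n_out)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                     fan_in, sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

nn_activate <- function(Z, activation) {
  switch(activation,
         relu = pmax(Z, 0),
         softplus = {
           # overflow-safe log(1 + exp(z))
           out <- Z
           small <- Z < 30
           out[small] <- log1p(exp(Z[small]))
           out
         },
         abort(paste0("unknown activation: ", activation)))
}

nn_activate_grad <- function(Z, activation) {
  switch(activation,
         relu = (Z > 0) * 1,
         softplus = 1 / (1 + exp(-Z)))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass.  When training with dropout, inverted dropout masks are
# drawn from the current RNG stream and returned for the backward pass.
nn_forward <- function(params, X, activation, dropout_rate = 0, training = FALSE) {
  L <- length(params$W)
  A <- X
  Zs <- vector("list", L)
  As <- vector("list", L + 1L)
  masks <- vector("list", L)
  As[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% params$W[[l]] + rep(params$b[[l]], each = nrow(A))
    Zs[[l]] <- Z
    if (l < L) {
      A <- nn_activate(Z, activation)
      if (training && dropout_rate > 0) {
        mask <- matrix(runif(length(A)) >= dropout_rate, nrow(A), ncol(A)) /
          (1 - dropout_rate)
        A <- A * mask
        masks[[l]] <- mask
      }
    } else {
      A <- softmax_rows(Z)
    }
    As[[l + 1L]] <- A
  }
  list(probs = A, Zs = Zs, As = As, masks = masks)
}

# Mean cross-entropy + L2 penalty; y is an integer class index vector.
nn_loss <- function(params, X, y, lambda, activation) {
  fw <- nn_forward(params, X, activation)
  p <- fw$probs[cbind(seq_along(y), y)]
  ce <- -mean(log(pmax(p, 1e-300)))
  ce + lambda * sum(vapply(params$W, function(w) sum(w^2), numeric(1)))
}

# Analytic gradients of nn_loss at `params` (with optional dropout masks
# from a recorded forward pass).
nn_gradients <- function(params, X, y, lambda, activation, fw = NULL) {
  if (is.null(fw)) fw <- nn_forward(params, X, activation)
  L <- length(params$W)
  n <- nrow(X)
  Y <- matrix(0, n, ncol(fw$probs))
  Y[cbind(seq_len(n), y)] <- 1
  delta <- (fw$probs - Y) / n
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$As[[l]], delta) + 2 * lambda * params$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(params$W[[l]])
      if (!is.null(fw$masks[[l - 1L]])) delta <- delta * fw$masks[[l - 1L]]
      delta <- delta * nn_activate_grad(fw$Zs[[l - 1L]], activation)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}
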