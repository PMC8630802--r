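# Minimal dense feedforward networks with manual backpropagation and Adam.
# Actors and critics are 2-hidden-layer ReLU MLPs (64 units per layer);
# everything is plain base-R matrix algebra so training is deterministic
# given R's RNG seed.

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    bound <- 1 / sqrt(sizes[l])                # fan-in uniform init
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -bound, bound),
                     sizes[l], sizes[l + 1])
    b[[l]] <- stats::runif(sizes[l + 1], -bound, bound)
  }
  list(W = W, b = b, sizes = sizes)
}

# Forward pass; X is n x d. Returns output and per-layer caches for backprop.
# Hidden layers ReLU, output linear. Bias addition and ReLU avoid sweep/pmax
# for speed (this sits in the per-step training loop).
mlp_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  n <- nrow(X)
  Hs <- vector("list", L + 1L); Hs[[1L]] <- X
  H <- X
  for (l in seq_len(L)) {
    Z <- H %*% net$W[[l]] + rep(net$b[[l]], each = n)
    H <- if (l < L) Z * (Z > 0) else Z
    Hs[[l + 1L]] <- H
  }
  if (cache) list(out = H, Hs = Hs) else H
}

# Backward pass from output gradient dY (n x out). Returns weight/bias
# gradients and the gradient with respect to the input (needed to push the
# critic's action gradient into the actor).
mlp_backward <- function(net, fwd, dY) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dY
  for (l in L:1) {
    H_in <- fwd$Hs[[l]]
    dW[[l]] <- crossprod(H_in, delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      delta <- delta * (fwd$Hs[[l]] > 0)       # ReLU mask on hidden output
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(dW = dW, db = db, dX = delta)
}

adam_init <- function(net) {
  zeros <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  list(mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
       mb = lapply(net$b, zeros), vb = lapply(net$b, zeros),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(net, grads, opt, lr) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t; c2 <- 1 - opt$beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- opt$beta1 * opt$mW[[l]] + (1 - opt$beta1) * grads$dW[[l]]
    opt$vW[[l]] <- opt$beta2 * opt$vW[[l]] + (1 - opt$beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (opt$mW[[l]] / c1) / (sqrt(opt$vW[[l]] / c2) + opt$eps)
    opt$mb[[l]] <- opt$beta1 * opt$mb[[l]] + (1 - opt$beta1) * grads$db[[l]]
    opt$vb[[l]] <- opt$beta2 * opt$vb[[l]] + (1 - opt$beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (opt$mb[[l]] / c1) / (sqrt(opt$vb[[l]] / c2) + opt$eps)
  }
  list(net = net, opt = opt)
}

soft_update <- function(target, online, tau) {
  for (l in seq_along(target$W)) {
    target$W[[l]] <- (1 - tau) * target$W[[l]] + tau * online$W[[l]]
    target$b[[l]] <- (1 - tau) * target$b[[l]] + tau * online$b[[l]]
  }
  target
}

# Actor output squashing: raw linear output -> (tanh + 1)/2 in [0, 1].
squash <- function(z) (tanh(z) + 1) / 2
dsquash <- function(a) 2 * a * (1 - a)          # d squash / d z, from a
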