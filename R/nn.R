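# Dense feed-forward network primitives used by the quantifier.
# Plain-R matrices + BLAS; rows are samples. Deterministic given the RNG
# state at initialization and the batch order during training.

act_fun <- function(z, act) {
  switch(act,
    relu = pmax(z, 0),
    linear = z,
    sigmoid = 1 / (1 + exp(-z)),
    stop("unknown activation: ", act))
}

# derivative wrt pre-activation, expressed via z (pre) and a (post)
act_grad <- function(z, a, act) {
  switch(act,
    relu = (z > 0) * 1,
    linear = 1,
    sigmoid = a * (1 - a),
    stop("unknown activation: ", act))
}

# dims: length L+1 (input, hidden..., output); acts: length L
nn_new <- function(dims, acts) {
  stopifnot(length(acts) == length(dims) - 1L)
  W <- vector("list", length(acts))
  b <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    fan_in <- dims[l]
    sd <- if (acts[l] == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sd),
                     fan_in, dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b, acts = acts, dims = dims)
}

# forward pass; returns output and, if cache, pre-/post-activations
nn_forward <- function(net, X, cache = FALSE) {
  A <- X
  Zs <- if (cache) vector("list", length(net$acts)) else NULL
  As <- if (cache) vector("list", length(net$acts) + 1L) else NULL
  if (cache) As[[1L]] <- X
  for (l in seq_along(net$acts)) {
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], `+`)
    A <- act_fun(Z, net$acts[l])
    if (cache) { Zs[[l]] <- Z; As[[l + 1L]] <- A }
  }
  if (cache) list(out = A, Zs = Zs, As = As) else list(out = A)
}

# backward pass from dL/d(output); returns parameter grads and dL/dX
nn_backward <- function(net, fw, dOut) {
  L <- length(net$acts)
  dW <- vector("list", L); db <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- dA * act_grad(fw$Zs[[l]], fw$As[[l + 1L]], net$acts[l])
    dW[[l]] <- crossprod(fw$As[[l]], dZ)
    db[[l]] <- colSums(dZ)
    dA <- tcrossprod(dZ, net$W[[l]])
  }
  list(dW = dW, db = db, dX = dA)
}

adam_new <- function(net) {
  zW <- lapply(net$W, function(w) array(0, dim(w)))
  zb <- lapply(net$b, function(v) numeric(length(v)))
  list(mW = zW, vW = zW, mb = zb, vb = zb)
}

# coupled weight decay (decay added to the gradient before the moments),
# matching the convention of Adam with an L2 penalty
adam_step <- function(net, grads, state, t, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in seq_along(net$W)) {
    g <- grads$dW[[l]] + weight_decay * net$W[[l]]
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * g
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * g * g
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    gb <- grads$db[[l]] + weight_decay * net$b[[l]]
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * gb
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * gb * gb
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}
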