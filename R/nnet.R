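# Minimal dense-network engine used by the denoiser and the classifiers.
# Networks are lists of weight matrices (input x output) and bias vectors,
# trained with explicit reverse-mode gradients; all heavy lifting is BLAS
# matrix multiplication, which is fast enough at phantom resolution.

sigm <- function(z) 1 / (1 + exp(-z))

silu <- function(z) z * sigm(z)

silu_grad <- function(z) {
  s <- sigm(z)
  s * (1 + z * (1 - s))
}

#' Initialise a fully connected network
#'
#' @param sizes Integer vector of layer widths, input first, output last.
#' @param seed Integer seed for the weight draw.
#' @return A list with elements `W` (list of input-by-output matrices) and
#'   `b` (list of bias vectors); hidden layers use the SiLU activation, the
#'   output layer is linear.
#' @keywords internal
nn_init <- function(sizes, seed = 1L) {
  stopifnot(length(sizes) >= 2)
  withr::with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      n_in <- sizes[l]
      W[[l]] <- matrix(stats::rnorm(n_in * sizes[l + 1L], sd = sqrt(2 / n_in)),
                       n_in, sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
  })
  structure(list(W = W, b = b, sizes = sizes), class = "dense_net")
}

# Forward pass; X has one example per row. Returns the output and the
# per-layer pre-activations needed for the backward pass.
nn_forward <- function(net, X) {
  L <- length(net$W)
  Z <- vector("list", L)   # pre-activations
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) silu(Z[[l]]) else Z[[l]]
  }
  list(out = A[[L + 1L]], Z = Z, A = A)
}

# Reverse-mode pass. dOut is dLoss/dOutput (same shape as out). Returns
# parameter gradients and the gradient with respect to the input rows.
nn_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * silu_grad(cache$Z[[l]])
    gW[[l]] <- crossprod(cache$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(W = gW, b = gb, dX = delta)
}

# --- optimisers ----------------------------------------------------------

adam_init <- function(net) {
  zeros <- function(p) lapply(p, function(x) array(0, dim = dim(x) %||% length(x)))
  list(mW = zeros(net$W), vW = zeros(net$W),
       mb = lapply(net$b, function(x) numeric(length(x))),
       vb = lapply(net$b, function(x) numeric(length(x))),
       t = 0L)
}

adam_step <- function(net, grads, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / c1) /
      (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / c1) /
      (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

sgd_init <- function(net) {
  list(vW = lapply(net$W, function(x) array(0, dim = dim(x))),
       vb = lapply(net$b, function(x) numeric(length(x))))
}

sgd_step <- function(net, grads, state, lr, momentum = 0.9) {
  for (l in seq_along(net$W)) {
    state$vW[[l]] <- momentum * state$vW[[l]] - lr * grads$W[[l]]
    net$W[[l]] <- net$W[[l]] + state$vW[[l]]
    state$vb[[l]] <- momentum * state$vb[[l]] - lr * grads$b[[l]]
    net$b[[l]] <- net$b[[l]] + state$vb[[l]]
  }
  list(net = net, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise softmax with the usual max-shift for stability.
softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

# Dims-preserving clamp (pmin/pmax with a scalar first argument drop dims).
clip_range <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}
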