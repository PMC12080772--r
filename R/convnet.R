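# Small convolutional network (im2col formulation) used by the classifiers:
# three 3x3 'same' convolution blocks with SiLU, 2x2 mean pooling after the
# first two, global average pooling, and a dense head. Weight sharing makes
# lesion detection translation-invariant, which is what separates the
# disease grades. Parameters live in the same $W / $b list layout as the
# dense network, so the optimisers apply unchanged.

# Gather indices for a 3x3 'same' convolution on an H x W x C activation
# stored as a flattened row (y fastest, then x, then channel). Padding
# positions point at an extra zero column (index d + 1).
conv_idx <- function(H, W, C) {
  d <- H * W * C
  pad <- d + 1L
  y <- rep(seq_len(H), W)
  x <- rep(seq_len(W), each = H)
  blocks <- list()
  for (c in seq_len(C)) {
    for (dx in -1:1) {
      for (dy in -1:1) {
        yy <- y + dy; xx <- x + dx
        ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
        src <- ifelse(ok, yy + (xx - 1L) * H + (c - 1L) * H * W, pad)
        blocks[[length(blocks) + 1L]] <- src
      }
    }
  }
  unlist(blocks)
}

# Gather indices for 2x2 mean pooling (H, W even).
pool_idx <- function(H, W, C) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  y <- rep(seq_len(H2), W2)
  x <- rep(seq_len(W2), each = H2)
  blocks <- list()
  for (c in seq_len(C)) {
    for (dx in 0:1) {
      for (dy in 0:1) {
        src <- (2L * y - 1L + dy) + (2L * x - 2L + dx) * H + (c - 1L) * H * W
        blocks[[length(blocks) + 1L]] <- src
      }
    }
  }
  unlist(blocks)
}

conv_forward_layer <- function(A, idx, W, b, HW) {
  B <- nrow(A)
  A0 <- cbind(A, 0)
  G <- A0[, idx, drop = FALSE]                 # B x (HW * 9C)
  M <- matrix(G, B * HW, length(idx) %/% HW)   # (B*HW) x 9C
  Z <- sweep(M %*% W, 2L, b, "+")              # (B*HW) x F
  list(out = matrix(Z, B, HW * ncol(W)), M = M)
}

# Scatter groups for the conv backward pass: for each of the 9 spatial
# offsets, the (source, patch-column) index pairs across all channels.
# Within one offset the source columns are distinct, so the adds vectorise.
conv_scatter_groups <- function(idx, HW, d_in) {
  C <- length(idx) %/% (HW * 9L)
  lapply(seq_len(9L), function(o) {
    blocks <- (seq_len(C) - 1L) * 9L + o
    dst <- as.vector(vapply(blocks, function(b) ((b - 1L) * HW + 1L):(b * HW),
                            integer(HW)))
    src <- idx[dst]
    ok <- src <= d_in
    list(src = src[ok], dst = dst[ok])
  })
}

conv_backward_layer <- function(dOut, M, idx, W, HW, d_in, B, groups = NULL) {
  F_ <- ncol(W)
  dZ <- matrix(dOut, B * HW, F_)
  dW <- crossprod(M, dZ)
  db <- colSums(dZ)
  dM <- tcrossprod(dZ, W)                      # (B*HW) x 9C
  dG <- matrix(dM, B, HW * ncol(dM))
  dA <- matrix(0, B, d_in)
  if (is.null(groups)) groups <- conv_scatter_groups(idx, HW, d_in)
  for (g in groups) {
    dA[, g$src] <- dA[, g$src] + dG[, g$dst, drop = FALSE]
  }
  list(dW = dW, db = db, dX = dA)
}

pool_forward <- function(A, idx, HW2) {
  B <- nrow(A)
  G <- A[, idx, drop = FALSE]
  n_blocks <- length(idx) %/% HW2              # 4 per channel
  C <- n_blocks %/% 4L
  out <- matrix(0, B, HW2 * C)
  for (c in seq_len(C)) {
    acc <- 0
    for (q in 1:4) {
      o <- (c - 1L) * 4L + q
      acc <- acc + G[, ((o - 1L) * HW2 + 1L):(o * HW2), drop = FALSE]
    }
    out[, ((c - 1L) * HW2 + 1L):(c * HW2)] <- acc / 4
  }
  out
}

pool_backward <- function(dOut, idx, HW2, d_in) {
  B <- nrow(dOut)
  dA <- matrix(0, B, d_in)
  n_blocks <- length(idx) %/% HW2
  C <- n_blocks %/% 4L
  for (c in seq_len(C)) {
    dblock <- dOut[, ((c - 1L) * HW2 + 1L):(c * HW2), drop = FALSE] / 4
    for (q in 1:4) {
      o <- (c - 1L) * 4L + q
      cols <- idx[((o - 1L) * HW2 + 1L):(o * HW2)]
      dA[, cols] <- dA[, cols] + dblock
    }
  }
  dA
}

#' Initialise the small convolutional classifier network
#'
#' @param img_dim `c(H, W)` or `c(H, W, C)`; H and W must be multiples of 4.
#' @param channels Widths of the three convolution blocks.
#' @param K Number of output classes.
#' @param seed Integer seed for the weight draw.
#' @return A `conv_net` with `$W`/`$b` parameter lists and precomputed
#'   gather indices.
#' @keywords internal
cnn_init <- function(img_dim, channels = c(8L, 16L, 16L), K, seed = 1L) {
  H <- img_dim[1]; W <- img_dim[2]
  C <- if (length(img_dim) >= 3L) img_dim[3] else 1L
  if (H %% 4L != 0L || W %% 4L != 0L) stop("image sides must be multiples of 4")
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  meta <- list(
    H = H, W = W, C = C, channels = channels, K = K,
    idx1 = conv_idx(H, W, C), HW1 = H * W,
    pidx1 = pool_idx(H, W, c1), HWp1 = (H %/% 2L) * (W %/% 2L),
    idx2 = conv_idx(H %/% 2L, W %/% 2L, c1), HW2 = (H %/% 2L) * (W %/% 2L),
    pidx2 = pool_idx(H %/% 2L, W %/% 2L, c2), HWp2 = (H %/% 4L) * (W %/% 4L),
    idx3 = conv_idx(H %/% 4L, W %/% 4L, c2), HW3 = (H %/% 4L) * (W %/% 4L))
  meta$grp1 <- conv_scatter_groups(meta$idx1, meta$HW1, H * W * C)
  meta$grp2 <- conv_scatter_groups(meta$idx2, meta$HW2, meta$HW2 * c1)
  meta$grp3 <- conv_scatter_groups(meta$idx3, meta$HW3, meta$HW3 * c2)
  withr::with_seed(seed, {
    Wl <- list(matrix(stats::rnorm(9 * C * c1, sd = sqrt(2 / (9 * C))), 9 * C, c1),
               matrix(stats::rnorm(9 * c1 * c2, sd = sqrt(2 / (9 * c1))), 9 * c1, c2),
               matrix(stats::rnorm(9 * c2 * c3, sd = sqrt(2 / (9 * c2))), 9 * c2, c3),
               matrix(stats::rnorm(c3 * K, sd = sqrt(2 / c3)), c3, K))
    bl <- list(numeric(c1), numeric(c2), numeric(c3), numeric(K))
  })
  structure(list(W = Wl, b = bl, meta = meta), class = "conv_net")
}

cnn_forward <- function(net, X) {
  m <- net$meta
  B <- nrow(X)
  l1 <- conv_forward_layer(X, m$idx1, net$W[[1]], net$b[[1]], m$HW1)
  a1 <- silu(l1$out)
  p1 <- pool_forward(a1, m$pidx1, m$HWp1)
  l2 <- conv_forward_layer(p1, m$idx2, net$W[[2]], net$b[[2]], m$HW2)
  a2 <- silu(l2$out)
  p2 <- pool_forward(a2, m$pidx2, m$HWp2)
  l3 <- conv_forward_layer(p2, m$idx3, net$W[[3]], net$b[[3]], m$HW3)
  a3 <- silu(l3$out)
  # global average pool per channel
  c3 <- m$channels[3]
  gap <- matrix(0, B, c3)
  for (c in seq_len(c3)) {
    gap[, c] <- rowMeans(a3[, ((c - 1L) * m$HW3 + 1L):(c * m$HW3), drop = FALSE])
  }
  out <- sweep(gap %*% net$W[[4]], 2L, net$b[[4]], "+")
  list(out = out, X = X, l1 = l1, a1 = a1, p1 = p1, l2 = l2, a2 = a2,
       p2 = p2, l3 = l3, a3 = a3, gap = gap)
}

cnn_backward <- function(net, cache, dOut) {
  m <- net$meta
  B <- nrow(dOut)
  c3 <- m$channels[3]
  dW4 <- crossprod(cache$gap, dOut)
  db4 <- colSums(dOut)
  dgap <- tcrossprod(dOut, net$W[[4]])
  da3 <- matrix(0, B, m$HW3 * c3)
  for (c in seq_len(c3)) {
    da3[, ((c - 1L) * m$HW3 + 1L):(c * m$HW3)] <- dgap[, c] / m$HW3
  }
  dl3 <- da3 * silu_grad(cache$l3$out)
  g3 <- conv_backward_layer(dl3, cache$l3$M, m$idx3, net$W[[3]], m$HW3,
                            ncol(cache$p2), B, m$grp3)
  dp2 <- g3$dX
  da2 <- pool_backward(dp2, m$pidx2, m$HWp2, ncol(cache$a2))
  dl2 <- da2 * silu_grad(cache$l2$out)
  g2 <- conv_backward_layer(dl2, cache$l2$M, m$idx2, net$W[[2]], m$HW2,
                            ncol(cache$p1), B, m$grp2)
  dp1 <- g2$dX
  da1 <- pool_backward(dp1, m$pidx1, m$HWp1, ncol(cache$a1))
  dl1 <- da1 * silu_grad(cache$l1$out)
  g1 <- conv_backward_layer(dl1, cache$l1$M, m$idx1, net$W[[1]], m$HW1,
                            ncol(cache$X), B, m$grp1)
  list(W = list(g1$dW, g2$dW, g3$dW, dW4),
       b = list(g1$db, g2$db, g3$db, db4),
       dX = g1$dX)
}

# Dispatch helpers so classifier code is agnostic to the network family.
net_forward <- function(net, X) {
  if (inherits(net, "conv_net")) cnn_forward(net, X) else nn_forward(net, X)
}

net_backward <- function(net, cache, dOut) {
  if (inherits(net, "conv_net")) cnn_backward(net, cache, dOut)
  else nn_backward(net, cache, dOut)
}

# --- convolutional denoiser ----------------------------------------------
# Full-resolution stack of 3x3 convolutions (no pooling): noise prediction
# is a local operation once the analytic skip handles the global scale.
# The time embedding enters as constant extra channels.

cnn_denoiser_init <- function(img_dim, channels = c(16L, 16L), t_channels = 4L,
                              seed = 1L) {
  H <- img_dim[1]; W <- img_dim[2]
  C <- if (length(img_dim) >= 3L) img_dim[3] else 1L
  c0 <- C + t_channels; c1 <- channels[1]; c2 <- channels[2]
  meta <- list(H = H, W = W, C = C, t_channels = t_channels,
               channels = channels, HW = H * W,
               idx1 = conv_idx(H, W, c0),
               idx2 = conv_idx(H, W, c1),
               idx3 = conv_idx(H, W, c2))
  meta$grp1 <- conv_scatter_groups(meta$idx1, meta$HW, meta$HW * c0)
  meta$grp2 <- conv_scatter_groups(meta$idx2, meta$HW, meta$HW * c1)
  meta$grp3 <- conv_scatter_groups(meta$idx3, meta$HW, meta$HW * c2)
  withr::with_seed(seed, {
    Wl <- list(matrix(stats::rnorm(9 * c0 * c1, sd = sqrt(2 / (9 * c0))), 9 * c0, c1),
               matrix(stats::rnorm(9 * c1 * c2, sd = sqrt(2 / (9 * c1))), 9 * c1, c2),
               matrix(stats::rnorm(9 * c2 * C, sd = 0.1 * sqrt(2 / (9 * c2))), 9 * c2, C))
    bl <- list(numeric(c1), numeric(c2), numeric(C))
  })
  structure(list(W = Wl, b = bl, meta = meta), class = "conv_denoiser_net")
}

cnn_den_forward <- function(net, X, tfeat) {
  m <- net$meta
  B <- nrow(X)
  # broadcast each time feature over the pixel grid as a constant channel
  Xin <- cbind(X, matrix(tfeat[, rep(seq_len(ncol(tfeat)), each = m$HW)],
                         B, m$t_channels * m$HW))
  l1 <- conv_forward_layer(Xin, m$idx1, net$W[[1]], net$b[[1]], m$HW)
  a1 <- silu(l1$out)
  l2 <- conv_forward_layer(a1, m$idx2, net$W[[2]], net$b[[2]], m$HW)
  a2 <- silu(l2$out)
  l3 <- conv_forward_layer(a2, m$idx3, net$W[[3]], net$b[[3]], m$HW)
  list(out = l3$out, Xin = Xin, l1 = l1, a1 = a1, l2 = l2, a2 = a2, l3 = l3)
}

cnn_den_backward <- function(net, cache, dOut) {
  m <- net$meta
  B <- nrow(dOut)
  g3 <- conv_backward_layer(dOut, cache$l3$M, m$idx3, net$W[[3]], m$HW,
                            ncol(cache$a2), B, m$grp3)
  dl2 <- g3$dX * silu_grad(cache$l2$out)
  g2 <- conv_backward_layer(dl2, cache$l2$M, m$idx2, net$W[[2]], m$HW,
                            ncol(cache$a1), B, m$grp2)
  dl1 <- g2$dX * silu_grad(cache$l1$out)
  g1 <- conv_backward_layer(dl1, cache$l1$M, m$idx1, net$W[[1]], m$HW,
                            ncol(cache$Xin), B, m$grp1)
  list(W = list(g1$dW, g2$dW, g3$dW),
       b = list(g1$db, g2$db, g3$db))
}
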