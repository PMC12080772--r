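# Denoising diffusion probabilistic model (DDPM) at phantom scale: linear
# beta schedule, closed-form forward marginal, epsilon-prediction denoiser,
# and the ancestral reverse sampler with an optional externally supplied
# mean shift (the hook used by classifier guidance).
#
# The diffusion value range is [-1, 1]; conversion from/to the [0, 1] image
# range happens at the module boundary.

#' Construct a linear noise schedule
#'
#' Per-step variances `beta_t` are linearly spaced between `beta_min` and
#' `beta_max`. The defaults rescale the reference 1000-step endpoints
#' (1e-4, 0.02) by `1000 / T`, which preserves the terminal signal level
#' `alpha_bar_T` when the number of steps is reduced (`beta_max` is capped
#' at 0.5 so that very short toy schedules remain valid).
#'
#' @param T Number of diffusion steps (>= 2).
#' @param beta_min,beta_max Endpoint variances, `0 < beta_min < beta_max < 1`.
#' @return A `noise_schedule` with fields `T`, `beta`, `alpha`, `alpha_bar`.
#' @export
make_linear_schedule <- function(T = 250L, beta_min = NULL, beta_max = NULL) {
  if (T < 2) stop("T must be at least 2")
  if (is.null(beta_min)) beta_min <- min(0.05, 1e-4 * (1000 / T))
  if (is.null(beta_max)) beta_max <- min(0.5, 0.02 * (1000 / T))
  if (!(beta_min > 0 && beta_min < beta_max && beta_max < 1)) {
    stop("need 0 < beta_min < beta_max < 1")
  }
  beta <- seq(beta_min, beta_max, length.out = T)
  alpha <- 1 - beta
  structure(list(T = as.integer(T), beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha)),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> T=%d, beta in [%.2e, %.2e], alpha_bar_T=%.3e\n",
              x$T, x$beta[1], x$beta[x$T], x$alpha_bar[x$T]))
  invisible(x)
}

# alpha_bar with the t = 0 convention alpha_bar_0 = 1
abar_at <- function(schedule, t) {
  if (any(t < 0) || any(t > schedule$T)) stop("t out of range [0, T]")
  c(1, schedule$alpha_bar)[t + 1L]
}

#' Sample from the forward-process marginal q(x_t | x_0)
#'
#' `x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) noise`.
#'
#' @param x0 Numeric vector or matrix (one image per row), in `[-1, 1]`.
#' @param t Step index (scalar, or one per row), `0 <= t <= T`; `t = 0`
#'   returns `x0` unchanged.
#' @param noise Standard-normal array of `x0`'s shape; drawn from the current
#'   RNG stream when `NULL`.
#' @param schedule A `noise_schedule`.
#' @return Array of `x0`'s shape.
#' @export
q_sample <- function(x0, t, noise = NULL, schedule) {
  ab <- abar_at(schedule, t)
  if (is.null(noise)) {
    noise <- if (is.matrix(x0)) matrix(stats::rnorm(length(x0)), nrow(x0))
             else stats::rnorm(length(x0))
  }
  # with per-row t, ab (length n) recycles down the rows of the matrix
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

#' Invert the forward marginal to estimate x_0
#'
#' `x0_hat = (x_t - sqrt(1 - alpha_bar_t) eps_hat) / sqrt(alpha_bar_t)`:
#' the denoised estimate of the original image from the noisy state at `t`,
#' exact when `eps_hat` is the true noise.
#'
#' @param x_t Noisy state (vector or matrix of rows).
#' @param t Step index, `t >= 1`.
#' @param eps_hat Predicted noise, same shape as `x_t`.
#' @param schedule A `noise_schedule`.
#' @return Estimate of `x0`, same shape as `x_t`.
#' @export
predict_x0 <- function(x_t, t, eps_hat, schedule) {
  if (any(t < 1)) stop("t must be >= 1")
  ab <- abar_at(schedule, t)
  if (any(ab <= 0)) stop("alpha_bar_t must be positive")
  (x_t - sqrt(1 - ab) * eps_hat) / sqrt(ab)
}

# Posterior variance beta_tilde_t; zero at t = 1 (no noise in the last step).
beta_tilde <- function(schedule, t) {
  ab_prev <- abar_at(schedule, t - 1L)
  ab <- abar_at(schedule, t)
  (1 - ab_prev) / (1 - ab) * schedule$beta[t]
}

#' One ancestral reverse-diffusion step
#'
#' Draws `x_{t-1} ~ N(mu_theta(x_t, t) + mean_shift, sigma_t^2 I)` with
#' `mu_theta = (x_t - beta_t / sqrt(1 - alpha_bar_t) eps_hat) / sqrt(alpha_t)`
#' and `sigma_t^2` the forward-posterior variance `beta_tilde_t` (zero at
#' `t = 1`, so the final step adds no noise). `mean_shift = 0` gives the
#' unconditional DDPM sampler.
#'
#' @param x_t Current state (vector or matrix of rows).
#' @param t Step index, `t >= 1`.
#' @param eps_hat Predicted noise at `(x_t, t)`.
#' @param schedule A `noise_schedule`.
#' @param mean_shift Additive shift of the transition mean (guidance hook).
#' @param noise Optional standard-normal array (for reproducing a trajectory
#'   exactly); drawn from the current RNG stream when `NULL`.
#' @return The state at `t - 1`, same shape as `x_t`.
#' @export
reverse_step <- function(x_t, t, eps_hat, schedule, mean_shift = 0, noise = NULL) {
  if (any(t < 1)) stop("t must be >= 1 (t = 0 is the end of the chain)")
  ab <- abar_at(schedule, t)
  mu <- (x_t - schedule$beta[t] / sqrt(1 - ab) * eps_hat) / sqrt(schedule$alpha[t])
  s2 <- beta_tilde(schedule, t)
  if (s2 > 0) {
    if (is.null(noise)) {
      noise <- if (is.matrix(x_t)) matrix(stats::rnorm(length(x_t)), nrow(x_t))
               else stats::rnorm(length(x_t))
    }
    mu + mean_shift + sqrt(s2) * noise
  } else {
    mu + mean_shift
  }
}

# --- denoiser ------------------------------------------------------------

# Sinusoidal features of t / T on log-spaced frequencies; 16 columns.
time_embedding <- function(t, T, dims = 16L) {
  half <- dims %/% 2L
  freqs <- exp(seq(log(1), log(T / 2), length.out = half))
  tt <- t / T
  ang <- outer(tt, freqs * 2 * pi)
  cbind(sin(ang), cos(ang))
}

#' Predict noise with a trained denoiser
#'
#' The network predicts a correction on top of the analytic skip term
#' `sqrt(1 - alpha_bar_t) x_t` (the conditional mean of the noise under a
#' standard-normal image prior). The default architecture is a stack of
#' full-resolution 3x3 convolutions with the sinusoidal time embedding
#' broadcast as constant channels; a dense network on the flattened image
#' is available via `arch = "mlp"` in [train_denoiser()].
#'
#' @param denoiser A `denoiser` object from [train_denoiser()].
#' @param x_t Matrix of noisy states (one per row, `[-1, 1]` scale).
#' @param t Step index (scalar or one per row).
#' @return Matrix of predicted noise, same shape as `x_t`.
#' @export
denoiser_eps <- function(denoiser, x_t, t) {
  if (!is.matrix(x_t)) x_t <- matrix(x_t, 1L)
  emb <- time_embedding(rep_len(t, nrow(x_t)), denoiser$schedule$T,
                        denoiser$temb_dims)
  out <- if (inherits(denoiser$net, "conv_denoiser_net")) {
    cnn_den_forward(denoiser$net, x_t, emb)$out
  } else {
    nn_forward(denoiser$net, cbind(x_t, emb))$out
  }
  ab <- abar_at(denoiser$schedule, t)
  out + sqrt(1 - ab) * x_t
}

#' Train an epsilon-prediction denoiser
#'
#' Minimises `E ||eps - eps_hat(x_t, t)||^2` over uniformly drawn `t` and
#' standard-normal noise, with Adam. Images enter in `[0, 1]` and are mapped
#' to the internal `[-1, 1]` range.
#'
#' @param X Matrix of flattened training images (rows, values in `[0, 1]`).
#' @param schedule A `noise_schedule`.
#' @param iterations Number of minibatch iterations.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param img_dim Image dimensions `c(H, W)` or `c(H, W, C)`; required for
#'   the convolutional architecture.
#' @param arch `"cnn"` (full-resolution convolutional stack, the default
#'   when `img_dim` is given) or `"mlp"` (dense network).
#' @param hidden Hidden-layer widths of the dense architecture.
#' @param seed Integer seed (initialisation and minibatch/noise draws).
#' @return A `denoiser` object with the network, schedule, and the training
#'   loss curve (recorded every 25 iterations).
#' @export
train_denoiser <- function(X, schedule, iterations = 2000L, batch_size = 16L,
                           lr = 1e-3, img_dim = NULL,
                           arch = if (is.null(img_dim)) "mlp" else "cnn",
                           hidden = c(256L, 256L), seed = 1L) {
  if (!is.matrix(X) || nrow(X) == 0L) stop("X must be a non-empty matrix of images")
  d <- ncol(X)
  Z <- 2 * X - 1
  temb_dims <- if (arch == "cnn") 4L else 16L
  net <- if (arch == "cnn") cnn_denoiser_init(img_dim, t_channels = temb_dims,
                                              seed = seed)
         else nn_init(c(d + 16L, hidden, d), seed = seed)
  opt <- adam_init(net)
  losses <- numeric(0)
  withr::with_seed(seed + 1L, {
    for (it in seq_len(iterations)) {
      idx <- sample.int(nrow(Z), batch_size, replace = nrow(Z) < batch_size)
      t <- sample.int(schedule$T, batch_size, replace = TRUE)
      x0 <- Z[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(batch_size * d), batch_size)
      ab <- abar_at(schedule, t)
      xt <- sqrt(ab) * x0 + sqrt(1 - ab) * eps
      emb <- time_embedding(t, schedule$T, temb_dims)
      fw <- if (arch == "cnn") cnn_den_forward(net, xt, emb)
            else nn_forward(net, cbind(xt, emb))
      eps_hat <- fw$out + sqrt(1 - ab) * xt
      resid <- eps_hat - eps
      loss <- mean(resid^2)
      if (it %% 25L == 1L) losses <- c(losses, loss)
      dres <- 2 * resid / length(resid)
      gr <- if (arch == "cnn") cnn_den_backward(net, fw, dres)
            else nn_backward(net, fw, dres)
      st <- adam_step(net, gr, opt, lr = lr)
      net <- st$net; opt <- st$state
    }
  })
  structure(list(net = net, schedule = schedule, d = d,
                 img_dim = img_dim, temb_dims = temb_dims,
                 iterations = as.integer(iterations), loss_curve = losses),
            class = "denoiser")
}

#' @export
print.denoiser <- function(x, ...) {
  cat(sprintf("<denoiser> d=%d, T=%d, %d iterations, final loss %.4f\n",
              x$d, x$schedule$T, x$iterations, utils::tail(x$loss_curve, 1)))
  invisible(x)
}

#' @export
plot.denoiser <- function(x, ...) {
  graphics::plot(seq_along(x$loss_curve) * 25L, x$loss_curve, type = "l",
                 xlab = "iteration", ylab = "training MSE", ...)
  invisible(x)
}

#' Draw unconditional samples from a trained denoiser
#'
#' Runs the full reverse chain from standard-normal states at `t = T` down
#' to `t = 0` with zero mean shift, then maps back to `[0, 1]` and clips.
#'
#' @param denoiser A `denoiser`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Matrix with one flattened sample per row, values in `[0, 1]`.
#' @export
sample_unconditional <- function(denoiser, n = 1L, seed = 1L) {
  sch <- denoiser$schedule
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * denoiser$d), n)
    for (t in rev(seq_len(sch$T))) {
      eps_hat <- denoiser_eps(denoiser, x, t)
      x <- reverse_step(x, t, eps_hat, sch)
    }
    clip_range((x + 1) / 2, 0, 1)
  })
}
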