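# Diffusion visual counterfactuals: guided reverse diffusion starting from
# the half-noised original. At every step the transition mean is shifted by
# a weighted sum of (i) the classifier's gradient of the target-class
# log-probability, evaluated on the denoised estimate x0_hat and taken with
# respect to the noisy state through the predict_x0 map, and (ii) a distance
# regularisation pulling x0_hat back towards the original image.

#' Guidance configuration for diffusion counterfactuals
#'
#' @param target Target class index (1-based).
#' @param lambda_d Distance-regularisation strength, `>= 0`. Smaller values
#'   allow larger changes to the image.
#' @param alpha Cone half-angle in degrees (used in `"cone"` mode).
#' @param start_fraction Fraction of the chain at which guided reverse
#'   diffusion starts (`0 < start_fraction <= 1`); the default 1/2 starts
#'   from the half-noised image.
#' @param mode Which gradients guide the sampler: `"plain"`, `"robust"`, or
#'   `"cone"` (robust gradients projected onto a cone around plain ones).
#' @param s Guidance scale applied to the normalised classifier gradient.
#'   The default 3 makes the classifier term outweigh the generative prior:
#'   with per-term unit normalisation, equal weighting leaves the
#'   lesion-rich prior free to repaint lesions that a diseased-to-healthy
#'   counterfactual should remove.
#' @param distance_p Norm order of the distance penalty (2 = Euclidean).
#' @param scale Per-step scaling of the shift: `"std"` multiplies the
#'   combined unit-normalised directions by the reverse-step standard
#'   deviation `sigma_t`, `"variance"` by `sigma_t^2`.
#' @param seed Integer seed for the noising and sampling randomness.
#' @return A `guidance_config` list.
#' @export
guidance_config <- function(target = 1L, lambda_d = 0.5, alpha = 30,
                            start_fraction = 0.5,
                            mode = c("cone", "plain", "robust"), s = 3,
                            distance_p = 2, scale = c("std", "variance"),
                            seed = 1L) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  if (!(start_fraction > 0 && start_fraction <= 1)) {
    stop("start_fraction must lie in (0, 1]")
  }
  if (lambda_d < 0) stop("lambda_d must be non-negative")
  if (!(alpha > 0 && alpha < 90)) stop("alpha must lie in (0, 90)")
  structure(list(target = as.integer(target), lambda_d = lambda_d,
                 alpha = alpha, start_fraction = start_fraction, mode = mode,
                 s = s, distance_p = distance_p, scale = scale,
                 seed = as.integer(seed)),
            class = "guidance_config")
}

# Map internal [-1,1] states to clamped [0,1] classifier inputs.
to_image_range <- function(Z) clip_range((Z + 1) / 2, 0, 1)

#' Classifier guidance gradient at a noisy state
#'
#' Returns the gradient of `log p(k | x0_hat)` with respect to the noisy
#' state `x_t`, where `x0_hat` is the denoised estimate carried by `state`.
#' The gradient is taken through the `predict_x0` map with the denoiser
#' output treated as constant, contributing the factor
#' `1 / sqrt(alpha_bar_t)` (times the range conversion constant). In
#' `"cone"` mode the plain and robust gradients are each computed this way
#' and combined with [cone_project()].
#'
#' @param classifiers List with elements `plain` and `robust`
#'   (`retina_classifier`s on the same label space).
#' @param state List with `x_t` (matrix of rows), `t`, and `x0_hat`
#'   (denoised estimate rows on the `[-1,1]` scale).
#' @param k Target class index.
#' @param config A [guidance_config()].
#' @param schedule A `noise_schedule`.
#' @return Matrix of gradient rows, same shape as `state$x_t`.
#' @export
guidance_gradient <- function(classifiers, state, k, config, schedule) {
  K <- (classifiers$plain %||% classifiers$robust)$K
  if (k > K || k < 1) stop("target class k out of range")
  X01 <- to_image_range(state$x0_hat)
  chain <- 0.5 / sqrt(abar_at(schedule, state$t))  # d x01 / d x_t, eps detached
  g_of <- function(clf) clf_input_grad_logp(clf, X01, k) * chain
  G <- switch(config$mode,
              plain = g_of(classifiers$plain),
              robust = g_of(classifiers$robust),
              cone = cone_project_rows(g_of(classifiers$robust),
                                       g_of(classifiers$plain), config$alpha))
  G
}

#' Distance-regularisation gradient
#'
#' Gradient of `-lambda_d * d(x0, x0_hat)` with respect to the denoised
#' estimate, for `d` the Euclidean distance: a pull of `x0_hat` towards the
#' original image. The positive chain factor through `predict_x0` is left to
#' the caller (it cancels under the unit-normalisation of [total_shift()]).
#'
#' @param x0_hat Matrix of denoised-estimate rows.
#' @param x0 Matrix of original-image rows (same scale as `x0_hat`).
#' @param lambda_d Regularisation strength.
#' @param p Norm order (only `p = 2` is implemented).
#' @return Matrix of gradient rows.
#' @export
distance_gradient <- function(x0_hat, x0, lambda_d, p = 2) {
  if (p != 2) stop("only the Euclidean distance (p = 2) is implemented")
  if (lambda_d == 0) return(0 * x0_hat)
  diff <- x0_hat - x0
  nrm <- sqrt(rowSums(diff^2))
  nrm[nrm == 0] <- 1
  -lambda_d * diff / nrm
}

#' Combine guidance and distance gradients into a mean shift
#'
#' Adaptive parameterisation: each gradient row is normalised to unit
#' Euclidean norm so that weights act consistently across images and steps,
#' then combined as `s * g_guidance + lambda_d * g_distance` and scaled by
#' the reverse-step noise scale at `t` (`sigma_t` by default, `sigma_t^2`
#' when `config$scale = "variance"`).
#'
#' @param g_guidance,g_distance Gradient matrices (rows).
#' @param schedule A `noise_schedule`.
#' @param t Step index.
#' @param config A [guidance_config()].
#' @return The mean-shift matrix for [reverse_step()].
#' @export
total_shift <- function(g_guidance, g_distance, schedule, t, config) {
  unit_rows <- function(G) {
    nrm <- sqrt(rowSums(G^2))
    nrm[nrm == 0] <- 1
    G / nrm
  }
  s2 <- beta_tilde(schedule, t)
  fac <- if (config$scale == "variance") s2 else sqrt(s2)
  fac * (config$s * unit_rows(g_guidance) + config$lambda_d * unit_rows(g_distance))
}

#' Generate diffusion visual counterfactuals
#'
#' Noises the original image(s) to step `ceiling(T * start_fraction)` via
#' the forward marginal, then runs guided reverse diffusion down to step 0:
#' at each step the denoised estimate `x0_hat` is formed with
#' [predict_x0()], classifier and distance gradients are computed on it,
#' combined with [total_shift()], and applied as the transition-mean shift
#' of [reverse_step()]. Deterministic given `config$seed`.
#'
#' @param x0 Original image(s): an H x W (x C) array in `[0,1]`, a
#'   `labeled_image`, or a matrix with one flattened image per row.
#' @param k Target class index (overrides `config$target` when given).
#' @param denoiser A trained `denoiser`.
#' @param classifiers List with `plain` and `robust` classifiers.
#' @param schedule Defaults to the denoiser's schedule.
#' @param config A [guidance_config()].
#' @return A `counterfactual_result`: `image` (matrix of rows in `[0,1]`),
#'   `target_confidence` (plain classifier probability of `k`),
#'   `l2_distance` to the original on the `[0,1]` scale, `flipped`
#'   (argmax class equals `k`), and the per-step confidence `trace`.
#' @export
generate_dvc <- function(x0, k = NULL, denoiser, classifiers,
                         schedule = denoiser$schedule,
                         config = guidance_config()) {
  if (inherits(x0, "labeled_image")) x0 <- x0$pixels
  X0 <- if (is.matrix(x0) && ncol(x0) == denoiser$d) x0
        else matrix(as.vector(x0), 1L)
  if (ncol(X0) != denoiser$d) stop("image shape incompatible with the denoiser")
  if (is.null(k)) k <- config$target
  Z0 <- 2 * X0 - 1
  t_start <- ceiling(schedule$T * config$start_fraction)
  trace <- matrix(NA_real_, nrow(X0), t_start)
  withr::with_seed(config$seed, {
    xt <- q_sample(Z0, t_start, schedule = schedule)
    for (t in seq(t_start, 1L)) {
      eps_hat <- denoiser_eps(denoiser, xt, t)
      x0h <- clip_range(predict_x0(xt, t, eps_hat, schedule), -1, 1)
      state <- list(x_t = xt, t = t, x0_hat = x0h)
      gg <- guidance_gradient(classifiers, state, k, config, schedule)
      gd <- distance_gradient(x0h, Z0, config$lambda_d)
      shift <- total_shift(gg, gd, schedule, t, config)
      trace[, t] <- predict(classifiers$plain, to_image_range(x0h))[, k]
      xt <- reverse_step(xt, t, eps_hat, schedule, mean_shift = shift)
    }
    out <- to_image_range(xt)
  })
  conf <- predict(classifiers$plain, out)[, k]
  cls <- max.col(predict(classifiers$plain, out), ties.method = "first")
  structure(list(image = out, target = k,
                 target_confidence = conf,
                 l2_distance = sqrt(rowSums((out - X0)^2)),
                 flipped = cls == k,
                 trace = trace, config = config),
            class = "counterfactual_result")
}

#' @export
print.counterfactual_result <- function(x, ...) {
  cat(sprintf(
    "<counterfactual_result> n=%d, target=%d, flipped %d/%d, median conf %.3f, median l2 %.2f\n",
    nrow(x$image), x$target, sum(x$flipped), length(x$flipped),
    stats::median(x$target_confidence), stats::median(x$l2_distance)))
  invisible(x)
}

#' @export
plot.counterfactual_result <- function(x, i = 1L, ...) {
  graphics::plot(rev(x$trace[i, ]), type = "l", xlab = "reverse step",
                 ylab = "target confidence", ylim = c(0, 1), ...)
  invisible(x)
}
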