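# Sparse visual counterfactuals: maximise the target-class log-probability
# inside an lp-norm ball around the original image with Frank-Wolfe
# iterations (closed-form linear maximisation over the ball, diminishing
# 2/(t+2) steps, box handled by clipping). The l4 ball is the default, which
# concentrates changes on few pixels.

#' Sparse-counterfactual configuration
#'
#' @param target Target class index (1-based).
#' @param eps Radius of the `lp` ball around the original image.
#' @param p Norm order; one of 1.5, 2, 4.
#' @param steps Number of Frank-Wolfe iterations.
#' @param ensemble If `TRUE`, maximise the summed log-probabilities of the
#'   plain and robust classifiers; otherwise the robust classifier alone.
#' @param seed Integer seed (kept for interface symmetry; the optimiser is
#'   deterministic).
#' @return An `svc_config` list.
#' @export
svc_config <- function(target = 1L, eps = 3, p = 4, steps = 50L,
                       ensemble = TRUE, seed = 1L) {
  if (!p %in% c(1.5, 2, 4)) stop("unsupported norm order p = ", p)
  if (eps < 0) stop("eps must be non-negative")
  structure(list(target = as.integer(target), eps = eps, p = p,
                 steps = as.integer(steps), ensemble = ensemble,
                 seed = as.integer(seed)),
            class = "svc_config")
}

#' Frank-Wolfe linear maximisation over an lp ball
#'
#' Closed-form maximiser of `<s, g>` subject to `||s||_p <= eps`:
#' `s_i = eps * sign(g_i) |g_i|^{1/(p-1)} / || |g|^{1/(p-1)} ||_p`.
#' For `p = 2` this reduces to `eps * g / ||g||_2`. A zero gradient returns
#' the zero vector.
#'
#' @param gradient Numeric vector (or matrix of gradient rows).
#' @param eps Ball radius.
#' @param p Norm order (> 1).
#' @return Step direction(s) of the same shape as `gradient`.
#' @export
fw_linear_oracle <- function(gradient, eps, p) {
  if (p <= 1) stop("p must exceed 1")
  vec <- !is.matrix(gradient)
  G <- if (vec) matrix(gradient, 1L) else gradient
  A <- abs(G)^(1 / (p - 1)) * sign(G)
  nrm <- lp_norm_rows(A, p)
  zero <- nrm == 0
  nrm[zero] <- 1
  S <- eps * A / nrm
  S[zero, ] <- 0
  if (vec) S[1L, ] else S
}

#' Generate sparse visual counterfactuals by Frank-Wolfe
#'
#' Maximises the target-class log-probability (of the plain + robust
#' ensemble, or the robust classifier alone) over the `lp` ball of radius
#' `eps` around the original image; iterates are clipped to the `[0,1]` box,
#' which cannot leave the ball because the original lies in the box.
#'
#' @param x0 Original image(s): array in `[0,1]`, `labeled_image`, or matrix
#'   of flattened rows.
#' @param config An [svc_config()].
#' @param classifiers List with `plain` and `robust` classifiers.
#' @return A `counterfactual_result` (confidence and flip judged by the
#'   plain classifier, as for diffusion counterfactuals).
#' @export
generate_svc <- function(x0, config, classifiers) {
  stopifnot(inherits(config, "svc_config"))
  if (inherits(x0, "labeled_image")) x0 <- x0$pixels
  d <- classifiers$plain$d
  X0 <- if (is.matrix(x0) && ncol(x0) == d) x0 else matrix(as.vector(x0), 1L)
  if (ncol(X0) != d) stop("image shape incompatible with the classifier")
  k <- config$target
  members <- if (config$ensemble) list(classifiers$plain, classifiers$robust)
             else list(classifiers$robust)
  x <- X0
  trace <- matrix(NA_real_, nrow(X0), config$steps)
  if (config$eps > 0) {
    for (it in seq_len(config$steps)) {
      G <- 0
      for (m in members) G <- G + clf_input_grad_logp(m, x, k)
      s_point <- X0 + fw_linear_oracle(G, config$eps, config$p)
      gamma <- 2 / (it + 2)
      x <- x + gamma * (s_point - x)
      x <- clip_range(x, 0, 1)
      trace[, it] <- predict(classifiers$plain, x)[, k]
    }
  }
  conf <- predict(classifiers$plain, x)[, k]
  cls <- max.col(predict(classifiers$plain, x), ties.method = "first")
  structure(list(image = x, target = k, target_confidence = conf,
                 l2_distance = sqrt(rowSums((x - X0)^2)),
                 lp_distance = lp_norm_rows(x - X0, config$p),
                 flipped = cls == k, trace = trace, config = config),
            class = "counterfactual_result")
}
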