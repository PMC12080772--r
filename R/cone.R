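# Euclidean projection onto the convex cone of directions within a fixed
# angle of a reference gradient. Combining the perceptually aligned
# gradients of an adversarially robust classifier with the (more accurate)
# plain classifier's direction is what makes guided counterfactuals both
# class-faithful and realistic.

#' Project a gradient onto a cone around a reference gradient
#'
#' Euclidean projection of `g_robust` onto the convex cone
#' `{v : angle(v, g_plain) <= alpha}`. If `g_robust` already lies inside
#' the cone it is returned unchanged (ties at exactly `alpha` keep
#' `g_robust`); if it lies in the polar cone (angle >= alpha + 90 degrees)
#' the projection is the zero vector; otherwise the projection lies on the
#' cone boundary inside `span{g_plain, g_robust}`.
#'
#' @param g_robust Numeric vector: the robust classifier's gradient.
#' @param g_plain Numeric vector: the plain classifier's gradient (cone
#'   axis). If zero, the constraint set is ill-defined: `g_robust` is
#'   returned unprojected with a warning.
#' @param alpha Cone half-angle in degrees, `0 < alpha < 90`.
#' @return The projected gradient, same length as `g_robust`.
#' @export
cone_project <- function(g_robust, g_plain, alpha = 30) {
  if (!(alpha > 0 && alpha < 90)) stop("alpha must lie in (0, 90) degrees")
  np <- sqrt(sum(g_plain^2))
  if (np == 0) {
    warning("g_plain is zero; cone is ill-defined, returning g_robust unprojected")
    return(g_robust)
  }
  nr <- sqrt(sum(g_robust^2))
  if (nr == 0) return(g_robust)
  a <- alpha * pi / 180
  u <- g_plain / np
  comp <- sum(g_robust * u)
  cosang <- comp / nr
  if (cosang >= cos(a)) return(g_robust)          # already inside the cone
  w <- g_robust - comp * u                        # orthogonal component
  nw <- sqrt(sum(w^2))
  if (cosang <= cos(a + pi / 2)) return(0 * g_robust)  # polar cone: project to 0
  what <- if (nw > 0) w / nw else u
  boundary <- cos(a) * u + sin(a) * what
  sum(g_robust * boundary) * boundary
}

# Row-wise cone projection for matrices of gradients.
cone_project_rows <- function(G_robust, G_plain, alpha) {
  out <- G_robust
  for (i in seq_len(nrow(G_robust))) {
    out[i, ] <- cone_project(G_robust[i, ], G_plain[i, ], alpha)
  }
  out
}
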