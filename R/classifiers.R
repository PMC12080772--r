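# Plain and adversarially robust K-class classifiers on flattened phantom
# images, with the targeted/untargeted projected-gradient attacks used both
# by TRADES training and by the sparse-counterfactual baseline.

#' Attack configuration
#'
#' @param eps Perturbation budget (radius of the `lp` ball), `> 0`; `eps = 0`
#'   is allowed and returns the input unchanged.
#' @param p Norm order; one of 1.5, 2, 4, or `Inf`.
#' @param steps Number of gradient steps (>= 1).
#' @param step_size Step length; default `2.5 * eps / steps`.
#' @param targeted If `TRUE` the attack minimises the loss towards `target`.
#' @param target Target class index (1-based) for targeted attacks.
#' @return An `attack_config` list.
#' @export
attack_config <- function(eps, p = 2, steps = 10L, step_size = NULL,
                          targeted = FALSE, target = NULL) {
  if (!p %in% c(1.5, 2, 4, Inf)) stop("unsupported norm order p = ", p)
  if (eps < 0) stop("eps must be non-negative")
  if (steps < 1) stop("steps must be >= 1")
  if (targeted && is.null(target)) stop("targeted attack needs a target class")
  if (is.null(step_size)) step_size <- 2.5 * eps / steps
  structure(list(eps = eps, p = p, steps = as.integer(steps),
                 step_size = step_size, targeted = targeted, target = target),
            class = "attack_config")
}

lp_norm_rows <- function(M, p) {
  if (is.infinite(p)) apply(abs(M), 1L, max) else rowSums(abs(M)^p)^(1 / p)
}

# Unit-lp-ball steepest-ascent direction for gradient rows (the maximiser of
# <s, g> over ||s||_p <= 1); rows with zero gradient stay zero.
lp_steepest_rows <- function(G, p) {
  if (is.infinite(p)) return(sign(G))
  A <- abs(G)^(1 / (p - 1)) * sign(G)
  nrm <- lp_norm_rows(A, p)
  nrm[nrm == 0] <- 1
  A / nrm
}

# Project perturbation rows into the lp ball of radius eps: exact for p = 2
# and p = Inf, radial rescaling for p = 1.5 and 4 (keeps feasibility).
lp_project_rows <- function(D, eps, p) {
  if (is.infinite(p)) return(clip_range(D, -eps, eps))
  nrm <- lp_norm_rows(D, p)
  f <- pmin(1, eps / pmax(nrm, .Machine$double.eps))
  D * f
}

clf_logits <- function(clf, X) net_forward(clf$net, X)$out

#' Class probabilities, logits or labels from a classifier
#'
#' @param object A `retina_classifier`.
#' @param X Matrix of flattened images (one per row) in `[0,1]`, or a single
#'   image array.
#' @param type `"prob"`, `"class"`, or `"logit"`.
#' @param ... Unused.
#' @return Matrix of probabilities/logits or an integer vector of classes.
#' @export
predict.retina_classifier <- function(object, X, type = c("prob", "class", "logit"),
                                      ...) {
  type <- match.arg(type)
  if (!is.matrix(X)) X <- matrix(as.vector(X), 1L)
  L <- clf_logits(object, X)
  switch(type,
         logit = L,
         prob = softmax_rows(L),
         class = max.col(L, ties.method = "first"))
}

# Gradient of log p(k | x) with respect to the input rows.
clf_input_grad_logp <- function(clf, X, k) {
  fw <- net_forward(clf$net, X)
  P <- softmax_rows(fw$out)
  dL <- -P
  dL[, k] <- dL[, k] + 1
  net_backward(clf$net, fw, dL)$dX
}

# Cross-entropy loss and logit gradient for integer labels y (1-based).
ce_loss_grad <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, grad = G / n)
}

new_classifier <- function(net, K, classes, d, mode, eps = NA, p = NA,
                           history = NULL) {
  structure(list(net = net, K = K, classes = classes, d = d, mode = mode,
                 eps = eps, p = p, history = history),
            class = "retina_classifier")
}

#' @export
print.retina_classifier <- function(x, ...) {
  cat(sprintf("<retina_classifier> %s, K=%d (%s), d=%d%s\n", x$mode, x$K,
              paste(x$classes, collapse = "/"), x$d,
              if (x$mode == "robust")
                sprintf(", TRADES eps=%.3g l%g", x$eps, x$p) else ""))
  invisible(x)
}

#' Train a plain classifier
#'
#' Cross-entropy minimisation under a cosine learning-rate schedule, with
#' Adam by default (SGD with momentum 0.9 available via `optimizer`); the
#' checkpoint with the best validation balanced accuracy is kept when
#' validation data are supplied.
#'
#' @param X,y Training images (rows, `[0,1]`) and 1-based integer labels.
#' @param epochs,lr,batch_size Optimiser settings.
#' @param img_dim Image dimensions `c(H, W)` or `c(H, W, C)`; required for
#'   the convolutional architecture.
#' @param arch `"cnn"` (small convolutional network, the default when
#'   `img_dim` is given) or `"mlp"` (dense network on the flat pixels).
#' @param hidden Hidden-layer widths (MLP architecture only).
#' @param X_val,y_val Optional validation split.
#' @param classes Optional class names.
#' @param seed Integer seed.
#' @return A `retina_classifier`.
#' @export
train_plain <- function(X, y, epochs = 30L, lr = NULL, batch_size = 32L,
                        img_dim = NULL, arch = if (is.null(img_dim)) "mlp" else "cnn",
                        optimizer = c("adam", "sgd"),
                        hidden = c(128L, 64L), X_val = NULL, y_val = NULL,
                        classes = NULL, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (is.null(lr)) lr <- if (optimizer == "adam") 3e-3 else 0.01
  K <- length(unique(y))
  if (K < 2) stop("training data must contain at least two classes")
  K <- max(y)
  if (is.null(classes)) classes <- paste0("class", seq_len(K))
  net <- if (arch == "cnn") cnn_init(img_dim, K = K, seed = seed)
         else nn_init(c(ncol(X), hidden, K), seed = seed)
  opt <- if (optimizer == "adam") adam_init(net) else sgd_init(net)
  best <- list(net = net, score = -Inf)
  hist <- numeric(0)
  withr::with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      lr_ep <- lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
      ord <- sample.int(nrow(X))
      for (start in seq(1L, nrow(X), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, nrow(X))]
        fw <- net_forward(net, X[idx, , drop = FALSE])
        cg <- ce_loss_grad(fw$out, y[idx])
        gr <- net_backward(net, fw, cg$grad)
        st <- if (optimizer == "adam") adam_step(net, gr, opt, lr_ep)
              else sgd_step(net, gr, opt, lr_ep)
        net <- st$net; opt <- st$state
      }
      if (!is.null(X_val)) {
        clf_tmp <- new_classifier(net, K, classes, ncol(X), "plain")
        m <- evaluate_classifier(clf_tmp, X_val, y_val)
        hist <- c(hist, m$balanced_accuracy)
        if (m$balanced_accuracy >= best$score) {
          best <- list(net = net, score = m$balanced_accuracy)
        }
      }
    }
  })
  if (is.null(X_val)) best$net <- net
  new_classifier(best$net, K, classes, ncol(X), "plain", history = hist)
}

#' Projected gradient attack in an lp ball
#'
#' Iterative steepest-ascent steps on the cross-entropy loss (descent
#' towards `target` when `targeted`), projected after every step onto the
#' `lp` ball of radius `eps` around `x0` and clipped to the `[0,1]` box.
#' Projection is exact for `p = 2` and `p = Inf` and radial for
#' `p = 1.5, 4`.
#'
#' @param classifier A `retina_classifier`.
#' @param x0 Matrix of starting images (rows) in `[0,1]`.
#' @param config An [attack_config()].
#' @param y True labels (needed for untargeted attacks).
#' @return Matrix of adversarial images, feasible for ball and box.
#' @export
pgd_attack <- function(classifier, x0, config, y = NULL) {
  stopifnot(inherits(config, "attack_config"))
  if (!is.matrix(x0)) x0 <- matrix(as.vector(x0), 1L)
  if (config$eps == 0) return(x0)
  if (!config$targeted && is.null(y)) stop("untargeted attack needs labels y")
  x <- x0
  for (s in seq_len(config$steps)) {
    fw <- net_forward(classifier$net, x)
    if (config$targeted) {
      cg <- ce_loss_grad(fw$out, rep_len(config$target, nrow(x)))
      G <- -net_backward(classifier$net, fw, cg$grad)$dX   # descend CE(target)
    } else {
      cg <- ce_loss_grad(fw$out, y)
      G <- net_backward(classifier$net, fw, cg$grad)$dX    # ascend CE(true)
    }
    x <- x + config$step_size * lp_steepest_rows(G, config$p)
    x <- x0 + lp_project_rows(x - x0, config$eps, config$p)
    x <- clip_range(x, 0, 1)
  }
  x
}

# KL(p || q) rows from two logit matrices.
kl_rows <- function(logits_p, logits_q) {
  P <- softmax_rows(logits_p); Q <- softmax_rows(logits_q)
  rowSums(P * (log(pmax(P, 1e-12)) - log(pmax(Q, 1e-12))))
}

# Inner maximisation of the TRADES KL term: PGD on x_adv starting from a
# small random perturbation of x.
trades_inner <- function(net, x, eps, p, steps, step_size) {
  fw0 <- net_forward(net, x)
  P <- softmax_rows(fw0$out)
  xa <- clip_range(x + matrix(stats::rnorm(length(x), 0, 1e-3), nrow(x)), 0, 1)
  for (s in seq_len(steps)) {
    fw <- net_forward(net, xa)
    Q <- softmax_rows(fw$out)
    G <- net_backward(net, fw, Q - P)$dX  # d KL(P||Q) / d logits_q = Q - P
    xa <- xa + step_size * lp_steepest_rows(G, p)
    xa <- x + lp_project_rows(xa - x, eps, p)
    xa <- clip_range(xa, 0, 1)
  }
  xa
}

#' TRADES loss value
#'
#' `CE(f(x), y) + beta_trades * mean KL(p(.|x) || p(.|x_adv))` where
#' `x_adv` maximises the KL term inside the `lp` ball of radius `eps`
#' (inner PGD). With `eps = 0` this reduces to plain cross-entropy.
#'
#' @param classifier A `retina_classifier`.
#' @param X,y Batch (rows in `[0,1]`) and 1-based labels.
#' @param eps,p Ball radius and norm order of the inner attack.
#' @param beta_trades Trade-off weight of the KL term.
#' @param attack_steps Inner PGD steps.
#' @return Scalar loss value.
#' @export
trades_loss <- function(classifier, X, y, eps, p = 2, beta_trades = 6,
                        attack_steps = 5L) {
  if (!is.matrix(X)) X <- matrix(as.vector(X), 1L)
  logits <- clf_logits(classifier, X)
  ce <- ce_loss_grad(logits, y)$loss
  if (eps == 0) return(ce)
  xa <- trades_inner(classifier$net, X, eps, p, attack_steps, 2.5 * eps / attack_steps)
  ce + beta_trades * mean(kl_rows(logits, clf_logits(classifier, xa)))
}

#' Train an adversarially robust classifier with TRADES
#'
#' Each minibatch step perturbs the batch by inner-maximisation PGD on the
#' KL term and descends the TRADES objective
#' `CE + beta_trades * KL(p(.|x) || p(.|x_adv))` under a cosine
#' learning-rate schedule (Adam by default, SGD via `optimizer`).
#'
#' @inheritParams train_plain
#' @param eps,p Training-time attack radius and norm order.
#' @param beta_trades KL trade-off weight.
#' @param attack_steps Inner PGD steps per minibatch.
#' @param init Optional trained `retina_classifier` of the same architecture
#'   whose weights initialise the robust model (the desk-scale analogue of
#'   starting from a pre-trained backbone); with a random start the KL term
#'   can trap the model in a constant-prediction minimum before it has
#'   learned any class-discriminating features.
#' @return A `retina_classifier` with `mode = "robust"`.
#' @export
train_robust <- function(X, y, eps = 0.25, p = 2, beta_trades = 6,
                         epochs = 30L, lr = NULL, batch_size = 32L,
                         img_dim = NULL, arch = if (is.null(img_dim)) "mlp" else "cnn",
                         optimizer = c("adam", "sgd"),
                         hidden = c(128L, 64L), attack_steps = 5L,
                         init = NULL, classes = NULL, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (is.null(lr)) lr <- if (optimizer == "adam") 3e-3 else 0.01
  K <- length(unique(y))
  if (K < 2) stop("training data must contain at least two classes")
  K <- max(y)
  if (is.null(classes)) classes <- paste0("class", seq_len(K))
  net <- if (!is.null(init)) init$net
         else if (arch == "cnn") cnn_init(img_dim, K = K, seed = seed)
         else nn_init(c(ncol(X), hidden, K), seed = seed)
  opt <- if (optimizer == "adam") adam_init(net) else sgd_init(net)
  withr::with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      lr_ep <- lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
      ord <- sample.int(nrow(X))
      for (start in seq(1L, nrow(X), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, nrow(X))]
        xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        xa <- trades_inner(net, xb, eps, p, attack_steps, 2.5 * eps / attack_steps)
        # clean branch: CE + beta * d KL / d logits_clean
        fwc <- net_forward(net, xb)
        fwa <- net_forward(net, xa)
        P <- softmax_rows(fwc$out); Q <- softmax_rows(fwa$out)
        n <- length(yb)
        dCE <- ce_loss_grad(fwc$out, yb)$grad
        lr_ratio <- log(pmax(P, 1e-12)) - log(pmax(Q, 1e-12))
        kl <- rowSums(P * lr_ratio)
        dKL_p <- P * (lr_ratio - kl) / n        # d KL / d logits_clean
        dKL_q <- (Q - P) / n                    # d KL / d logits_adv
        g1 <- net_backward(net, fwc, dCE + beta_trades * dKL_p)
        g2 <- net_backward(net, fwa, beta_trades * dKL_q)
        gr <- list(W = Map(`+`, g1$W, g2$W), b = Map(`+`, g1$b, g2$b))
        st <- if (optimizer == "adam") adam_step(net, gr, opt, lr_ep)
              else sgd_step(net, gr, opt, lr_ep)
        net <- st$net; opt <- st$state
      }
    }
  })
  new_classifier(net, K, classes, ncol(X), "robust", eps = eps, p = p)
}

#' Evaluate a classifier
#'
#' Standard accuracy, balanced accuracy (mean per-class recall) and the
#' quadratically weighted Cohen's kappa with weights
#' `(i - j)^2 / (K - 1)^2` over the full confusion matrix.
#'
#' @param classifier A `retina_classifier`.
#' @param X,y Evaluation images (rows) and 1-based labels.
#' @return List with `accuracy`, `balanced_accuracy`, `quadratic_kappa`,
#'   and the confusion matrix (`rows = truth`).
#' @export
evaluate_classifier <- function(classifier, X, y) {
  pred <- predict(classifier, X, type = "class")
  K <- classifier$K
  conf <- matrix(0L, K, K)
  for (i in seq_along(y)) conf[y[i], pred[i]] <- conf[y[i], pred[i]] + 1L
  acc <- sum(diag(conf)) / sum(conf)
  recalls <- diag(conf) / pmax(rowSums(conf), 1L)
  bal <- mean(recalls[rowSums(conf) > 0])
  list(accuracy = acc, balanced_accuracy = bal,
       quadratic_kappa = quadratic_kappa(conf), confusion = conf)
}

#' Quadratically weighted Cohen's kappa from a confusion matrix
#'
#' `1 - sum(w * O) / sum(w * E)` with weights `w_ij = (i-j)^2 / (K-1)^2`
#' and `E` the outer product of the margins scaled to the table total.
#'
#' @param conf K x K confusion matrix (rows = truth, columns = prediction).
#' @return Scalar kappa in `[-1, 1]`.
#' @export
quadratic_kappa <- function(conf) {
  K <- nrow(conf)
  if (K == 1L) return(NA_real_)
  W <- outer(seq_len(K), seq_len(K), function(i, j) (i - j)^2 / (K - 1)^2)
  n <- sum(conf)
  E <- outer(rowSums(conf), colSums(conf)) / n
  1 - sum(W * conf) / sum(W * E)
}

#' Group fundus grades into the referable-disease binary task
#'
#' Disease onset is taken from the moderate grade: healthy and mild map to
#' class 1 ("normal"), moderate and worse to class 2 ("referable").
#'
#' @param grades Character vector of fundus grade names, or integer labels
#'   into [fundus_grades()].
#' @return Integer vector of binary labels (1 = normal, 2 = referable).
#' @export
referable_labels <- function(grades) {
  if (is.numeric(grades)) grades <- fundus_grades()[grades]
  ifelse(grades %in% c("healthy", "mild"), 1L, 2L)
}
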