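# Toy-scale classifier, attack and metric tests (dense architecture; the
# convolutional pipeline is exercised by the guided-sampling tests).

make_linear_clf <- function(W, b) {
  # hand-built linear-logit classifier: logits = x %*% W + b
  net <- retinocf:::nn_init(c(nrow(W), ncol(W)), seed = 1)
  net$W[[1]] <- W
  net$b[[1]] <- b
  retinocf:::new_classifier(net, ncol(W), paste0("c", seq_len(ncol(W))),
                            nrow(W), "plain")
}

test_that("probabilities normalise and training separates a toy problem", {
  withr::with_seed(1, {
    X <- matrix(stats::rnorm(300 * 2), 300)
    y <- ifelse(X[, 1] + X[, 2] > 0, 1L, 2L)
  })
  clf <- train_plain(X, y, epochs = 40, seed = 2)
  expect_equal(mean(predict(clf, X, type = "class") == y), 1)
  P <- predict(clf, X, type = "prob")
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  # seeded reruns are identical
  clf2 <- train_plain(X, y, epochs = 40, seed = 2)
  expect_identical(clf$net$W, clf2$net$W)
  expect_error(train_plain(X, rep(1L, nrow(X)), epochs = 1), "two classes")
})

test_that("input gradient of log p(k|x) matches the softmax closed form", {
  W <- matrix(c(0.5, -1, 2, 0.3, 1, -0.7), 2, 3)
  b <- c(0.1, -0.2, 0)
  clf <- make_linear_clf(W, b)
  x <- matrix(c(0.3, 0.8), 1)
  p <- drop(predict(clf, x))
  for (k in 1:3) {
    # closed form: W[, k] - W %*% p
    expect_equal(drop(retinocf:::clf_input_grad_logp(clf, x, k)),
                 W[, k] - drop(W %*% p), tolerance = 1e-10)
  }
})

test_that("PGD attacks respect ball and box constraints for every norm", {
  withr::with_seed(3, {
    X <- matrix(stats::runif(12 * 8), 12)
    y <- rep(1:2, 6)
    Wm <- matrix(stats::rnorm(16), 8, 2)
  })
  clf <- make_linear_clf(Wm, c(0, 0))
  for (p in c(1.5, 2, 4, Inf)) {
    cfg <- attack_config(eps = 0.4, p = p, steps = 8)
    xa <- pgd_attack(clf, X, cfg, y = y)
    expect_true(all(retinocf:::lp_norm_rows(xa - X, p) <= 0.4 * (1 + 1e-6)))
    expect_true(all(xa >= 0 & xa <= 1))
  }
  expect_identical(pgd_attack(clf, X, attack_config(eps = 0, p = 2), y = y), X)
  expect_error(attack_config(eps = 0.1, p = 3), "unsupported norm")
})

test_that("untargeted l2 PGD flips exactly the points within eps of the margin", {
  # linear 2-class toy with known weights: decision line x1 + x2 = 1
  w <- c(1, 1); b0 <- -1
  clf <- make_linear_clf(cbind(0, w), c(0, b0))
  withr::with_seed(4, {
    X <- matrix(stats::runif(200 * 2, 0.3, 0.7), 200)
  })
  margin <- (X %*% w + b0) / sqrt(sum(w^2))   # signed distance to the line
  y <- ifelse(margin > 0, 2L, 1L)
  eps <- 0.15
  clear <- abs(margin) > 0.01 & abs(abs(margin) - eps) > 0.01
  cfg <- attack_config(eps = eps, p = 2, steps = 20)
  xa <- pgd_attack(clf, X, cfg, y = y)
  flipped <- predict(clf, xa, type = "class") != y
  expect_identical(flipped[clear], (abs(margin) < eps)[clear])
})

test_that("TRADES loss matches a pencil-and-paper single-pixel oracle", {
  # one pixel, two classes, hand-set weights
  W <- matrix(c(2, -1), 1, 2); b <- c(0.2, -0.1)
  clf <- make_linear_clf(W, b)
  x <- matrix(0.6, 1); y <- 1L
  eps <- 0.2; beta <- 6
  got <- withr::with_seed(11, trades_loss(clf, x, y, eps = eps, p = 2,
                                          beta_trades = beta, attack_steps = 1))
  # independent scalar computation of the same quantity
  soft <- function(l) exp(l - max(l)) / sum(exp(l - max(l)))
  P <- soft(drop(x) * W[1, ] + b)
  ce <- -log(P[y])
  xa1 <- withr::with_seed(11, min(1, max(0, drop(x) + stats::rnorm(1, 0, 1e-3))))
  Q1 <- soft(xa1 * W[1, ] + b)
  g <- sum((Q1 - P) * W[1, ])                 # d KL / d x_adv
  xa <- xa1 + 2.5 * eps * sign(g)             # one step of size 2.5 eps
  xa <- drop(x) + max(-eps, min(eps, xa - drop(x)))
  xa <- min(1, max(0, xa))
  Q <- soft(xa * W[1, ] + b)
  expect_equal(got, ce + beta * sum(P * (log(P) - log(Q))), tolerance = 1e-10)
  # eps = 0 reduces to the cross-entropy; KL term is never negative
  expect_equal(trades_loss(clf, x, y, eps = 0), ce, tolerance = 1e-10)
  expect_gte(got - ce, 0)
})

test_that("evaluation metrics match their definitions", {
  clf <- make_linear_clf(diag(2), c(0, 0))
  # perfect predictions
  X <- rbind(c(1, 0), c(0, 1), c(1, 0))
  y <- c(1L, 2L, 1L)
  m <- evaluate_classifier(clf, X, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$quadratic_kappa, 1)
  # degenerate always-class-1 confusion: balanced accuracy 0.5
  expect_equal(retinocf:::quadratic_kappa(matrix(c(5, 5, 0, 0), 2)), 0)
  conf <- matrix(c(5, 5, 0, 0), 2)
  rec <- diag(conf) / rowSums(conf)
  expect_equal(mean(rec), 0.5)
  # 3-class table against a brute-force evaluation of the weighted formula
  conf3 <- rbind(c(2, 1, 0), c(0, 2, 1), c(1, 0, 2))
  num <- den <- 0
  n <- sum(conf3)
  for (i in 1:3) for (j in 1:3) {
    w <- (i - j)^2 / 4
    num <- num + w * conf3[i, j]
    den <- den + w * sum(conf3[i, ]) * sum(conf3[, j]) / n
  }
  expect_equal(quadratic_kappa(conf3), 1 - num / den, tolerance = 1e-12)
})

test_that("referable grouping maps grades to the binary task", {
  expect_equal(referable_labels(c("healthy", "mild", "moderate", "severe",
                                  "proliferative")),
               c(1L, 1L, 2L, 2L, 2L))
  expect_equal(referable_labels(1:5), c(1L, 1L, 2L, 2L, 2L))
})
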