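test_that("linear schedule matches hand-computed products and invariants", {
  s <- make_linear_schedule(2, 0.1, 0.2)
  expect_equal(s$alpha_bar, c(0.9, 0.72))
  s1000 <- make_linear_schedule(1000, 1e-4, 0.02)
  # independent oracle: direct cumulative product
  expect_equal(s1000$alpha_bar, cumprod(1 - seq(1e-4, 0.02, length.out = 1000)))
  expect_lt(s1000$alpha_bar[1000], 1e-4)
  expect_true(all(diff(s1000$alpha_bar) < 0))
  expect_error(make_linear_schedule(100, 0.2, 0.1), "beta_min")
  # shipped default schedules reach the same terminal signal level
  for (T in c(100L, 250L, 1000L)) {
    expect_lt(make_linear_schedule(T)$alpha_bar[T], 0.01)
  }
})

test_that("q_sample realises the closed-form forward marginal", {
  sch <- make_linear_schedule(50)
  x0 <- c(0.4, -0.2, 0.9)
  expect_equal(q_sample(x0, 0, stats::rnorm(3), sch), x0)        # t = 0
  nz <- c(1.5, -0.3, 0.2)
  expect_equal(q_sample(0 * x0, 10, nz, sch),
               sqrt(1 - sch$alpha_bar[10]) * nz)                 # x0 = 0
  expect_error(q_sample(x0, 51, NULL, sch), "out of range")
  # Monte-Carlo moments at fixed t within 3 standard errors (n = 10,000)
  n <- 10000; t <- 25
  withr::with_seed(1, draws <- q_sample(matrix(0.5, n, 1), t, schedule = sch))
  ab <- sch$alpha_bar[t]
  se_mean <- sqrt(1 - ab) / sqrt(n)
  expect_lt(abs(mean(draws) - sqrt(ab) * 0.5), 3 * se_mean)
  se_var <- (1 - ab) * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(as.vector(draws)) - (1 - ab)), 3 * se_var)
})

test_that("predict_x0 inverts q_sample and round-trips", {
  sch <- make_linear_schedule(100)
  withr::with_seed(2, {
    x0 <- stats::runif(16, -1, 1)
    nz <- stats::rnorm(16)
  })
  xt <- q_sample(x0, 40, nz, sch)
  expect_equal(predict_x0(xt, 40, nz, sch), x0, tolerance = 1e-10)
  expect_equal(predict_x0(xt, 40, 0 * nz, sch), xt / sqrt(sch$alpha_bar[40]))
  # round trip: q_sample(predict_x0(x_t)) with the same noise returns x_t
  x0h <- predict_x0(xt, 40, nz, sch)
  expect_equal(q_sample(x0h, 40, nz, sch), xt, tolerance = 1e-10)
  expect_error(predict_x0(xt, 0, nz, sch), "t must be")
})

test_that("reverse_step matches an independent textbook DDPM step", {
  sch <- make_linear_schedule(10, 0.02, 0.2)
  # independent implementation, written from the sampling equations
  oracle_step <- function(x, t, eps, noise) {
    ab <- sch$alpha_bar[t]
    ab_prev <- if (t > 1) sch$alpha_bar[t - 1] else 1
    mu <- (x - sch$beta[t] * eps / sqrt(1 - ab)) / sqrt(1 - sch$beta[t])
    sig2 <- (1 - ab_prev) / (1 - ab) * sch$beta[t]
    mu + sqrt(sig2) * noise
  }
  withr::with_seed(3, {
    x <- stats::rnorm(4)   # a 4-pixel image
    eps <- stats::rnorm(4)
    nz <- stats::rnorm(4)
  })
  for (t in c(10, 5, 2)) {
    expect_equal(reverse_step(x, t, eps, sch, noise = nz),
                 oracle_step(x, t, eps, nz), tolerance = 1e-6)
  }
  # t = 1 adds no noise: result is deterministic
  expect_equal(reverse_step(x, 1, eps, sch, noise = NULL),
               reverse_step(x, 1, eps, sch, noise = nz))
  # zero shift equals the unconditional step; a shift adds exactly
  shift <- c(0.1, -0.2, 0, 0.05)
  expect_equal(reverse_step(x, 5, eps, sch, mean_shift = shift, noise = nz),
               reverse_step(x, 5, eps, sch, noise = nz) + shift)
  expect_error(reverse_step(x, 0, eps, sch), "t must be")
})

test_that("single-step chain with a perfect denoiser recovers x0 exactly", {
  # T = 1, one-pixel image: x1 = sqrt(a) x0 + sqrt(1-a) e; the reverse mean
  # with the true eps equals x0 (hand algebra), and t = 1 adds no noise.
  sch <- make_linear_schedule(2, 0.05, 0.1)
  x0 <- 0.3; e <- 0.7
  x1 <- q_sample(x0, 1, e, sch)
  expect_equal(reverse_step(x1, 1, e, sch), x0, tolerance = 1e-12)
})

test_that("denoiser training reduces the loss and is reproducible", {
  withr::with_seed(10, {
    X <- matrix(stats::runif(24 * 64), 24)   # 24 tiny 8x8 images
  })
  sch <- make_linear_schedule(50)
  d1 <- train_denoiser(X, sch, iterations = 300, batch_size = 8,
                       hidden = c(32L), seed = 4)
  d2 <- train_denoiser(X, sch, iterations = 300, batch_size = 8,
                       hidden = c(32L), seed = 4)
  expect_identical(d1$loss_curve, d2$loss_curve)     # seeded determinism
  n <- length(d1$loss_curve)
  expect_lt(mean(utils::tail(d1$loss_curve, 3)), d1$loss_curve[1])
  expect_error(train_denoiser(matrix(0, 0, 4), sch), "non-empty")
})

test_that("unconditional samples are reproducible, in range, and data-like", {
  withr::with_seed(11, {
    # one-class data: noisy blobs around a fixed template
    template <- as.vector(outer(1:8, 1:8, function(y, x)
      exp(-((y - 4)^2 + (x - 5)^2) / 6)))
    X <- t(replicate(32, pmax(0, pmin(1, template + stats::rnorm(64, 0, 0.05)))))
  })
  sch <- make_linear_schedule(50)
  den <- train_denoiser(X, sch, iterations = 800, batch_size = 8,
                        img_dim = c(8L, 8L), seed = 5)
  s1 <- sample_unconditional(den, n = 6, seed = 9)
  s2 <- sample_unconditional(den, n = 6, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # samples correlate with the data template far better than noise does
  cors <- apply(s1, 1L, function(r) stats::cor(r, template))
  withr::with_seed(12, {
    ncors <- replicate(50, stats::cor(stats::runif(64), template))
  })
  expect_gt(stats::median(cors), max(abs(ncors)))
})
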