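# Cone projection and the guidance building blocks on analytic toys; the
# full guided sampler is exercised end-to-end in the pipeline tests.

test_that("cone projection handles the inside, boundary and polar cases", {
  g_p <- c(1, 0)
  # parallel and inside-cone gradients are returned unchanged
  expect_equal(cone_project(c(2, 0), g_p, 30), c(2, 0))
  inside <- c(cos(0.2), sin(0.2))        # ~11 degrees off axis
  expect_equal(cone_project(inside, g_p, 30), inside)
  # orthogonal gradient at alpha = 45 degrees: the worked 2D case
  expect_equal(cone_project(c(0, 1), g_p, 45), c(0.5, 0.5), tolerance = 1e-12)
  # polar cone: opposite direction projects to zero
  expect_equal(cone_project(c(-1, 1e-3), g_p, 30), c(0, 0), tolerance = 1e-9)
  # degenerate axis falls back with a warning
  expect_warning(out <- cone_project(c(1, 2), c(0, 0), 30), "ill-defined")
  expect_equal(out, c(1, 2))
  expect_error(cone_project(c(1, 0), c(0, 1), 95), "alpha")
})

test_that("projected gradients never exceed the cone angle", {
  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(2:8, 1)
      g_r <- stats::rnorm(n); g_p <- stats::rnorm(n)
      a <- stats::runif(1, 10, 80)
      v <- cone_project(g_r, g_p, a)
      if (sqrt(sum(v^2)) > 1e-10) {
        cosang <- sum(v * g_p) / sqrt(sum(v^2) * sum(g_p^2))
        expect_gte(cosang, cos(a * pi / 180) - 1e-6)
      }
    }
  })
})

test_that("guidance gradient reduces to the analytic form for linear logits", {
  W <- matrix(c(1, -0.5, 0.2, 0.4, 0.3, -0.1, 0.8, -0.6), 4, 2)
  clf <- retinocf:::new_classifier({
    net <- retinocf:::nn_init(c(4, 2), seed = 1)
    net$W[[1]] <- W; net$b[[1]] <- c(0, 0); net
  }, 2, c("a", "b"), 4, "plain")
  sch <- make_linear_schedule(50)
  x0h <- matrix(c(-0.2, 0.4, 0.1, -0.6), 1)   # internal [-1,1] scale
  state <- list(x_t = x0h, t = 20L, x0_hat = x0h)
  cfg <- guidance_config(target = 2, mode = "plain")
  g <- guidance_gradient(list(plain = clf, robust = clf), state, 2, cfg, sch)
  x01 <- (x0h + 1) / 2
  p <- drop(predict(clf, x01))
  chain <- 0.5 / sqrt(sch$alpha_bar[20])
  expect_equal(drop(g), (W[, 2] - drop(W %*% p)) * chain, tolerance = 1e-10)
  # a constant-logit classifier has zero gradient
  clf0 <- retinocf:::new_classifier({
    net <- retinocf:::nn_init(c(4, 2), seed = 1)
    net$W[[1]] <- matrix(0, 4, 2); net$b[[1]] <- c(1, 1); net
  }, 2, c("a", "b"), 4, "plain")
  g0 <- guidance_gradient(list(plain = clf0, robust = clf0), state, 1, cfg, sch)
  expect_equal(drop(g0), rep(0, 4))
  expect_error(guidance_gradient(list(plain = clf, robust = clf), state, 5,
                                 cfg, sch), "out of range")
})

test_that("distance gradient is a unit pull towards the original", {
  x0 <- matrix(c(0.2, -0.1, 0.5), 1)
  expect_equal(distance_gradient(x0, x0, 0.5), 0 * x0)     # at the original
  expect_equal(distance_gradient(x0 + 1, x0, 0), 0 * x0)   # lambda_d = 0
  g1 <- distance_gradient(x0 + 0.3, x0, 0.4)
  g2 <- distance_gradient(x0 + 0.3, x0, 0.8)
  expect_equal(2 * g1, g2)                                  # linear in lambda
  expect_equal(drop(g1), -0.4 * rep(0.3, 3) / sqrt(3 * 0.09), tolerance = 1e-12)
})

test_that("total shift combines unit-normalised terms at the step noise scale", {
  sch <- make_linear_schedule(100)
  cfg <- guidance_config(target = 1, lambda_d = 1, s = 1)
  t <- 60L
  gg <- matrix(c(1, 0, 0, 0), 1)
  gd <- matrix(c(0, 1, 0, 0), 1)     # orthogonal unit gradients
  sh <- total_shift(gg, gd, sch, t, cfg)
  sig <- sqrt(retinocf:::beta_tilde(sch, t))
  expect_equal(sqrt(sum(sh^2)), sqrt(2) * sig, tolerance = 1e-12)
  # magnitudes of the inputs do not matter, only directions
  expect_equal(total_shift(5 * gg, 0.1 * gd, sch, t, cfg), sh)
  expect_equal(total_shift(0 * gg, 0 * gd, sch, t, cfg), 0 * gg)
  # lambda_d = 0 leaves the guidance direction only
  cfg0 <- guidance_config(target = 1, lambda_d = 0, s = 1)
  expect_equal(total_shift(gg, gd, sch, t, cfg0), sig * gg)
  # variance scaling is available behind the config flag
  cfgv <- guidance_config(target = 1, lambda_d = 0, s = 1, scale = "variance")
  expect_equal(total_shift(gg, gd, sch, t, cfgv), sig^2 * gg)
})

test_that("guidance configuration enforces its invariants", {
  expect_error(guidance_config(start_fraction = 0), "start_fraction")
  expect_error(guidance_config(start_fraction = 1.2), "start_fraction")
  expect_error(guidance_config(lambda_d = -0.1), "lambda_d")
  expect_error(guidance_config(alpha = 90), "alpha")
})
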