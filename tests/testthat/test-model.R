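test_that("standardization modes round-trip and behave as documented", {
  Y <- tiny_traces()
  for (mode in c("scale", "global", "pointwise")) {
    std <- standardize_traces(Y, mode = mode)
    back <- invert_standardization(std$stats, std$y_std)
    expect_equal(back, t(Y$traces), tolerance = 1e-12)
  }
  # scale mode: pure rescaling, zero stays zero
  std <- standardize_traces(Y, "scale")
  expect_equal(std$stats$center, 0)
  expect_equal(std$y_std, t(Y$traces) / std$stats$scale)
  # global mode: affine-invariance of the standardized output
  Y2 <- time_trace_set(Y$time, 3 * Y$traces + 5)
  expect_equal(standardize_traces(Y2, "global")$y_std,
               standardize_traces(Y, "global")$y_std, tolerance = 1e-12)
  # pointwise mode: per-time z-scores; duplicate traces degenerate with warning
  stp <- standardize_traces(Y, "pointwise")
  expect_equal(colMeans(stp$y_std), numeric(length(Y$time)), tolerance = 1e-12)
  expect_equal(apply(stp$y_std, 2, sd), rep(1, length(Y$time)),
               tolerance = 1e-12)
  Ydup <- time_trace_set(Y$time, Y$traces[, c(1, 1, 1)])
  expect_warning(standardize_traces(Ydup, "pointwise"), "zero variance")
})

test_that("encoder produces a k = 4 latent Gaussian deterministically", {
  model <- dpinn_model(seq(0, 7, by = 1), seed = 2)
  y <- runif(8)
  e1 <- encode(model, y)
  e2 <- encode(model, y)
  expect_identical(e1, e2)
  expect_equal(length(e1$mu), 4L)
  expect_equal(length(e1$sigma), 4L)
  expect_true(all(e1$sigma > 0))
  expect_error(encode(model, runif(5)), "expected d")
})

test_that("reparameterization is the affine map z = mu + sigma * eps", {
  mu <- c(1, -2, 0.5, 3); sigma <- c(0.1, 1, 2, 0)
  expect_equal(reparameterize(mu, sigma, rep(0, 4)), mu)
  expect_equal(reparameterize(mu, sigma * 0, rnorm(4)), mu)
  set.seed(8)
  zbar <- rowMeans(vapply(1:2000, function(i)
    reparameterize(mu, sigma, rnorm(4)), numeric(4)))
  expect_equal(zbar, mu, tolerance = 4 * max(sigma) / sqrt(2000))
})

test_that("decoder outputs satisfy their constraints for random latents", {
  model <- dpinn_model(seq(0, 7, by = 1), seed = 3)
  set.seed(4)
  Z <- matrix(rnorm(200 * 4, sd = 2), 200, 4)
  dec <- decode(model, Z)
  expect_equal(rowSums(dec$omega), rep(1, 200), tolerance = 1e-6)
  expect_true(all(dec$omega >= 0))
  expect_true(all(dec$s >= model$hyper$s_min & dec$s <= model$hyper$s_max))
  expect_true(all(dec$lambda_b > 0))
  expect_true(all(dec$lambda_d > 0))
  # fixed-lambda_d mode returns the constant exactly
  mf <- dpinn_model(seq(0, 7, by = 1), fixed_lambda_d = 0.37, seed = 3)
  expect_equal(decode(mf, Z)$lambda_d, rep(0.37, 200))
})

test_that("weight transform maps the simplex to the simplex", {
  model <- dpinn_model(seq(0, 7, by = 1), seed = 5)
  w <- rep(1 / 8, 8)
  wp <- transform_weights(model, w)
  expect_equal(length(wp), 8L)
  expect_equal(sum(wp), 1, tolerance = 1e-6)
  expect_identical(wp, transform_weights(model, w))
  expect_error(transform_weights(model, rep(0.2, 5)), "expected M")
})

test_that("reconstruction is a closed-form CDF mixture", {
  centers <- seq(0, 7, by = 1)
  set.seed(6)
  wp <- as.vector(softmax_rows(matrix(rnorm(8), 1)))
  s <- runif(8, 0.5, 2)
  tgrid <- seq(0, 12, by = 0.1)
  y <- reconstruct(wp, s, centers, tgrid)
  expect_equal(y[1], 0)
  expect_true(all(diff(y) >= 0))
  expect_equal(reconstruct(wp, s, centers, 1e5), 1, tolerance = 1e-8)
  # single kernel degenerates to the kernel cdf
  expect_equal(reconstruct(1, 1.2, 2, tgrid),
               kernel_cdf(tgrid, rayleigh_kernel(2, 1.2)))
  # derivative of the reconstruction equals the omega'-weighted density
  m <- kernel_mixture(centers, s, wp)
  num <- diff(reconstruct(wp, s, centers, seq(0, 12, by = 1e-4))) / 1e-4
  ana <- mixture_pdf(seq(0, 12, by = 1e-4)[-1] - 5e-5, m)
  expect_lt(max(abs(num - ana)), 1e-6)
})

test_that("end-to-end forward pass is deterministic and shape-stable", {
  for (d in c(4, 9, 17)) {
    grid <- seq(0, d - 1)
    model <- dpinn_model(grid, seed = d)
    Y <- matrix(runif(3 * d), 3, d)
    run_once <- function() {
      enc <- encode(model, Y)
      z <- reparameterize(enc$mu, enc$sigma, enc$mu * 0)
      dec <- decode(model, z)
      wp <- transform_weights(model, dec$omega)
      reconstruct(wp[1, ], dec$s[1, ], model$hyper$centers, grid)
    }
    r1 <- run_once(); r2 <- run_once()
    expect_identical(r1, r2)
    expect_equal(length(r1), d)
  }
})

test_that("checkpoints round-trip through JSON", {
  Y <- tiny_traces()
  fit <- train_dpinn(Y, config = quick_config(25), fixed_lambda_d = 0.4)
  tmp <- tempfile(fileext = ".json")
  save_checkpoint(fit, tmp)
  back <- load_checkpoint(tmp)
  expect_equal(back$par, fit$par, tolerance = 1e-12)
  expect_equal(back$hyper$fixed_lambda_d, 0.4)
  expect_equal(back$stats$scale, fit$stats$scale)
  # identical posterior inference from the restored model
  p1 <- posterior_sample(fit, n = 20, seed = 3)
  p2 <- posterior_sample(back, n = 20, seed = 3)
  expect_equal(p1$omega, p2$omega, tolerance = 1e-12)
  expect_equal(p1$lambda_b, p2$lambda_b, tolerance = 1e-12)
})
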