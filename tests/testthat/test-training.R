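test_that("data loss is the mean absolute error", {
  expect_equal(data_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(data_loss(c(2, 3), c(1, 2)), 1)              # constant offset
  expect_equal(data_loss(c(1, -3), c(0, 0)), 2)             # (|1| + |-3|) / 2
  expect_error(data_loss(1:3, 1:4), "shape mismatch")
})

test_that("physics loss vanishes on exact solutions", {
  # steady state: y = lb/ld with G = 1 gives zero residual
  expect_equal(physics_residual(0, 1, 3 / 0.5, 3, 0.5), 0)
  # lambda_b = 0 and y = 0
  expect_equal(physics_residual(0, 0.7, 0, 0, 0.9), 0)
  # quadrature oracle: y built from the mean-field equation has residual ~ 0
  set.seed(10)
  for (rep in 1:3) {
    M <- 3
    w <- runif(M); w <- w / sum(w)
    m <- kernel_mixture(sort(runif(M, 0, 4)), runif(M, 0.4, 1.5), w)
    lb <- runif(1, 1, 5); ld <- runif(1, 0.2, 1)
    fine <- seq(0, 15, by = 0.01)
    y <- mean_trace_ode(lb, ld, function(t) mixture_cdf(t, m), fine)
    dy <- c(NA, (y[-(1:2)] - y[1:(length(y) - 2)]) / 0.02, NA)
    mid <- 2:(length(fine) - 1)
    res <- physics_residual(dy[mid], mixture_cdf(fine[mid], m), y[mid], lb, ld)
    expect_lt(mean(abs(res)), 1e-4)
  }
})

test_that("closed-form physics loss agrees with its definition", {
  # physics_loss (kernel closed forms) vs an independent composition from
  # mixture_pdf / mixture_cdf
  set.seed(11)
  M <- 5
  centers <- seq(0, 8, length.out = M)
  w <- runif(M); w <- w / sum(w)
  wp <- runif(M); wp <- wp / sum(wp)
  s <- runif(M, 0.5, 2)
  coll <- seq(0, 10, length.out = 17)
  got <- physics_loss(w, wp, s, 2.5, 0.6, centers, coll)
  m_g <- kernel_mixture(centers, s, w)
  m_y <- kernel_mixture(centers, s, wp)
  want <- mean(abs(mixture_pdf(coll, m_y) -
                   (2.5 * mixture_cdf(coll, m_g) - 0.6 * mixture_cdf(coll, m_y))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("scale targets track the smoothed rise", {
  grid <- seq(0, 20, by = 0.5)
  y <- 40 / (1 + exp(-(grid - 8)))               # logistic rise
  st <- scale_target(y, grid, L = 7, s_min = 0.5, s_max = 2.5)
  expect_true(all(st$beta >= 0 & st$beta <= 1))
  expect_equal(st$beta[which.max(abs(c(diff(y), 0)))], 1, tolerance = 0.05)
  expect_equal(st$target[which.max(st$beta)], 0.5)           # steepest -> s_min
  expect_equal(st$target[which.min(st$beta)], 2.5)           # flattest -> s_max
  # moving average of a constant sequence is the constant; flat trace warns
  expect_warning(st0 <- scale_target(rep(3, 41), grid, 7, 0.5, 2.5), "flat")
  expect_equal(st0$beta, numeric(41))
  expect_equal(st0$target, rep(2.5, 41))
})

test_that("scale regularization measures deviation from targets", {
  tg <- c(1, 2, 1.5)
  expect_equal(scale_regularization(tg, tg), 0)
  expect_equal(scale_regularization(tg + 0.3, tg), 0.3)
  expect_error(scale_regularization(1:2, 1:3), "shape mismatch")
})

test_that("KL regularization: closed form, zero point and MC oracle", {
  expect_equal(kl_regularization(rep(0, 4), rep(1, 4)), 0)
  expect_equal(kl_regularization(c(1, 0, 0, 0), rep(1, 4)), 0.5)
  expect_error(kl_regularization(0, -1), "positive")
  # Monte-Carlo oracle: E_q[log q(z) - log p(z)]
  mu <- c(0.5, -1); sigma <- c(0.7, 1.3)
  set.seed(12)
  z <- cbind(rnorm(2e5, mu[1], sigma[1]), rnorm(2e5, mu[2], sigma[2]))
  lq <- dnorm(z[, 1], mu[1], sigma[1], log = TRUE) +
    dnorm(z[, 2], mu[2], sigma[2], log = TRUE)
  lp <- dnorm(z[, 1], log = TRUE) + dnorm(z[, 2], log = TRUE)
  expect_equal(kl_regularization(mu, sigma), mean(lq - lp),
               tolerance = 4 * sd(lq - lp) / sqrt(2e5))
})

test_that("fused loss kernel matches the exported R operations", {
  Y <- tiny_traces()
  std <- standardize_traces(Y)
  model <- dpinn_model(Y$time, seed = 9)
  h <- model$hyper
  N <- nrow(std$y_std)
  coll <- seq(0, max(Y$time), length.out = 13)
  starget <- matrix(runif(N * h$M, h$s_min, h$s_max), N, h$M)
  eps <- matrix(rnorm(N * h$k), N, h$k)
  lg <- densitypinn:::.loss_and_grad(model, std$y_std, eps, starget, coll,
                                     c(data = 1, physics = 1, scale_reg = 1,
                                       kl_reg = 1))
  fw <- lg$forward
  # data term
  yhat <- t(vapply(seq_len(N), function(i)
    reconstruct(fw$omegap[i, ], fw$s[i, ], h$centers, Y$time),
    numeric(h$d)))
  expect_equal(lg$losses[["data"]], data_loss(yhat, std$y_std),
               tolerance = 1e-12)
  # physics term
  expect_equal(lg$losses[["physics"]],
               physics_loss(fw$omega, fw$omegap, fw$s, fw$lb, fw$ld,
                            h$centers, coll), tolerance = 1e-12)
  # scale and KL terms
  expect_equal(lg$losses[["scale_reg"]], scale_regularization(fw$s, starget),
               tolerance = 1e-12)
  expect_equal(lg$losses[["kl_reg"]], kl_regularization(fw$mu, fw$sigma),
               tolerance = 1e-12)
})

test_that("training is reproducible and the history is additive", {
  Y <- tiny_traces(n = 6)
  f1 <- train_dpinn(Y, config = quick_config(30), fixed_lambda_d = 0.5)
  f2 <- train_dpinn(Y, config = quick_config(30), fixed_lambda_d = 0.5)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$history$total,
               with(f1$history, data + physics + scale_reg + kl_reg),
               tolerance = 1e-12)
  expect_true(all(is.finite(f1$history$total)))
  # the best-checkpoint total is no worse than the first epoch
  expect_lte(min(f1$history$total), f1$history$total[1])
})

test_that("training beats the best constant predictor on preset data", {
  dat <- small_dataset(n = 8, seed = 3)
  fit <- train_dpinn(dat, config = quick_config(400), fixed_lambda_d = 0.5)
  std <- standardize_traces(dat)
  # best constant-in-time predictor per trace set under L1
  const_loss <- mean(abs(sweep(std$y_std, 1, apply(std$y_std, 1, median))))
  expect_lt(tail(fit$history$data, 1), const_loss)
})

test_that("free-mode training runs the decay profile and selects a rate", {
  dat <- small_dataset(n = 6, seed = 5)
  fit <- train_dpinn(dat, config = quick_config(800))
  expect_true(fit$trained)
  expect_gt(fit$lambda_d_selected, 0)
  expect_true(is.data.frame(fit$lambda_d_profile$first))
  post <- posterior_sample(fit, n = 10, seed = 1)
  expect_equal(unique(post$lambda_d), fit$lambda_d_selected)
})
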