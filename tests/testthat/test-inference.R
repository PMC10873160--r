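fit_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- train_dpinn(small_dataset(n = 8, seed = 2),
                            config = quick_config(120),
                            fixed_lambda_d = 0.5)
    cache
  }
})

test_that("posterior sampling is seeded and produces valid mixtures", {
  fit <- fit_cache()
  expect_error(posterior_sample(dpinn_model(seq(0, 7), seed = 1)),
               "untrained")
  p1 <- posterior_sample(fit, n = 50, seed = 4)
  p2 <- posterior_sample(fit, n = 50, seed = 4)
  expect_identical(p1$omega, p2$omega)
  expect_equal(nrow(p1$omega), 50L)
  expect_equal(rowSums(p1$omega), rep(1, 50), tolerance = 1e-6)
  expect_true(all(p1$s >= fit$hyper$s_min & p1$s <= fit$hyper$s_max))
  expect_true(all(p1$lambda_b > 0))
  expect_s3_class(p1$mean_mixture, "kernel_mixture")
})

test_that("a collapsed latent posterior reproduces the eps = 0 decode", {
  fit <- fit_cache()
  # force sigma ~ 0 by pushing the encoder log-variance head far negative
  fit2 <- fit
  L <- length(fit2$par$enc_lv)
  fit2$par$enc_lv[[L]]$W[] <- 0
  fit2$par$enc_lv[[L]]$b[] <- -60
  post <- posterior_sample(fit2, n = 20, seed = 5)
  enc <- encode(fit2, apply_standardization(fit2$stats, fit2$train_mean_raw))
  dec <- decode(fit2, enc$mu)
  for (l in 1:20) {
    expect_equal(post$omega[l, ], as.vector(dec$omega), tolerance = 1e-8)
    expect_equal(post$s[l, ], as.vector(dec$s), tolerance = 1e-8)
  }
})

test_that("prediction intervals are pointwise mean +/- 1.96 sd, clipped", {
  fit <- fit_cache()
  post <- posterior_sample(fit, n = 200, seed = 6)
  grid <- fit$hyper$grid
  summ <- prediction_interval(post, grid)
  expect_true(all(summ$pi_lower >= 0))
  expect_true(all(summ$pi_lower <= summ$g_mean + 1e-12))
  expect_true(all(summ$g_mean <= summ$pi_upper + 1e-12))
  expect_equal(summ$pi_upper, summ$g_mean + 1.96 * summ$g_sd)
  expect_equal(summ$pi_lower, pmax(summ$g_mean - 1.96 * summ$g_sd, 0))
  # the posterior-mean density integrates to ~ 1 on a wide grid
  wide <- seq(0, 4 * max(grid), by = 0.05)
  mass <- sum(mixture_pdf(wide, post$mean_mixture)) * 0.05
  expect_equal(mass, 1, tolerance = 1e-3)
})

test_that("interval coverage is ~95% for Gaussian-perturbed synthetic draws", {
  # synthetic posterior: kernel parameters jittered around a base mixture
  set.seed(7)
  M <- 6
  centers <- seq(0.5, 8, length.out = M)
  n <- 400
  omega <- softmax_rows(matrix(rnorm(n * M, rep(c(2, 1, 0, 0, 1, 0), each = n), 0.15),
                               n, M))
  s <- matrix(pmin(pmax(rnorm(n * M, 1, 0.05), 0.4), 2), n, M)
  post <- structure(list(omega = omega, s = s, centers = centers,
                         lambda_b = rep(1, n), lambda_b_internal = rep(1, n),
                         lambda_d = rep(1, n), n = n,
                         mean_mixture = kernel_mixture(centers, colMeans(s),
                                                       colMeans(omega) /
                                                         sum(colMeans(omega)))),
                    class = "dpinn_posterior")
  grid <- seq(0.5, 10, by = 0.25)
  summ <- prediction_interval(post, grid)
  # coverage of independent draws from the same ensemble
  omega2 <- softmax_rows(matrix(rnorm(200 * M, rep(c(2, 1, 0, 0, 1, 0), each = 200), 0.15),
                                200, M))
  s2 <- matrix(pmin(pmax(rnorm(200 * M, 1, 0.05), 0.4), 2), 200, M)
  inside <- vapply(1:200, function(l) {
    g <- mixture_pdf(grid, kernel_mixture(centers, s2[l, ],
                                          omega2[l, ] / sum(omega2[l, ])))
    mean(g >= summ$pi_lower & g <= summ$pi_upper)
  }, numeric(1))
  expect_gt(mean(inside), 0.85)
  expect_lt(mean(inside), 1.0)
  # identical draws give a zero-width interval
  post0 <- post
  post0$omega <- post$omega[rep(1, 10), ]
  post0$s <- post$s[rep(1, 10), ]
  post0$lambda_b <- rep(1, 10); post0$lambda_d <- rep(1, 10); post0$n <- 10L
  s0 <- prediction_interval(post0, grid)
  expect_equal(s0$pi_lower, pmax(s0$g_mean, 0) - 0, tolerance = 1e-12)
  expect_equal(s0$g_sd, numeric(length(grid)), tolerance = 1e-12)
})

test_that("pathway characteristics follow their definitions", {
  fit <- fit_cache()
  post <- posterior_sample(fit, n = 100, seed = 8)
  summ <- prediction_interval(post, fit$hyper$grid)
  ch <- summarize_pathway(summ, dip_draws = 600, threshold = 0.05, seed = 1)
  mom <- mixture_moments(post$mean_mixture)
  expect_equal(ch$mu_g, mom$mean)
  expect_equal(ch$cv_g, mom$cv)
  expect_equal(ch$initiation_time, 1 / summ$lambda_b_mean)
  expect_equal(ch$response_time, log(1 / summ$lambda_b_mean) + log(mom$mean))
  expect_true(ch$modality %in% c("unimodal", "multimodal"))
  # response-time identities
  s1 <- summ; s1$lambda_b_mean <- 1
  m1 <- s1$mean_mixture
  # lambda_b = 1 and mu_g = 1 would give response time 0: check additivity
  expect_equal(ch$response_time,
               log(ch$initiation_time) + log(ch$mu_g))
})

test_that("characteristic tables standardize to zero mean unit variance", {
  tab <- data.frame(initiation_time = c(1, 2, 4), mu_g = c(3, 3, 6),
                    cv_g = c(0.5, 0.5, 0.5))
  expect_warning(z <- standardize_characteristics(tab), "zero variance")
  expect_equal(colMeans(z), c(initiation_time = 0, mu_g = 0, cv_g = 0),
               tolerance = 1e-12)
  expect_equal(sd(z$initiation_time), 1, tolerance = 1e-12)
  expect_equal(z$cv_g, c(0, 0, 0))
  # two entries give +/- 1/sqrt(2)... i.e. symmetric z-scores
  z2 <- standardize_characteristics(data.frame(a = c(1, 3), b = c(5, 1)))
  expect_equal(z2$a, c(-1, 1) / sqrt(2))
  expect_equal(z2$b, c(1, -1) / sqrt(2))
})

test_that("dip threshold calibration is a null quantile", {
  th <- dip_threshold(300, n_sims = 30, seed = 2)
  expect_gt(th, 1 / 600)
  expect_lt(th, 0.1)
  # bimodal samples exceed it, unimodal mostly do not
  set.seed(3)
  expect_gt(dip_statistic(c(rnorm(150), rnorm(150, 8))), th)
  expect_lt(dip_statistic(runif(300)), 2 * th)
})
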