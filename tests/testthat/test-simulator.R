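test_that("delay specs expose consistent pdf/cdf/sampler", {
  specs <- list(
    delay_spec("gamma", shape = 8, rate = 2),
    delay_spec("uniform", min = 2, max = 8),
    delay_spec("mixture",
               components = list(delay_spec("gamma", shape = 16, rate = 4),
                                 delay_spec("gamma", shape = 100, rate = 10)),
               weights = c(0.5, 0.5)),
    delay_spec(kernel_mixture(c(1, 4), c(0.5, 1), c(0.4, 0.6))))
  set.seed(1)
  for (g in specs) {
    x <- g$sample(2e4)
    expect_true(all(x >= 0))
    xs <- sort(x)
    sup <- max(abs(ecdf(x)(xs) - g$cdf(xs)))
    expect_lt(sup, 0.02)
    # cdf is the integral of the pdf
    mid <- median(x)
    quad <- integrate(g$pdf, 0, mid, rel.tol = 1e-9)$value
    expect_equal(g$cdf(mid), quad, tolerance = 1e-6)
  }
  expect_error(delay_spec("nope"), "unknown delay family")
})

test_that("delayed_ssa respects degenerate limits", {
  scen0 <- simulation_scenario(0, 0.5, delay_spec("point", at = 1), t_max = 10)
  expect_equal(delayed_ssa(scen0, seed = 1), numeric(21))
  # no molecule can appear before the deterministic delay
  scen <- simulation_scenario(10, 0.3, delay_spec("point", at = 4), t_max = 10)
  grid <- seq(0, 10, by = 0.5)
  for (s in 1:20) {
    tr <- delayed_ssa(scen, seed = s)
    expect_true(all(tr[grid < 4] == 0))
    expect_true(all(tr == floor(tr) & tr >= 0))
  }
})

test_that("point-mass delay mean trace matches the analytic solution", {
  lb <- 12; ld <- 0.6; tau0 <- 3
  scen <- simulation_scenario(lb, ld, delay_spec("point", at = tau0),
                              t_max = 12, n_traces = 400, seed = 42)
  dat <- generate_dataset(scen)
  grid <- dat$time
  emp <- rowMeans(dat$traces)
  se <- apply(dat$traces, 1, sd) / sqrt(ncol(dat$traces))
  theo <- (lb / ld) * (1 - exp(-ld * pmax(grid - tau0, 0))) * (grid >= tau0)
  expect_true(all(abs(emp - theo) <= 3.5 * pmax(se, 1e-9) + 1e-9))
})

test_that("mean_trace_ode solves the governing equation", {
  grid <- seq(0, 30, by = 0.5)
  y <- mean_trace_ode(8, 0.4, function(t) pmin(t * 100, 1) * (t > 0), grid)
  # steady state lambda_b / lambda_d once G ~ 1
  expect_equal(y[length(y)], 8 / 0.4, tolerance = 1e-4)
  # lambda_d = 0: y = lambda_b * int_0^t G, nondecreasing
  G <- delay_spec("gamma", shape = 8, rate = 2)
  y0 <- mean_trace_ode(5, 0, G, grid)
  expect_true(all(diff(y0) >= 0))
  intG <- vapply(grid, function(tt)
    integrate(G$cdf, 0, tt, rel.tol = 1e-10)$value, numeric(1))
  expect_equal(y0, 5 * intG, tolerance = 1e-6)
  # point-mass closed form (discontinuous G: fine quadrature needed)
  yp <- mean_trace_ode(12, 0.6, function(t) as.numeric(t >= 3), grid,
                       substeps = 500L)
  theo <- (12 / 0.6) * (1 - exp(-0.6 * pmax(grid - 3, 0))) * (grid >= 3)
  expect_equal(yp, theo, tolerance = 1e-3)
  expect_error(mean_trace_ode(1, 1, function(t) -t, grid), "nondecreasing")
})

test_that("presets have the advertised shapes and sampling design", {
  ps <- preset_scenarios()
  expect_named(ps, c("unimodal", "weakly_bimodal", "strongly_bimodal",
                     "trimodal", "flat_peak"))
  for (p in ps) {
    grid <- seq(0, p$t_max, by = p$dt)
    expect_equal(p$dt, 0.5)
    expect_equal(length(grid), 41L)      # T/dt ~ 40 points
    expect_equal(p$n_traces, 50L)
  }
  set.seed(3)
  dips <- vapply(ps[c("unimodal", "weakly_bimodal", "strongly_bimodal")],
                 function(p) dip_statistic(p$delay$sample(1e4)), numeric(1))
  expect_lt(dips["unimodal"], dips["weakly_bimodal"])
  expect_lt(dips["weakly_bimodal"], dips["strongly_bimodal"])
  # responses saturate within the horizon: mean-field plateau reached
  for (p in ps) {
    grid <- seq(0, p$t_max, by = p$dt)
    y <- mean_trace_ode(p$lambda_b, p$lambda_d, p$delay, grid)
    expect_gt(y[length(y)], 0.9 * p$lambda_b / p$lambda_d)
  }
})

test_that("generate_dataset is seeded, sized and noise-consistent", {
  ps <- preset_scenarios(n_traces = 50L)
  d1 <- generate_dataset(ps$unimodal, seed = 4)
  d2 <- generate_dataset(ps$unimodal, seed = 4)
  expect_identical(d1$traces, d2$traces)
  expect_equal(ncol(d1$traces), 50L)
  truth <- attr(d1, "truth")
  expect_equal(truth$lambda_b, 20)
  expect_equal(truth$lambda_d, 0.5)
  # noise_sd = 0 gives bitwise-identical output to the noiseless path
  psn <- preset_scenarios(n_traces = 5L, noise_sd = 0)
  expect_identical(generate_dataset(psn$unimodal, seed = 9)$traces,
                   generate_dataset(psn$unimodal, seed = 9)$traces)
  # multiplicative noise is mean-one: pointwise means agree within MC error
  scen_n <- simulation_scenario(20, 0.5, delay_spec("gamma", shape = 8, rate = 2),
                                t_max = 20, n_traces = 300, noise_sd = 0.2,
                                seed = 11)
  scen_0 <- simulation_scenario(20, 0.5, delay_spec("gamma", shape = 8, rate = 2),
                                t_max = 20, n_traces = 300, noise_sd = 0,
                                seed = 11)
  mn <- rowMeans(generate_dataset(scen_n)$traces)
  m0 <- rowMeans(generate_dataset(scen_0)$traces)
  expect_equal(mn[-1], m0[-1], tolerance = 0.12)
})

test_that("zero-delay limit is an immigration-death process", {
  # molecule count at a time well past relaxation ~ Poisson(lambda_b/lambda_d)
  scen <- simulation_scenario(6, 0.8, delay_spec("point", at = 0),
                              t_max = 12, n_traces = 600, seed = 21)
  dat <- generate_dataset(scen)
  finals <- dat$traces[nrow(dat$traces), ]
  lam <- 6 / 0.8
  expect_equal(mean(finals), lam, tolerance = 4 * sqrt(lam / 600))
  expect_equal(var(finals), lam, tolerance = 0.2 * lam)
})
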