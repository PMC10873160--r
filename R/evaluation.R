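#' Kullback-Leibler divergence between two densities on a grid
#'
#' Both densities are renormalized on the grid (trapezoid-free rectangle rule
#' with the grid spacing), the estimate is floored at `eps` to avoid division
#' by zero where it carries no mass, and terms with `p = 0` contribute 0.
#'
#' @param p True density values on the grid (nonnegative).
#' @param q Estimated density values on the same grid.
#' @param grid Evaluation times (uniform spacing assumed for the quadrature
#'   weight; non-uniform grids use per-interval widths).
#' @param eps Floor applied to the renormalized `q` (default 1e-12).
#' @return Nonnegative scalar `sum p * log(p / q) * dt`.
#' @export
kl_divergence <- function(p, q, grid, eps = 1e-12) {
  stopifnot(length(p) == length(q), length(p) == length(grid))
  if (any(p < 0) || any(q < 0)) stop("densities must be nonnegative")
  w <- diff(grid)
  w <- c(w, w[length(w)])                # rectangle weights
  sp <- sum(p * w); sq <- sum(q * w)
  if (sp <= 0) stop("'p' has zero mass on the grid")
  if (sq <= 0) stop("'q' has zero mass on the grid")
  pn <- p / sp
  qn <- pmax(q / sq, eps)
  pos <- pn > 0
  sum(pn[pos] * log(pn[pos] / qn[pos]) * w[pos])
}

#' Hartigan's dip statistic of unimodality
#'
#' The dip is the smallest sup-norm distance between the empirical CDF of
#' `samples` and any unimodal CDF (convex to the left of its mode, concave to
#' the right).  It lies in `[1/(2n), 0.25]`, is invariant under monotone
#' affine transformations of the sample, and grows with multimodality.
#' Values agree with the canonical AS 217 implementation; tied observations
#' are treated as infinitesimally separated.
#'
#' @param samples At least 4 finite numeric values.
#' @return The dip statistic, a scalar in `[0, 0.25]`.
#' @examples
#' dip_statistic(rnorm(200))                     # small: unimodal
#' dip_statistic(c(rnorm(100), rnorm(100, 10)))  # large: bimodal
#' @export
dip_statistic <- function(samples) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (length(samples) < 4L) stop("dip statistic requires at least 4 samples")
  .dip_cpp(sort(samples))
}

#' Population coefficient of variation at the final observation point
#'
#' The cell-to-cell heterogeneity measure: SD/mean of the trace values at
#' the last time point (sample SD, denominator N - 1).
#'
#' @param Y A [time_trace_set()] with at least 2 traces.
#' @return Scalar CV.
#' @export
population_cv <- function(Y) {
  stopifnot(inherits(Y, "time_trace_set"))
  if (ncol(Y$traces) < 2L) stop("population CV needs at least 2 traces")
  final <- Y$traces[nrow(Y$traces), ]
  mu <- mean(final)
  if (mu == 0) stop("mean response at the final observation point is zero; CV undefined")
  stats::sd(final) / mu
}

#' Correlation of population CV against pathway characteristics
#'
#' Convenience helper: Pearson correlation (and test) of a population-CV
#' column against each remaining numeric column of a characteristics table.
#'
#' @param tab Data frame with a `cv_population` column plus numeric
#'   characteristic columns.
#' @return Data frame with `characteristic`, `r`, `p_value`.
#' @export
cv_correlations <- function(tab) {
  stopifnot(is.data.frame(tab), "cv_population" %in% names(tab))
  vars <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))], "cv_population")
  out <- lapply(vars, function(v) {
    ct <- stats::cor.test(tab[[v]], tab$cv_population)
    data.frame(characteristic = v, r = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, out)
}

#' Replicated parameter-recovery experiment
#'
#' For each trace count in `n_list` and each of `replicates` replicate
#' datasets: simulate from a preset scenario, fit the estimator, run
#' posterior inference, and record the estimated rates, the KL divergence
#' between the true and estimated delay density, and the dip statistic of
#' the estimated delay distribution.  A failed fit is recorded with `NA`s
#' and a warning, never silently dropped.
#'
#' @param preset Preset name (see [preset_scenarios()]).
#' @param replicates Number of replicate datasets R (desk-scale default 10).
#' @param n_list Trace counts to sweep (default 50).
#' @param seed Base seed; replicate r with trace count N uses a deterministic
#'   sub-seed.
#' @param config Training configuration from [training_config()].
#' @param fix_lambda_d Fix the decay rate at the scenario truth during
#'   fitting.
#' @param noise_sd Multiplicative measurement-noise SD for the datasets.
#' @param dip_draws Draws from each fitted mixture for the dip statistic.
#' @return Data frame of class `"recovery_report"` with one row per
#'   (N, replicate): `preset`, `n_traces`, `replicate`, `lambda_b_true`,
#'   `lambda_d_true`, `lambda_b_hat`, `lambda_d_hat`, `kl`, `dip`.
#' @export
recovery_experiment <- function(preset, replicates = 10L, n_list = 50L,
                                seed = 1L, config = training_config(),
                                fix_lambda_d = FALSE, noise_sd = 0,
                                dip_draws = 5000L) {
  stopifnot(replicates >= 1L, all(n_list >= 1L))
  presets <- preset_scenarios(noise_sd = noise_sd)
  if (!preset %in% names(presets))
    stop(sprintf("unknown preset '%s'", preset))
  base <- presets[[preset]]
  rows <- list()
  for (N in n_list) {
    for (r in seq_len(replicates)) {
      sub_seed <- (seed * 1000L + N * 10L + r) %% .Machine$integer.max
      scen <- simulation_scenario(base$lambda_b, base$lambda_d, base$delay,
                                  base$t_max, base$dt, n_traces = N,
                                  noise_sd = noise_sd, seed = sub_seed,
                                  name = base$name)
      dat <- generate_dataset(scen)
      res <- tryCatch({
        cfg <- config
        cfg$seed <- sub_seed + 1L
        fit <- train_dpinn(dat, config = cfg,
                           fixed_lambda_d = if (fix_lambda_d) base$lambda_d else NULL)
        post <- posterior_sample(fit, n = 1000L, seed = sub_seed + 2L)
        summ <- prediction_interval(post, grid = scenario_grid(scen))
        gq <- mixture_pdf(scenario_grid(scen), post$mean_mixture)
        gp <- base$delay$pdf(scenario_grid(scen))
        list(lb = summ$lambda_b_mean, ld = summ$lambda_d_mean,
             kl = kl_divergence(gp, gq, scenario_grid(scen)),
             dip = dip_statistic(sample_mixture(post$mean_mixture, dip_draws,
                                                seed = sub_seed + 3L)))
      }, error = function(e) {
        warning(sprintf("replicate %d (N = %d) failed: %s", r, N,
                        conditionMessage(e)))
        list(lb = NA_real_, ld = NA_real_, kl = NA_real_, dip = NA_real_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        preset = preset, n_traces = N, replicate = r,
        lambda_b_true = base$lambda_b, lambda_d_true = base$lambda_d,
        lambda_b_hat = res$lb, lambda_d_hat = res$ld,
        kl = res$kl, dip = res$dip)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", class(out))
  out
}

#' Summarize a recovery report
#' @param object A `"recovery_report"`.
#' @param ... Unused.
#' @return Data frame of medians and quartiles per trace count.
#' @export
summary.recovery_report <- function(object, ...) {
  sp <- split(object, object$n_traces)
  do.call(rbind, lapply(sp, function(d) {
    q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(n_traces = d$n_traces[1], n_ok = sum(!is.na(d$kl)),
               lambda_b_med = q(d$lambda_b_hat)[2],
               lambda_d_med = q(d$lambda_d_hat)[2],
               kl_q1 = q(d$kl)[1], kl_med = q(d$kl)[2], kl_q3 = q(d$kl)[3],
               dip_med = q(d$dip)[2])
  }))
}
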