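#' Sample the posterior of the delay distribution and rates
#'
#' Passes the (standardized) population mean trace through the encoder,
#' draws `n` latent samples from N(mu, diag(sigma^2)), and decodes each into
#' a kernel mixture g~ and rates.  The activation rate is returned both on
#' the internal (standardized) scale and back-transformed to raw units
#' (exact for the default `"scale"` standardization, which is a pure
#' rescaling of the governing equation).
#'
#' @param model A trained [dpinn_model()].
#' @param traces Optional [time_trace_set()] whose mean trace is used;
#'   defaults to the training data's mean trace stored in the model.
#' @param n Number of posterior draws (default 1000).
#' @param seed Optional seed.
#' @return An object of class `"dpinn_posterior"`: list with `omega`,
#'   `s` (n x M), `lambda_b`, `lambda_d` (raw scale, length n),
#'   `lambda_b_internal`, `mu`, `sigma`, `mean_mixture` (a
#'   [kernel_mixture()] built from the posterior-mean parameters), and
#'   `centers`.
#' @export
posterior_sample <- function(model, traces = NULL, n = 1000L, seed = NULL) {
  stopifnot(inherits(model, "dpinn_model"))
  if (!model$trained) stop("model is untrained; call train_dpinn() first")
  n <- as.integer(n)
  stopifnot(n >= 1L)
  ybar_raw <- if (is.null(traces)) model$train_mean_raw
              else rowMeans(traces$traces)
  if (length(ybar_raw) != model$hyper$d)
    stop("mean trace length does not match the model's grid")
  ybar <- apply_standardization(model$stats, ybar_raw)
  if (!is.null(seed)) set.seed(seed)
  enc <- encode(model, ybar)
  k <- model$hyper$k
  eps <- matrix(stats::rnorm(n * k), n, k)
  Z <- sweep(sweep(eps, 2L, as.vector(enc$sigma), "*"),
             2L, as.vector(enc$mu), "+")
  dec <- decode(model, Z)
  scale_fac <- if (model$stats$mode == "pointwise") NA_real_
               else rep_len(model$stats$scale, 1L)[1L]
  lb_raw <- dec$lambda_b * scale_fac
  structure(list(
    omega = dec$omega, s = dec$s,
    lambda_b = lb_raw, lambda_b_internal = dec$lambda_b,
    lambda_d = dec$lambda_d,
    mu = as.vector(enc$mu), sigma = as.vector(enc$sigma),
    centers = model$hyper$centers,
    mean_mixture = kernel_mixture_unchecked(model$hyper$centers,
                                            colMeans(dec$s),
                                            colMeans(dec$omega)),
    n = n
  ), class = "dpinn_posterior")
}

#' Pointwise 95% prediction interval of the estimated delay distribution
#'
#' Evaluates every posterior draw's mixture density on `grid`, then reports
#' the pointwise sample mean m(t), SD S(t), and the interval
#' `[max(m - 1.96 S, 0), m + 1.96 S]`, together with posterior mean +/- SD
#' of the rates.
#'
#' @param post A `"dpinn_posterior"` from [posterior_sample()].
#' @param grid Evaluation times.
#' @return An object of class `"posterior_summary"`: list with `grid`,
#'   `g_mean`, `g_sd`, `pi_lower`, `pi_upper`, `lambda_b_mean`,
#'   `lambda_b_sd`, `lambda_d_mean`, `lambda_d_sd`, `n_samples`,
#'   `mean_mixture`.
#' @export
prediction_interval <- function(post, grid) {
  stopifnot(inherits(post, "dpinn_posterior"))
  if (post$n < 2L) stop("need at least 2 posterior draws")
  G <- matrix(0, post$n, length(grid))
  for (l in seq_len(post$n)) {
    m <- kernel_mixture_unchecked(post$centers, post$s[l, ], post$omega[l, ])
    G[l, ] <- mixture_pdf(grid, m)
  }
  g_mean <- colMeans(G)
  g_sd <- apply(G, 2L, stats::sd)
  structure(list(
    grid = grid, g_mean = g_mean, g_sd = g_sd,
    pi_lower = pmax(g_mean - 1.96 * g_sd, 0),
    pi_upper = g_mean + 1.96 * g_sd,
    lambda_b_mean = mean(post$lambda_b), lambda_b_sd = stats::sd(post$lambda_b),
    lambda_d_mean = mean(post$lambda_d), lambda_d_sd = stats::sd(post$lambda_d),
    n_samples = post$n, mean_mixture = post$mean_mixture
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary from %d draws\n", x$n_samples))
  cat(sprintf("  lambda_b = %.4g +/- %.3g /h, lambda_d = %.4g +/- %.3g /h\n",
              x$lambda_b_mean, x$lambda_b_sd, x$lambda_d_mean, x$lambda_d_sd))
  mom <- mixture_moments(x$mean_mixture)
  cat(sprintf("  delay distribution: mean %.3g h, sd %.3g h, cv %.3g\n",
              mom$mean, sqrt(mom$variance), mom$cv))
  invisible(x)
}

#' Export a posterior summary
#' @param summ A `"posterior_summary"`.
#' @param csv_path CSV of `(t, g_mean, g_sd, pi_lower, pi_upper)`.
#' @param json_path Optional JSON of the scalar estimates.
#' @return `csv_path`, invisibly.
#' @export
write_posterior_summary <- function(summ, csv_path, json_path = NULL) {
  stopifnot(inherits(summ, "posterior_summary"))
  utils::write.csv(data.frame(t = summ$grid, g_mean = summ$g_mean,
                              g_sd = summ$g_sd, pi_lower = summ$pi_lower,
                              pi_upper = summ$pi_upper),
                   csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    writeLines(jsonlite::toJSON(list(
      lambda_b_mean = summ$lambda_b_mean, lambda_b_sd = summ$lambda_b_sd,
      lambda_d_mean = summ$lambda_d_mean, lambda_d_sd = summ$lambda_d_sd,
      n_samples = summ$n_samples), digits = NA, auto_unbox = TRUE), json_path)
  }
  invisible(csv_path)
}

#' Monte-Carlo threshold for the dip statistic under a unimodal null
#'
#' 95th percentile (at level `alpha`) of the dip statistic of `n` draws from
#' the uniform distribution, the classical conservative unimodal null.
#'
#' @param n Sample size the threshold is calibrated for.
#' @param alpha Test level (default 0.05).
#' @param n_sims Null simulations (default 100).
#' @param seed Seed for the null simulations.
#' @return Scalar threshold.
#' @export
dip_threshold <- function(n, alpha = 0.05, n_sims = 100L, seed = 1L) {
  set.seed(seed)
  null_dips <- vapply(seq_len(n_sims),
                      function(i) dip_statistic(stats::runif(n)), numeric(1))
  unname(stats::quantile(null_dips, 1 - alpha))
}

#' Pathway characteristics from a posterior summary
#'
#' Derives the signal-initiation time 1/lambda_b, the delay-distribution
#' mean, SD and CV (from the posterior-mean mixture), the log response time
#' `log(1/lambda_b) + log(mu_g)`, and a modality call: the dip statistic of
#' `dip_draws` samples from the posterior-mean mixture compared against a
#' uniform-null threshold at level 0.05.
#'
#' @param summ A `"posterior_summary"`.
#' @param dip_draws Draws from the fitted mixture (default 5000).
#' @param threshold Optional fixed dip threshold; when `NULL` it is
#'   calibrated by [dip_threshold()].
#' @param seed Seed for the mixture draws (and null calibration).
#' @return An object of class `"pathway_characteristics"`: list with
#'   `initiation_time`, `mu_g`, `sigma_g`, `cv_g`, `response_time`,
#'   `dip`, `dip_threshold`, `modality` (`"unimodal"` or `"multimodal"`).
#' @export
summarize_pathway <- function(summ, dip_draws = 5000L, threshold = NULL,
                              seed = 1L) {
  stopifnot(inherits(summ, "posterior_summary"))
  mom <- mixture_moments(summ$mean_mixture)
  lb <- summ$lambda_b_mean
  draws <- sample_mixture(summ$mean_mixture, dip_draws, seed = seed)
  dp <- dip_statistic(draws)
  if (is.null(threshold))
    threshold <- dip_threshold(dip_draws, seed = seed + 1L)
  structure(list(
    initiation_time = 1 / lb,
    mu_g = mom$mean, sigma_g = sqrt(mom$variance), cv_g = mom$cv,
    response_time = log(1 / lb) + log(mom$mean),
    dip = dp, dip_threshold = threshold,
    modality = if (dp > threshold) "multimodal" else "unimodal"
  ), class = "pathway_characteristics")
}

#' @export
print.pathway_characteristics <- function(x, ...) {
  cat(sprintf("Pathway characteristics: initiation %.3g h, mu_g %.3g h, sd %.3g h, cv %.3g\n",
              x$initiation_time, x$mu_g, x$sigma_g, x$cv_g))
  cat(sprintf("  log response time %.3g; dip %.4g (threshold %.4g) -> %s\n",
              x$response_time, x$dip, x$dip_threshold, x$modality))
  invisible(x)
}

#' Z-score a table of pathway characteristics
#'
#' Column-wise standardization to zero mean and unit variance across
#' entries (e.g. promoters); zero-variance columns become all-zero with a
#' warning.
#'
#' @param chars A list of `"pathway_characteristics"` objects or a numeric
#'   data frame.
#' @return Data frame of z-scored numeric columns.
#' @export
standardize_characteristics <- function(chars) {
  if (!is.data.frame(chars)) {
    stopifnot(is.list(chars), length(chars) >= 2L)
    chars <- do.call(rbind, lapply(chars, function(ch)
      data.frame(initiation_time = ch$initiation_time, mu_g = ch$mu_g,
                 sigma_g = ch$sigma_g, cv_g = ch$cv_g,
                 response_time = ch$response_time)))
  }
  if (nrow(chars) < 2L) stop("need at least 2 entries to standardize")
  num <- vapply(chars, is.numeric, logical(1))
  out <- chars
  for (j in which(num)) {
    v <- chars[[j]]
    sdv <- stats::sd(v)
    if (sdv == 0) {
      warning(sprintf("column '%s' has zero variance; set to 0", names(chars)[j]))
      out[[j]] <- v * 0
    } else {
      out[[j]] <- (v - mean(v)) / sdv
    }
  }
  out
}
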