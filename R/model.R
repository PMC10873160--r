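#' Standardize a set of time traces
#'
#' Puts raw traces on the estimator's internal scale and records the affine
#' transform so that the identical mapping can be applied to the mean trace
#' at inference time (and inverted for reporting).
#'
#' Modes:
#' * `"scale"` (default): divide by the mean final-point response.  This is a
#'   pure rescaling, so the governing equation keeps its form with
#'   `lambda_b -> lambda_b / scale` and `lambda_d` unchanged, the internal
#'   traces start at 0 and plateau near 1 (matching the reconstruction,
#'   whose kernel-CDF mixture saturates at 1), and the activation rate
#'   back-transforms exactly as `lambda_b = lambda_b_internal * scale`.
#' * `"global"`: pooled z-score over all traces and times.
#' * `"pointwise"`: per-time-point z-score across traces.  Note that under
#'   this mode the population mean trace standardizes to the zero vector.
#'
#' @param Y A [time_trace_set()] (N >= 2 for data-driven statistics).
#' @param mode Standardization dialect, see above.
#' @return List with `y_std` (N x d matrix, traces in rows) and `stats`
#'   (list `mode`, `center`, `scale`) reusable via
#'   [apply_standardization()] / [invert_standardization()].
#' @export
standardize_traces <- function(Y, mode = c("scale", "global", "pointwise")) {
  stopifnot(inherits(Y, "time_trace_set"))
  mode <- match.arg(mode)
  X <- t(Y$traces)                       # N x d
  if (nrow(X) < 2L && mode != "scale")
    stop("need at least 2 traces for data-driven standardization statistics")
  if (mode == "scale") {
    sc <- mean(X[, ncol(X)])
    if (!is.finite(sc) || sc <= 0) {
      sc <- stats::sd(as.vector(X))
      if (!is.finite(sc) || sc == 0) sc <- 1
      warning("nonpositive mean final response; falling back to pooled SD scale")
    }
    stats <- list(mode = mode, center = 0, scale = sc)
  } else if (mode == "global") {
    mu <- mean(X); sg <- stats::sd(as.vector(X))
    if (sg == 0) { sg <- 1; warning("zero pooled variance; unit scale used") }
    stats <- list(mode = mode, center = mu, scale = sg)
  } else {
    mu <- colMeans(X); sg <- apply(X, 2L, stats::sd)
    if (any(sg == 0)) {
      warning("zero variance at some time points; pooled SD substituted there")
      pool <- stats::sd(as.vector(X)); if (pool == 0) pool <- 1
      sg[sg == 0] <- pool
    }
    stats <- list(mode = mode, center = mu, scale = sg)
  }
  list(y_std = apply_standardization(stats, X), stats = stats)
}

#' @rdname standardize_traces
#' @param stats Statistics list from [standardize_traces()].
#' @param X Matrix of traces in rows (or a single trace vector).
#' @export
apply_standardization <- function(stats, X) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  out <- sweep(sweep(X, 2L, rep_len(stats$center, ncol(X)), "-"),
               2L, rep_len(stats$scale, ncol(X)), "/")
  if (vec) out[1L, ] else out
}

#' @rdname standardize_traces
#' @export
invert_standardization <- function(stats, X) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  out <- sweep(sweep(X, 2L, rep_len(stats$scale, ncol(X)), "*"),
               2L, rep_len(stats$center, ncol(X)), "+")
  if (vec) out[1L, ] else out
}

#' Construct an untrained delay-distribution estimator
#'
#' The architecture is a variational autoencoder with a physics-informed
#' decoder: an encoder (input d, two tanh hidden layers of width 16, linear
#' heads for the latent mean and log-variance, latent dimension k = 4) and
#' three decoder networks mapping the latent variable to (i) kernel weights
#' omega on the probability simplex, (ii) kernel scales s in
#' `[s_min, s_max]`, and (iii) positive rates (lambda_b, lambda_d); a fourth
#' network (input, one hidden and output layer all of width M) maps omega to
#' the reconstruction weights omega'.  Kernel shifts are M points evenly
#' spaced over the observation window (default: the observation times
#' themselves, M = d).
#'
#' @param grid Observation time grid (length d >= 4).
#' @param M Number of Rayleigh kernels (default `length(grid)`).
#' @param k Latent dimension (default 4).
#' @param hidden Hidden width of encoder/decoder networks (default 16).
#' @param s_min,s_max Bounds for the kernel scales; defaults are the grid
#'   spacing and a quarter of the horizon.
#' @param fixed_lambda_d Optional known decay rate (raw units, per hour);
#'   when set, `decode()` returns this constant for lambda_d.
#' @param seed Seed for parameter initialization.
#' @return An object of class `"dpinn_model"`.
#' @export
dpinn_model <- function(grid, M = length(grid), k = 4L, hidden = 16L,
                        s_min = NULL, s_max = NULL, fixed_lambda_d = NULL,
                        seed = 1L) {
  grid <- as.numeric(grid)
  d <- length(grid)
  if (d < 4L) stop("need at least 4 observation times")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  T_end <- max(grid)
  if (is.null(s_min)) s_min <- min(diff(grid))
  if (is.null(s_max)) s_max <- max(T_end / 8, 2 * s_min)
  stopifnot(s_min > 0, s_max > s_min, M >= 1L, k >= 1L)
  centers <- if (M == d) grid else seq(0, T_end, length.out = M)
  set.seed(seed)
  par <- list(
    enc_trunk = mlp_init(c(d, hidden, hidden)),
    enc_mu = mlp_init(c(hidden, k)),
    enc_lv = mlp_init(c(hidden, k)),
    dec_omega = mlp_init(c(k, hidden, hidden, M)),
    dec_s = mlp_init(c(k, hidden, hidden, M)),
    dec_rate = mlp_init(c(k, hidden, 2L)),
    wnet = mlp_init(c(M, M, M))
  )
  # Start both rates small (softplus ~ 0.1/h).  lambda_d is only identified
  # from below -- any faster decay can be compensated by reshaping g -- so
  # the optimizer must approach the feasible region from slow rates and stop
  # at the smallest decay consistent with the data.
  par$dec_rate[[length(par$dec_rate)]]$b[] <- log(expm1(0.1))
  structure(list(
    par = par,
    hyper = list(d = d, k = as.integer(k), M = as.integer(M),
                 hidden = as.integer(hidden), s_min = s_min, s_max = s_max,
                 grid = grid, centers = centers,
                 fixed_lambda_d = fixed_lambda_d),
    stats = NULL,               # standardization record, set by training
    train_mean_raw = NULL,      # raw-scale mean trace of the training data
    trained = FALSE,
    history = NULL
  ), class = "dpinn_model")
}

#' @export
print.dpinn_model <- function(x, ...) {
  h <- x$hyper
  cat(sprintf("Density-PINN model: d = %d, latent k = %d, M = %d kernels, hidden %d\n",
              h$d, h$k, h$M, h$hidden))
  cat(sprintf("  kernel scale bounds [%.3g, %.3g] h; %s\n", h$s_min, h$s_max,
              if (is.null(h$fixed_lambda_d)) "lambda_d free"
              else sprintf("lambda_d fixed at %g /h", h$fixed_lambda_d)))
  cat(sprintf("  %s\n", if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Encode traces to the latent Gaussian
#'
#' @param model A [dpinn_model()].
#' @param y Standardized trace (length-d vector) or N x d matrix.
#' @return List with `mu` and `sigma` (each N x k), and `lv`
#'   (log sigma^2).
#' @export
encode <- function(model, y) {
  stopifnot(inherits(model, "dpinn_model"))
  vec <- is.null(dim(y))
  Y <- if (vec) matrix(y, nrow = 1L) else as.matrix(y)
  if (ncol(Y) != model$hyper$d)
    stop(sprintf("input has length %d, expected d = %d", ncol(Y), model$hyper$d))
  tr <- mlp_forward(model$par$enc_trunk, Y)
  mu <- mlp_forward(model$par$enc_mu, tr$out)$out
  lv <- mlp_forward(model$par$enc_lv, tr$out)$out
  list(mu = mu, sigma = exp(0.5 * lv), lv = lv)
}

#' Reparameterization: z = mu + sigma * eps
#'
#' @param mu,sigma Latent mean and SD (vectors or matrices of equal shape).
#' @param eps Standard-normal draw of the same shape.
#' @return z of the same shape.
#' @export
reparameterize <- function(mu, sigma, eps) {
  stopifnot(length(mu) == length(sigma), length(mu) == length(eps))
  mu + sigma * eps
}

#' Decode latent variables to mixture parameters and rates
#'
#' @param model A [dpinn_model()].
#' @param z Latent vector (length k) or N x k matrix.
#' @return List with `omega` (simplex, N x M), `s` (in `[s_min, s_max]`,
#'   N x M), `lambda_b`, `lambda_d` (positive, length N; `lambda_d` equals
#'   the configured constant in fixed-lambda_d mode).
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "dpinn_model"))
  Z <- if (is.null(dim(z))) matrix(z, nrow = 1L) else as.matrix(z)
  if (ncol(Z) != model$hyper$k)
    stop(sprintf("latent input has length %d, expected k = %d",
                 ncol(Z), model$hyper$k))
  h <- model$hyper
  omega <- softmax_rows(mlp_forward(model$par$dec_omega, Z)$out)
  s <- h$s_min + (h$s_max - h$s_min) *
    sigmoid(mlp_forward(model$par$dec_s, Z)$out)
  rates <- softplus(mlp_forward(model$par$dec_rate, Z)$out)
  lambda_b <- rates[, 1L]
  lambda_d <- if (is.null(h$fixed_lambda_d)) rates[, 2L]
              else rep(h$fixed_lambda_d, nrow(Z))
  list(omega = omega, s = s, lambda_b = lambda_b, lambda_d = lambda_d)
}

#' Map kernel weights to reconstruction weights
#'
#' @param model A [dpinn_model()].
#' @param omega Simplex weights (length M or N x M).
#' @return omega' of the same shape, on the simplex.
#' @export
transform_weights <- function(model, omega) {
  stopifnot(inherits(model, "dpinn_model"))
  vec <- is.null(dim(omega))
  Om <- if (vec) matrix(omega, nrow = 1L) else as.matrix(omega)
  if (ncol(Om) != model$hyper$M)
    stop(sprintf("omega has length %d, expected M = %d", ncol(Om), model$hyper$M))
  out <- softmax_rows(mlp_forward(model$par$wnet, Om)$out)
  if (vec) out[1L, ] else out
}

#' Reconstruct the response curve from reconstruction weights and scales
#'
#' \deqn{\tilde y(t) = \sum_j \omega'_j \int_0^t K(u; c_j, s_j)\,du
#'   = \sum_j \omega'_j F(t; c_j, s_j)}
#' using the closed-form kernel CDF F; no numerical integration.
#'
#' @param omega_prime Reconstruction weights (length M).
#' @param s Kernel scales (length M).
#' @param centers Kernel shifts (length M).
#' @param tgrid Evaluation times.
#' @return Numeric vector, nondecreasing, 0 at t = 0, saturating at
#'   `sum(omega_prime)`.
#' @export
reconstruct <- function(omega_prime, s, centers, tgrid) {
  stopifnot(length(omega_prime) == length(s), length(s) == length(centers))
  out <- numeric(length(tgrid))
  for (j in seq_along(centers)) {
    u <- pmax(tgrid - centers[j], 0)
    out <- out - omega_prime[j] * expm1(-u^2 / (2 * s[j]^2))
  }
  out
}

# full forward pass with caches, used by the training loop
.forward_full <- function(model, Ystd, eps) {
  h <- model$hyper
  tr <- mlp_forward(model$par$enc_trunk, Ystd)
  fmu <- mlp_forward(model$par$enc_mu, tr$out)
  flv <- mlp_forward(model$par$enc_lv, tr$out)
  mu <- fmu$out; lv <- flv$out
  sigma <- exp(0.5 * lv)
  z <- mu + sigma * eps
  fom <- mlp_forward(model$par$dec_omega, z)
  omega <- softmax_rows(fom$out)
  fs <- mlp_forward(model$par$dec_s, z)
  sig_s <- sigmoid(fs$out)
  s <- h$s_min + (h$s_max - h$s_min) * sig_s
  fr <- mlp_forward(model$par$dec_rate, z)
  lb <- softplus(fr$out[, 1L])
  ld <- if (is.null(h$fixed_lambda_d)) softplus(fr$out[, 2L])
        else rep(h$fixed_lambda_d, nrow(z))
  fw <- mlp_forward(model$par$wnet, omega)
  omegap <- softmax_rows(fw$out)
  list(tr = tr, fmu = fmu, flv = flv, mu = mu, lv = lv, sigma = sigma,
       z = z, eps = eps, fom = fom, omega = omega, fs = fs, sig_s = sig_s,
       s = s, fr = fr, lb = lb, ld = ld, fw = fw, omegap = omegap)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file holding all network parameters at
#' full precision plus the hyperparameters, standardization record, and
#' training-data mean trace.
#'
#' @param model A trained or untrained [dpinn_model()].
#' @param path Output file.
#' @return `path` (invisibly) for `save_checkpoint`; a `"dpinn_model"` for
#'   `load_checkpoint`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dpinn_model"))
  ser_mlp <- function(layers) lapply(layers, function(l)
    list(W = as.vector(l$W), dim = dim(l$W), b = l$b))
  obj <- list(
    par = lapply(model$par, ser_mlp),
    hyper = model$hyper,
    stats = model$stats,
    train_mean_raw = model$train_mean_raw,
    trained = model$trained
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  de_mlp <- function(layers) {
    n <- if (is.data.frame(layers)) nrow(layers) else length(layers)
    lapply(seq_len(n), function(i) {
      l <- if (is.data.frame(layers)) lapply(layers, `[[`, i) else layers[[i]]
      list(W = matrix(unlist(l$W), unlist(l$dim)[1], unlist(l$dim)[2]),
           b = as.numeric(unlist(l$b)))
    })
  }
  h <- obj$hyper
  model <- dpinn_model(grid = as.numeric(h$grid), M = h$M, k = h$k,
                       hidden = h$hidden, s_min = h$s_min, s_max = h$s_max,
                       fixed_lambda_d = h$fixed_lambda_d, seed = 1L)
  model$par <- lapply(obj$par, de_mlp)
  if (!is.null(obj$stats)) {
    model$stats <- list(mode = obj$stats$mode,
                        center = as.numeric(obj$stats$center),
                        scale = as.numeric(obj$stats$scale))
  }
  if (!is.null(obj$train_mean_raw))
    model$train_mean_raw <- as.numeric(obj$train_mean_raw)
  model$trained <- isTRUE(obj$trained)
  model
}
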