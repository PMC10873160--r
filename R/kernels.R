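#' Shifted Rayleigh kernel
#'
#' Constructs the elementary building block of the estimated transduction-time
#' distribution: a Rayleigh density shifted to start at time `c`,
#' \deqn{K(t; c, s) = \frac{t - c}{s^2} \exp\left(-\frac{(t-c)^2}{2 s^2}\right),
#'   \quad t \ge c,}
#' and 0 for `t < c`.  The shift `c` places the kernel's support, the scale `s`
#' sets its width; the mode sits at `c + s`.  The Rayleigh family is used
#' because it vanishes at the shift (so mixtures are continuous densities with
#' nonnegative support) and its CDF is available in closed form, which lets the
#' physics residual be evaluated without numerical integration.
#'
#' @param c Shift parameter in time units, `c >= 0`.
#' @param s Scale parameter in time units, strictly positive.
#' @return An object of class `"rayleigh_kernel"`.
#' @examples
#' k <- rayleigh_kernel(c = 2, s = 1)
#' kernel_pdf(seq(0, 8, by = 0.5), k)
#' @export
rayleigh_kernel <- function(c, s) {
  stopifnot(length(c) == 1L, length(s) == 1L, is.finite(c), is.finite(s))
  if (s <= 0) stop("Rayleigh scale parameter 's' must be strictly positive")
  if (c < 0) stop("Rayleigh shift parameter 'c' must be nonnegative")
  structure(list(c = as.numeric(c), s = as.numeric(s)),
            class = "rayleigh_kernel")
}

#' @export
print.rayleigh_kernel <- function(x, ...) {
  cat(sprintf("Shifted Rayleigh kernel: shift c = %g, scale s = %g (mode at %g)\n",
              x$c, x$s, x$c + x$s))
  invisible(x)
}

#' Shifted Rayleigh density
#'
#' @param t Vector of evaluation times.
#' @param k A [rayleigh_kernel()].
#' @return Density values, one per element of `t`.
#' @export
kernel_pdf <- function(t, k) {
  stopifnot(inherits(k, "rayleigh_kernel"))
  u <- t - k$c
  out <- numeric(length(t))
  pos <- u >= 0
  out[pos] <- (u[pos] / k$s^2) * exp(-u[pos]^2 / (2 * k$s^2))
  out
}

#' Shifted Rayleigh distribution function
#'
#' Closed form \eqn{1 - \exp(-(t-c)^2 / (2 s^2))} on `t >= c`, 0 below the
#' shift.
#'
#' @inheritParams kernel_pdf
#' @return Probabilities in `[0, 1]`.
#' @export
kernel_cdf <- function(t, k) {
  stopifnot(inherits(k, "rayleigh_kernel"))
  u <- pmax(t - k$c, 0)
  -expm1(-u^2 / (2 * k$s^2))
}

#' Mixture of shifted Rayleigh kernels
#'
#' The estimated transduction-time distribution
#' \deqn{\tilde g(t) = \sum_{j=1}^M \omega_j K(t; c_j, s_j)}
#' with shifts `centers`, scales `scales`, and nonnegative `weights`.  Weights
#' are expected to sum to one (a warning is emitted otherwise and nothing is
#' renormalised; sub-probability mixtures are occasionally useful for
#' diagnostics).
#'
#' @param centers Ordered vector of M shifts (time units, nonnegative).
#' @param scales Vector of M scales (time units, strictly positive).
#' @param weights Vector of M nonnegative weights.
#' @return An object of class `"kernel_mixture"`.
#' @examples
#' m <- kernel_mixture(centers = c(1, 4), scales = c(0.5, 1), weights = c(0.3, 0.7))
#' mixture_moments(m)
#' @export
kernel_mixture <- function(centers, scales, weights) {
  centers <- as.numeric(centers); scales <- as.numeric(scales)
  weights <- as.numeric(weights)
  n <- length(centers)
  if (length(scales) != n || length(weights) != n)
    stop(sprintf("mismatched component lengths: centers %d, scales %d, weights %d",
                 n, length(scales), length(weights)))
  if (n < 1L) stop("a kernel mixture needs at least one component")
  if (any(!is.finite(centers)) || any(!is.finite(scales)) || any(!is.finite(weights)))
    stop("non-finite mixture parameters")
  if (any(scales <= 0)) stop("all mixture scales must be strictly positive")
  if (any(centers < 0)) stop("all mixture centers must be nonnegative")
  if (any(weights < 0)) stop("all mixture weights must be nonnegative")
  if (is.unsorted(centers)) {
    o <- order(centers)
    centers <- centers[o]; scales <- scales[o]; weights <- weights[o]
  }
  if (abs(sum(weights) - 1) > 1e-6)
    warning(sprintf("mixture weights sum to %.8g, not 1", sum(weights)))
  structure(list(centers = centers, scales = scales, weights = weights),
            class = "kernel_mixture")
}

#' @export
print.kernel_mixture <- function(x, ...) {
  cat(sprintf("Rayleigh kernel mixture with %d component(s)\n", length(x$centers)))
  mom <- mixture_moments(x)
  cat(sprintf("  mean %.4g, sd %.4g, cv %.4g; weight mass %.6g\n",
              mom$mean, sqrt(mom$variance), mom$cv, sum(x$weights)))
  invisible(x)
}

#' Mixture density
#' @param t Vector of evaluation times.
#' @param m A [kernel_mixture()].
#' @return Density values \eqn{\sum_j \omega_j K(t; c_j, s_j)}.
#' @export
mixture_pdf <- function(t, m) {
  stopifnot(inherits(m, "kernel_mixture"))
  out <- numeric(length(t))
  for (j in seq_along(m$centers)) {
    u <- t - m$centers[j]
    pos <- u >= 0
    out[pos] <- out[pos] +
      m$weights[j] * (u[pos] / m$scales[j]^2) * exp(-u[pos]^2 / (2 * m$scales[j]^2))
  }
  out
}

#' Mixture distribution function
#' @inheritParams mixture_pdf
#' @return \eqn{\sum_j \omega_j F(t; c_j, s_j)} where F is the kernel CDF.
#' @export
mixture_cdf <- function(t, m) {
  stopifnot(inherits(m, "kernel_mixture"))
  out <- numeric(length(t))
  for (j in seq_along(m$centers)) {
    u <- pmax(t - m$centers[j], 0)
    out <- out - m$weights[j] * expm1(-u^2 / (2 * m$scales[j]^2))
  }
  out
}

#' Moments of a Rayleigh kernel mixture
#'
#' Closed forms from the shifted Rayleigh moments
#' \eqn{E[T_j] = c_j + s_j \sqrt{\pi/2}} and
#' \eqn{E[T_j^2] = c_j^2 + 2 c_j s_j \sqrt{\pi/2} + 2 s_j^2}.
#'
#' @param m A [kernel_mixture()].
#' @return List with `mean`, `variance`, and `cv` (sd/mean).
#' @export
mixture_moments <- function(m) {
  stopifnot(inherits(m, "kernel_mixture"))
  w <- m$weights / sum(m$weights)
  hp <- sqrt(pi / 2)
  m1j <- m$centers + m$scales * hp
  m2j <- m$centers^2 + 2 * m$centers * m$scales * hp + 2 * m$scales^2
  mu <- sum(w * m1j)
  v <- sum(w * m2j) - mu^2
  v <- max(v, 0)
  if (mu == 0) stop("mixture mean is zero; CV undefined")
  list(mean = mu, variance = v, cv = sqrt(v) / mu)
}

#' Sample delays from a Rayleigh kernel mixture
#'
#' Draws the component with probability \eqn{\omega_j}, then inverts the
#' kernel CDF: \eqn{\tau = c_j + s_j \sqrt{-2 \log(1 - u)}}.
#'
#' @param m A [kernel_mixture()].
#' @param n Number of draws, `n >= 1`.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @return Numeric vector of `n` nonnegative delay draws.
#' @export
sample_mixture <- function(m, n, seed = NULL) {
  stopifnot(inherits(m, "kernel_mixture"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  w <- m$weights / sum(m$weights)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  u <- stats::runif(n)
  m$centers[comp] + m$scales[comp] * sqrt(-2 * log1p(-u))
}

#' Serialize / deserialize a kernel mixture as JSON
#'
#' The JSON layout is `{"centers": [...], "scales": [...], "weights": [...]}`.
#'
#' @param m A [kernel_mixture()].
#' @param path Optional file path; when `NULL`, the JSON string is returned.
#' @return `mixture_to_json()` returns the JSON string (invisibly when written
#'   to a file); `mixture_from_json()` returns a [kernel_mixture()].
#' @export
mixture_to_json <- function(m, path = NULL) {
  stopifnot(inherits(m, "kernel_mixture"))
  js <- jsonlite::toJSON(list(centers = m$centers, scales = m$scales,
                              weights = m$weights),
                         digits = NA, auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname mixture_to_json
#' @param json A JSON string or path to a JSON file.
#' @export
mixture_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  kernel_mixture(x$centers, x$scales, x$weights)
}

#' Export mixture pdf/cdf on a grid as a two-column data frame
#'
#' @param m A [kernel_mixture()].
#' @param grid Evaluation times.
#' @param what `"pdf"` or `"cdf"`.
#' @param path Optional CSV path to write `(t, value)`.
#' @return Data frame with columns `t` and `value` (invisibly when written).
#' @export
mixture_export <- function(m, grid, what = c("pdf", "cdf"), path = NULL) {
  what <- match.arg(what)
  val <- if (what == "pdf") mixture_pdf(grid, m) else mixture_cdf(grid, m)
  df <- data.frame(t = grid, value = val)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
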