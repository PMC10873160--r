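# Minimal dense-network machinery with manual backpropagation.
# Networks here are small (widths <= 64), so plain R matrix algebra is fast
# enough; the expensive kernel computations live in src/loss.cpp.

dense_init <- function(n_in, n_out) {
  a <- sqrt(6 / (n_in + n_out))           # Glorot uniform
  list(W = matrix(stats::runif(n_out * n_in, -a, a), n_out, n_in),
       b = numeric(n_out))
}

# sizes: c(in, h1, ..., out); tanh on hidden layers, linear output
mlp_init <- function(sizes) {
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers)) layers[[i]] <- dense_init(sizes[i], sizes[i + 1L])
  layers
}

mlp_forward <- function(layers, X) {
  L <- length(layers)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (i in seq_len(L)) {
    Z <- tcrossprod(acts[[i]], layers[[i]]$W)
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    acts[[i + 1L]] <- if (i < L) tanh(Z) else Z
  }
  list(out = acts[[L + 1L]], acts = acts)
}

# dOut: gradient wrt output (N x out); returns parameter grads + input grad
mlp_backward <- function(layers, acts, dOut) {
  L <- length(layers)
  grads <- vector("list", L)
  dZ <- dOut
  for (i in rev(seq_len(L))) {
    # acts[[i+1]] is post-activation; hidden layers used tanh
    if (i < L) dZ <- dZ * (1 - acts[[i + 1L]]^2)
    grads[[i]] <- list(W = crossprod(dZ, acts[[i]]), b = colSums(dZ))
    dZ <- dZ %*% layers[[i]]$W
  }
  list(grads = grads, dX = dZ)
}

softmax_rows <- function(A) {
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  E / rowSums(E)
}

# gradient through row-wise softmax: dA = P * (dP - rowSums(dP * P))
softmax_backward <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}

softplus <- function(a) ifelse(a > 30, a, log1p(exp(pmin(a, 30))))
softplus_grad <- function(a) 1 / (1 + exp(-a))
sigmoid <- function(a) 1 / (1 + exp(-a))

# ---- Adam over nested parameter lists ------------------------------------

nested_zeros <- function(par) rapply(par, function(x) x * 0, how = "replace")

adam_init <- function(par) list(m = nested_zeros(par), v = nested_zeros(par), t = 0L)

adam_step <- function(par, grad, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p) && !is.null(names(p)) && all(c("W", "b") %in% names(p))) {
      rw <- upd(p$W, g$W, m$W, v$W); rb <- upd(p$b, g$b, m$b, v$b)
      list(p = list(W = rw$p, b = rb$p), m = list(W = rw$m, b = rb$m),
           v = list(W = rw$v, b = rb$v))
    } else if (is.list(p)) {
      res <- Map(walk, p, g, m, v)
      list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  res <- walk(par, grad, state$m, state$v)
  list(par = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

# elementwise sum of two nested grad structures
nested_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) Map(nested_add, a, b) else a + b
}
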