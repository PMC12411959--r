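# Shared neural-network primitives: Adam over nested parameter lists and
# batch normalisation with batch statistics at training time and running
# averages at inference time.

adam_init <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else x * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

bn_new <- function(ch) {
  list(gamma = rep(1, ch), beta = rep(0, ch),
       rmean = rep(0, ch), rvar = rep(1, ch))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Returns list(out, cache, bn): bn carries updated running stats in training.
bn_forward <- function(Z, bn, training) {
  if (training) {
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2
    bn$rmean <- (1 - BN_MOMENTUM) * bn$rmean + BN_MOMENTUM * mu
    bn$rvar <- (1 - BN_MOMENTUM) * bn$rvar + BN_MOMENTUM * va
  } else {
    mu <- bn$rmean
    va <- bn$rvar
  }
  istd <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(Z, 2, mu, "-")
  xhat <- sweep(xhat, 2, istd, "*")
  out <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(out = out, cache = list(xhat = xhat, istd = istd), bn = bn)
}

# dY: gradient wrt bn output. Returns dZ plus parameter gradients.
bn_backward <- function(dY, cache, gamma, training) {
  xhat <- cache$xhat
  n <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  if (training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dZ <- sweep(sweep(n * dxhat, 2, s1, "-") -
                  sweep(xhat, 2, s2, "*"), 2, cache$istd / n, "*")
  } else {
    dZ <- sweep(dxhat, 2, cache$istd, "*")
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

n_params <- function(params) {
  if (is.list(params)) sum(vapply(params, n_params, numeric(1))) else
    length(params)
}
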