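# Rectified Adam with optional Lookahead wrapping.
#
# RAdam rectifies the adaptive learning rate in early steps, falling back
# to an SGD-with-momentum update while the variance estimate is untrusted
# (rho_t <= 4). Lookahead keeps a slow copy of the weights and, every k
# inner steps, interpolates slow <- slow + alpha (fast - slow) and resets
# the fast weights to it; k <= 1 disables the wrapper, leaving plain RAdam.

radam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      lookahead_k = 5L, lookahead_alpha = 0.5) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim(p)))
  st$v <- lapply(params, function(p) array(0, dim(p)))
  st$rho_inf <- 2 / (1 - beta2) - 1
  st$k <- as.integer(lookahead_k)
  st$alpha <- lookahead_alpha
  st$slow <- if (st$k > 1L) params else NULL
  st
}

radam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  t <- st$t
  b1 <- st$beta1; b2 <- st$beta2
  rho_t <- st$rho_inf - 2 * t * b2^t / (1 - b2^t)
  rect <- rho_t > 4
  r_t <- if (rect) {
    sqrt(((rho_t - 4) * (rho_t - 2) * st$rho_inf) /
           ((st$rho_inf - 4) * (st$rho_inf - 2) * rho_t))
  } else NA_real_
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / (1 - b1^t)
    params[[nm]] <- if (rect) {
      vhat <- sqrt(st$v[[nm]] / (1 - b2^t))
      params[[nm]] - st$lr * r_t * mhat / (vhat + st$eps)
    } else {
      params[[nm]] - st$lr * mhat
    }
  }
  if (!is.null(st$slow) && st$t %% st$k == 0L) {
    for (nm in names(params)) {
      st$slow[[nm]] <- st$slow[[nm]] + st$alpha * (params[[nm]] - st$slow[[nm]])
      params[[nm]] <- st$slow[[nm]]
    }
  }
  params
}
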