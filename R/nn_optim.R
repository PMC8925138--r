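# Rectified Adam (RAdam). Maintains first/second moment estimates per
# parameter leaf and rectifies the adaptive learning rate while the
# second-moment variance is intractable (early steps), falling back to an
# unadapted momentum update there.

#' Create a RAdam optimizer state
#'
#' @param params parameter tree (nested list of numeric arrays); only the
#'   shapes are used.
#' @param lr learning rate (default 1e-3).
#' @param beta1,beta2 exponential moment decay rates.
#' @param eps numerical floor added to the adaptive denominator.
#' @return An environment holding optimizer state.
#' @export
radam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr
  st$beta1 <- beta1
  st$beta2 <- beta2
  st$eps <- eps
  st$t <- 0L
  st$m <- map_params(params, function(x) x * 0)   # zeros, same shape class
  st$v <- map_params(params, function(x) x * 0)
  st$rho_inf <- 2 / (1 - beta2) - 1
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply one RAdam update
#'
#' @param st optimizer state from [radam_init()].
#' @param params current parameter tree.
#' @param grads gradient tree of identical shape.
#' @return Updated parameter tree.
#' @export
radam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  t <- st$t
  b1 <- st$beta1
  b2 <- st$beta2
  st$m <- map2_params(st$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  st$v <- map2_params(st$v, grads, function(v, g) b2 * v + (1 - b2) * g * g)
  rho_t <- st$rho_inf - 2 * t * b2^t / (1 - b2^t)
  bias1 <- 1 - b1^t
  if (rho_t > 5) {
    r_t <- sqrt(((rho_t - 4) * (rho_t - 2) * st$rho_inf) /
                ((st$rho_inf - 4) * (st$rho_inf - 2) * rho_t))
    bias2 <- sqrt(1 - b2^t)
    upd <- map2_params(st$m, st$v, function(m, v) {
      (m / bias1) / (sqrt(v) / bias2 + st$eps) * (st$lr * r_t)
    })
  } else {
    upd <- map_params(st$m, function(m) st$lr * m / bias1)
  }
  map2_params(params, upd, function(p, u) p - u)
}
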