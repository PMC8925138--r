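# Minimal neural-network primitives on base R matrices.
#
# A pairwise feature map over an L x L grid is stored as an N x ch matrix
# with N = c*c rows; row p corresponds to grid cell (i, j) via the
# column-major convention p = i + (j - 1) * c. 3x3 dilated convolutions are
# implemented as im2col gathers followed by one BLAS matmul; every layer has
# an explicit backward pass so the network trains without an autodiff
# framework.

IN_EPS <- 1e-5

# --- im2col index cache --------------------------------------------------
# For a c x c grid and dilation d, tap t in 1..9 has offsets
# (da, db) = (OFF[t, 1], OFF[t, 2]) * d, da varying fastest. Out-of-grid
# taps point at the dummy zero row 1 of the padded matrix (real rows are
# shifted by +1).
CONV_OFFSETS <- as.matrix(expand.grid(da = c(-1L, 0L, 1L), db = c(-1L, 0L, 1L)))

conv_index_cache <- new.env(parent = emptyenv())

conv_indices <- function(c, dilation) {
  key <- sprintf("c%d_d%d", c, dilation)
  if (!is.null(conv_index_cache[[key]])) return(conv_index_cache[[key]])
  ii <- rep(seq_len(c), times = c)
  jj <- rep(seq_len(c), each = c)
  idx <- matrix(1L, nrow = c * c, ncol = 9L)
  for (t in 1:9) {
    i2 <- ii + CONV_OFFSETS[t, 1L] * dilation
    j2 <- jj + CONV_OFFSETS[t, 2L] * dilation
    ok <- i2 >= 1L & i2 <= c & j2 >= 1L & j2 <= c
    idx[ok, t] <- i2[ok] + (j2[ok] - 1L) * c + 1L
  }
  conv_index_cache[[key]] <- idx
  idx
}

im2col <- function(x, c, dilation) {
  idx <- conv_indices(c, dilation)
  xpad <- rbind(0, x)
  cols <- vector("list", 9L)
  for (t in 1:9) cols[[t]] <- xpad[idx[, t], , drop = FALSE]
  do.call(cbind, cols)
}

# --- layers: forward returns list(out, cache) ----------------------------

linear_fwd <- function(x, w, b) {
  out <- x %*% w
  out <- sweep(out, 2L, b, "+")
  list(out = out, cache = list(x = x, w = w))
}

linear_bwd <- function(dout, cache) {
  list(dx = dout %*% t(cache$w),
       dw = crossprod(cache$x, dout),
       db = colSums(dout))
}

conv3x3_fwd <- function(x, w, b, c, dilation) {
  col <- im2col(x, c, dilation)
  out <- sweep(col %*% w, 2L, b, "+")
  list(out = out, cache = list(x = x, w = w, c = c, dilation = dilation))
}

conv3x3_bwd <- function(dout, cache) {
  c <- cache$c
  ch_in <- ncol(cache$x)
  col <- im2col(cache$x, c, cache$dilation)   # recomputed, not stored
  dw <- crossprod(col, dout)
  dcol <- dout %*% t(cache$w)
  idx <- conv_indices(c, cache$dilation)
  dxpad <- matrix(0, nrow = c * c + 1L, ncol = ch_in)
  for (t in 1:9) {
    block <- dcol[, ((t - 1L) * ch_in + 1L):(t * ch_in), drop = FALSE]
    tap <- idx[, t]
    keep <- tap > 1L   # within a tap, in-grid targets are unique
    dxpad[tap[keep], ] <- dxpad[tap[keep], , drop = FALSE] +
      block[keep, , drop = FALSE]
  }
  list(dx = dxpad[-1L, , drop = FALSE], dw = dw, db = colSums(dout))
}

instnorm_fwd <- function(x, gamma, beta) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  var <- colMeans(xc * xc)
  inv_sd <- 1 / sqrt(var + IN_EPS)
  xhat <- sweep(xc, 2L, inv_sd, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma))
}

instnorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, cache$gamma, "*")
  n <- nrow(xhat)
  term <- sweep(dxhat, 2L, colMeans(dxhat), "-") -
    sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
  dx <- sweep(term, 2L, cache$inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_bwd <- function(dout, mask) dout * mask

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# --- parameter initialization -------------------------------------------

he_weight <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
         nrow = fan_in, ncol = fan_out)
}

# --- generic parameter-tree utilities ------------------------------------
# Parameters and their gradients share one nested-list shape with numeric
# leaves; these walkers apply a function leaf-wise.

map_params <- function(p, f) {
  if (is.list(p)) return(lapply(p, map_params, f = f))
  f(p)
}

map2_params <- function(a, b, f) {
  if (is.list(a)) {
    return(mapply(map2_params, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  }
  f(a, b)
}

sum_abs_params <- function(p) {
  tot <- 0
  walk <- function(q) {
    if (is.list(q)) lapply(q, walk) else tot <<- tot + sum(abs(q))
    invisible(NULL)
  }
  walk(p)
  tot
}

params_finite <- function(p) {
  ok <- TRUE
  walk <- function(q) {
    if (is.list(q)) lapply(q, walk) else if (any(!is.finite(q))) ok <<- FALSE
    invisible(NULL)
  }
  walk(p)
  ok
}
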