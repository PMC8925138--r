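# Pairwise feature construction: the query row's 768-dim features are
# reduced to 128 by a position-wise MLP, outer-concatenated to a
# c x c x 256 block, and concatenated with the 144 symmetrized row-attention
# maps, giving the c x c x 400 input of the geometry network.

ATTN_CHANNELS <- ATTN_LAYERS * ATTN_HEADS  # 144

# Position index helpers for the N = c*c row layout (i varies fastest).
grid_ii <- function(c) rep(seq_len(c), times = c)
grid_jj <- function(c) rep(seq_len(c), each = c)

#' Initialize the query-feature reduction MLP
#'
#' Three position-wise linear layers (768 -> sizes\[1\] -> sizes\[2\] ->
#' sizes\[3\], default 384/192/128) with ReLU between layers and none after
#' the last.
#'
#' @param sizes hidden/output sizes of the three layers.
#' @param in_dim input feature depth (default 768).
#' @return Parameter list, one `(w, b)` pair per layer.
#' @export
init_mlp <- function(sizes = c(384L, 192L, 128L), in_dim = EMBED_DIM) {
  dims <- c(in_dim, sizes)
  lapply(seq_along(sizes), function(i) {
    list(w = he_weight(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L]))
  })
}

mlp_fwd <- function(x, mlp) {
  caches <- vector("list", length(mlp))
  n <- length(mlp)
  for (i in seq_len(n)) {
    lin <- linear_fwd(x, mlp[[i]]$w, mlp[[i]]$b)
    if (i < n) {
      act <- relu_fwd(lin$out)
      caches[[i]] <- list(lin = lin$cache, mask = act$cache)
      x <- act$out
    } else {
      caches[[i]] <- list(lin = lin$cache, mask = NULL)
      x <- lin$out
    }
  }
  list(out = x, cache = caches)
}

mlp_bwd <- function(dout, caches) {
  n <- length(caches)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    if (!is.null(caches[[i]]$mask)) dout <- relu_bwd(dout, caches[[i]]$mask)
    bw <- linear_bwd(dout, caches[[i]]$lin)
    grads[[i]] <- list(w = bw$dw, b = bw$db)
    dout <- bw$dx
  }
  list(grads = grads, dx = dout)
}

#' Reduce query-row features to 128 dimensions
#'
#' Selects row 1 (the query) of the r x c x 768 feature tensor and applies
#' the position-wise reduction MLP.
#'
#' @param msa_features r x c x 768 array from an embedder.
#' @param mlp MLP parameters from [init_mlp()].
#' @return c x k matrix (k = last MLP size, default 128).
#' @export
reduce_query_features <- function(msa_features, mlp = NULL) {
  if (is.null(mlp)) mlp <- with_seed(1L, init_mlp())
  d <- dim(msa_features)
  if (length(d) != 3L) stop("msa_features must be a 3D array r x c x depth")
  if (d[3L] != nrow(mlp[[1L]]$w)) {
    stop(sprintf("feature depth %d does not match MLP input %d",
                 d[3L], nrow(mlp[[1L]]$w)))
  }
  q <- matrix(msa_features[1L, , ], nrow = d[2L], ncol = d[3L])
  mlp_fwd(q, mlp)$out
}

#' Outer-concatenate per-position features into a pair block
#'
#' `out[i, j, ] = c(q[i, ], q[j, ])`: depth doubles.
#'
#' @param q c x k matrix of per-position features.
#' @return c x c x 2k array.
#' @export
outer_concatenate <- function(q) {
  c <- nrow(q)
  k <- ncol(q)
  mat <- cbind(q[grid_ii(c), , drop = FALSE], q[grid_jj(c), , drop = FALSE])
  array(mat, dim = c(c, c, 2L * k))
}

#' Symmetrize stacked row-attention maps
#'
#' Each of the 12 x 12 attention maps M becomes M + t(M); maps are stacked
#' layer-major then head-minor into 144 channels.
#'
#' @param row_attentions 12 x 12 x c x c array.
#' @return c x c x 144 array, exactly symmetric in the two position axes.
#' @export
symmetrize_attentions <- function(row_attentions) {
  d <- dim(row_attentions)
  if (length(d) != 4L || d[1L] != ATTN_LAYERS || d[2L] != ATTN_HEADS ||
      d[3L] != d[4L]) {
    stop("row_attentions must be 12 x 12 x c x c")
  }
  c <- d[3L]
  out <- array(0, dim = c(c, c, ATTN_CHANNELS))
  for (l in seq_len(ATTN_LAYERS)) {
    for (h in seq_len(ATTN_HEADS)) {
      m <- matrix(row_attentions[l, h, , ], c, c)
      out[, , (l - 1L) * ATTN_HEADS + h] <- m + t(m)
    }
  }
  out
}

#' Build the pairwise feature map
#'
#' Concatenates the outer-concatenated reduced query features (channels
#' 1..2k, default 256) with the symmetrized attention maps (last 144
#' channels) into the c x c x 400 network input.
#'
#' @param e an `embedder_output`.
#' @param mlp reduction-MLP parameters ([init_mlp()]).
#' @return Object of class `pair_feature_map`: the c x c x depth array with
#'   attribute `attn_offset` marking where attention channels start.
#' @export
build_pair_features <- function(e, mlp) {
  q <- reduce_query_features(e$msa_features, mlp)
  qq <- outer_concatenate(q)
  at <- symmetrize_attentions(e$row_attentions)
  if (dim(qq)[1L] != dim(at)[1L]) {
    stop(sprintf("branch length mismatch: query block c=%d, attentions c=%d",
                 dim(qq)[1L], dim(at)[1L]))
  }
  c <- dim(qq)[1L]
  depth <- dim(qq)[3L] + ATTN_CHANNELS
  out <- array(0, dim = c(c, c, depth))
  out[, , seq_len(dim(qq)[3L])] <- qq
  out[, , (dim(qq)[3L] + 1L):depth] <- at
  if (anyNA(out) || any(!is.finite(out))) stop("pair features contain NaN/Inf")
  structure(out, attn_offset = dim(qq)[3L], class = "pair_feature_map")
}

# Internal differentiable version used by training: returns the feature
# matrix (N x depth) plus the MLP cache so gradients can flow back into the
# reduction MLP (never into the embedder, whose output is treated as data).
build_pair_features_grad <- function(e, mlp) {
  d <- dim(e$msa_features)
  c <- d[2L]
  q_in <- matrix(e$msa_features[1L, , ], nrow = c, ncol = d[3L])
  fw <- mlp_fwd(q_in, mlp)
  q <- fw$out
  k <- ncol(q)
  at <- symmetrize_attentions(e$row_attentions)
  mat <- cbind(q[grid_ii(c), , drop = FALSE],
               q[grid_jj(c), , drop = FALSE],
               matrix(at, nrow = c * c, ncol = ATTN_CHANNELS))
  list(mat = mat, c = c, k = k, mlp_cache = fw$cache, q_in = q_in)
}

# Backward: dmat is N x depth; returns MLP gradients.
pair_features_bwd <- function(dmat, ctx) {
  c <- ctx$c
  k <- ctx$k
  dq <- rowsum(dmat[, seq_len(k), drop = FALSE], group = grid_ii(c)) +
    rowsum(dmat[, (k + 1L):(2L * k), drop = FALSE], group = grid_jj(c))
  mlp_bwd(dq, ctx$mlp_cache)$grads
}
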