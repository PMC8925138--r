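# The trainable head network: three 1x1-conv reduction layers
# (256/128/64 kernels, each followed by instance norm + ReLU), a dilated
# residual trunk of 28 pre-activation blocks (dilations cycling 1, 2, 4;
# two 3x3 convs of 64 kernels per block), and four independent 1x1 heads
# predicting the binned geometries theta/phi/omega/d (25/13/25/37 classes).

HEAD_BINS_DEFAULT <- c(theta = 25L, phi = 13L, omega = 25L, dist = 37L)

#' Network configuration
#'
#' @param reduction_channels kernel counts of the three 1x1 reduction
#'   layers.
#' @param trunk_blocks number of residual blocks (default 28).
#' @param trunk_channels trunk width (default 64).
#' @param dilation_cycle dilation rates cycled across blocks.
#' @param head_bins named integer vector of output classes per geometry.
#' @param mlp_sizes layer sizes of the query-feature reduction MLP.
#' @param seed seed for parameter initialization.
#' @return A `net_config` list.
#' @export
net_config <- function(reduction_channels = c(256L, 128L, 64L),
                       trunk_blocks = 28L,
                       trunk_channels = 64L,
                       dilation_cycle = c(1L, 2L, 4L),
                       head_bins = HEAD_BINS_DEFAULT,
                       mlp_sizes = c(384L, 192L, 128L),
                       seed = 1L) {
  stopifnot(trunk_blocks >= 1L, length(reduction_channels) == 3L,
            all(head_bins >= 2L),
            identical(names(head_bins), names(HEAD_BINS_DEFAULT)))
  structure(list(reduction_channels = as.integer(reduction_channels),
                 trunk_blocks = as.integer(trunk_blocks),
                 trunk_channels = as.integer(trunk_channels),
                 dilation_cycle = as.integer(dilation_cycle),
                 head_bins = head_bins,
                 mlp_sizes = as.integer(mlp_sizes),
                 seed = as.integer(seed)),
            class = "net_config")
}

# Dilation of block k (1-based): cycle through the configured rates.
block_dilation <- function(cfg, k) {
  cfg$dilation_cycle[((k - 1L) %% length(cfg$dilation_cycle)) + 1L]
}

#' Initialize network parameters
#'
#' Seeded He-style initialization for all convolution and linear weights;
#' instance-norm scales start at 1 and shifts at 0. The parameter tree also
#' contains the query-feature reduction MLP, so one object carries
#' everything trainable.
#'
#' @param cfg a [net_config()].
#' @return Parameter tree (`mlp`, `reduce`, `trunk`, `heads`).
#' @export
init_network <- function(cfg = net_config()) {
  with_seed(cfg$seed, {
    mlp <- init_mlp(cfg$mlp_sizes)
    in_depth <- 2L * cfg$mlp_sizes[length(cfg$mlp_sizes)] + ATTN_CHANNELS
    dims <- c(in_depth, cfg$reduction_channels)
    reduce <- lapply(seq_len(3L), function(i) {
      list(w = he_weight(dims[i], dims[i + 1L]),
           b = numeric(dims[i + 1L]),
           gamma = rep(1, dims[i + 1L]),
           beta = numeric(dims[i + 1L]))
    })
    ch <- cfg$trunk_channels
    trunk <- lapply(seq_len(cfg$trunk_blocks), function(k) {
      list(gamma = rep(1, ch), beta = numeric(ch),
           w1 = he_weight(9L * ch, ch), b1 = numeric(ch),
           w2 = he_weight(9L * ch, ch), b2 = numeric(ch))
    })
    heads <- lapply(cfg$head_bins, function(nb) {
      list(w = he_weight(ch, nb), b = numeric(nb))
    })
    list(mlp = mlp, reduce = reduce, trunk = trunk, heads = heads)
  })
}

# Forward pass on the N x depth feature matrix. Returns logits (list of
# N x bins matrices) and, when grad = TRUE, the caches needed for backward.
net_forward_mat <- function(mat, params, cfg, c, grad = FALSE) {
  caches <- if (grad) list(reduce = vector("list", 3L),
                           trunk = vector("list", cfg$trunk_blocks))
  x <- mat
  for (i in seq_len(3L)) {
    p <- params$reduce[[i]]
    lin <- linear_fwd(x, p$w, p$b)
    nrm <- instnorm_fwd(lin$out, p$gamma, p$beta)
    act <- relu_fwd(nrm$out)
    if (grad) caches$reduce[[i]] <- list(lin = lin$cache, nrm = nrm$cache,
                                         mask = act$cache)
    x <- act$out
  }
  for (k in seq_len(cfg$trunk_blocks)) {
    p <- params$trunk[[k]]
    dil <- block_dilation(cfg, k)
    nrm <- instnorm_fwd(x, p$gamma, p$beta)
    a1 <- relu_fwd(nrm$out)
    c1 <- conv3x3_fwd(a1$out, p$w1, p$b1, c, dil)
    a2 <- relu_fwd(c1$out)
    c2 <- conv3x3_fwd(a2$out, p$w2, p$b2, c, dil)
    if (grad) caches$trunk[[k]] <- list(nrm = nrm$cache, m1 = a1$cache,
                                        c1 = c1$cache, m2 = a2$cache,
                                        c2 = c2$cache)
    x <- x + c2$out
  }
  logits <- lapply(names(params$heads), function(nm) {
    p <- params$heads[[nm]]
    sweep(x %*% p$w, 2L, p$b, "+")
  })
  names(logits) <- names(params$heads)
  if (grad) list(logits = logits, caches = caches, trunk_out = x)
  else list(logits = logits)
}

# Backward pass: dlogits is a named list of N x bins gradient matrices.
# Returns gradients for heads, trunk, reduction layers and (via dmat) the
# input feature matrix.
net_backward_mat <- function(dlogits, fw, params, cfg, c) {
  x_out <- fw$trunk_out
  gheads <- lapply(names(params$heads), function(nm) {
    list(w = crossprod(x_out, dlogits[[nm]]),
         b = colSums(dlogits[[nm]]))
  })
  names(gheads) <- names(params$heads)
  dx <- Reduce(`+`, lapply(names(params$heads), function(nm) {
    dlogits[[nm]] %*% t(params$heads[[nm]]$w)
  }))
  gtrunk <- vector("list", cfg$trunk_blocks)
  for (k in rev(seq_len(cfg$trunk_blocks))) {
    cache <- fw$caches$trunk[[k]]
    d2 <- conv3x3_bwd(dx, cache$c2)
    da2 <- relu_bwd(d2$dx, cache$m2)
    d1 <- conv3x3_bwd(da2, cache$c1)
    da1 <- relu_bwd(d1$dx, cache$m1)
    dn <- instnorm_bwd(da1, cache$nrm)
    gtrunk[[k]] <- list(gamma = dn$dgamma, beta = dn$dbeta,
                        w1 = d1$dw, b1 = d1$db, w2 = d2$dw, b2 = d2$db)
    dx <- dx + dn$dx   # skip connection
  }
  greduce <- vector("list", 3L)
  for (i in rev(seq_len(3L))) {
    cache <- fw$caches$reduce[[i]]
    da <- relu_bwd(dx, cache$mask)
    dn <- instnorm_bwd(da, cache$nrm)
    dl <- linear_bwd(dn$dx, cache$lin)
    greduce[[i]] <- list(w = dl$dw, b = dl$db,
                         gamma = dn$dgamma, beta = dn$dbeta)
    dx <- dl$dx
  }
  list(heads = gheads, trunk = gtrunk, reduce = greduce, dmat = dx)
}

#' Run the geometry network
#'
#' @param features a `pair_feature_map` (c x c x depth array).
#' @param params parameter tree from [init_network()].
#' @param cfg the matching [net_config()].
#' @return Object of class `geometry_logits`: list of c x c x bins arrays
#'   (`theta`, `phi`, `omega`, `dist`).
#' @export
forward_geometry <- function(features, params, cfg = net_config()) {
  d <- dim(features)
  expected <- 2L * cfg$mlp_sizes[length(cfg$mlp_sizes)] + ATTN_CHANNELS
  if (length(d) != 3L || d[3L] != expected) {
    stop(sprintf("pair features must be c x c x %d, got depth %s",
                 expected, if (length(d) == 3L) d[3L] else "?"))
  }
  c <- d[1L]
  mat <- matrix(features, nrow = c * c, ncol = d[3L])
  out <- net_forward_mat(mat, params, cfg, c)
  logits <- lapply(names(out$logits), function(nm) {
    array(out$logits[[nm]], dim = c(c, c, ncol(out$logits[[nm]])))
  })
  names(logits) <- names(out$logits)
  structure(logits, class = "geometry_logits")
}

#' Convert logits to per-pair posterior distributions
#'
#' Applies a per-pair softmax over bins. With `symmetrize = TRUE` (default)
#' the distance and omega posteriors — symmetric pair functions — are
#' averaged with their position-transpose; theta and phi are directional
#' and left asymmetric.
#'
#' @param logits a `geometry_logits`.
#' @param symmetrize average dist/omega with their transpose.
#' @return Object of class `geometry_posteriors` with the same shapes.
#' @export
logits_to_posteriors <- function(logits, symmetrize = TRUE) {
  post <- lapply(names(logits), function(nm) {
    a <- logits[[nm]]
    d <- dim(a)
    p <- softmax_rows(matrix(a, nrow = d[1L] * d[2L], ncol = d[3L]))
    p <- array(p, dim = d)
    if (symmetrize && nm %in% c("dist", "omega")) {
      p <- (p + aperm(p, c(2L, 1L, 3L))) / 2
    }
    p
  })
  names(post) <- names(logits)
  structure(post, class = "geometry_posteriors")
}

#' Validate a posterior object
#'
#' @param post a `geometry_posteriors`.
#' @param tol normalization tolerance per pair.
#' @return `post`, invisibly.
#' @export
validate_posteriors <- function(post, tol = 1e-5) {
  for (nm in names(post)) {
    a <- post[[nm]]
    if (anyNA(a) || any(!is.finite(a)) || any(a < 0)) {
      stop(sprintf("%s posterior has invalid entries", nm))
    }
    sums <- apply(a, c(1L, 2L), sum)
    if (any(abs(sums - 1) > tol)) {
      stop(sprintf("%s posterior rows deviate from sum 1 by more than %g",
                   nm, tol))
    }
  }
  invisible(post)
}
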