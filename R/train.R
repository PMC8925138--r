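# Training of the geometry head network. The embedder is frozen — its
# output is treated as data — while the reduction MLP, the 1x1 reduction
# convs, the residual trunk and the four heads receive gradients. Batches
# are assembled by gradient accumulation over single examples, since
# variable sequence lengths preclude padding-free batching.

#' Training configuration
#'
#' @param learning_rate RAdam learning rate (default 1e-3).
#' @param effective_batch number of examples accumulated per optimizer step
#'   (default 16).
#' @param epochs passes over the dataset (ignored when `steps` is given).
#' @param steps optional total number of accumulation micro-steps; overrides
#'   `epochs`.
#' @param max_length proteins longer than this are skipped (default 1023).
#' @param seed master seed for shuffling and per-step subsampling.
#' @param subsample a [subsample_config()] used for training-time row
#'   subsampling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, effective_batch = 16L,
                         epochs = 1L, steps = NULL, max_length = 1023L,
                         seed = 1L, subsample = subsample_config()) {
  stopifnot(effective_batch >= 1L, max_length >= 2L, learning_rate >= 0)
  structure(list(learning_rate = learning_rate,
                 effective_batch = as.integer(effective_batch),
                 epochs = as.integer(epochs),
                 steps = if (!is.null(steps)) as.integer(steps),
                 max_length = as.integer(max_length),
                 seed = as.integer(seed),
                 subsample = subsample),
            class = "train_config")
}

# Internal cross-entropy on N x bins logit matrices. labels: named list of
# L x L integer matrices (0-based bins). Returns loss, per-objective
# breakdown and (optionally) logit gradients. The diagonal is excluded;
# no-contact pairs (label 0) are ordinary classification targets.
geometry_loss_mat <- function(logits, labels, c, grad = FALSE) {
  mask <- grid_ii(c) != grid_jj(c)
  nmask <- sum(mask)
  breakdown <- numeric(length(logits))
  names(breakdown) <- names(logits)
  dlogits <- if (grad) vector("list", length(logits))
  if (grad) names(dlogits) <- names(logits)
  for (nm in names(logits)) {
    lg <- logits[[nm]]
    lab <- as.vector(labels[[nm]]) + 1L
    p <- softmax_rows(lg)
    sel <- p[cbind(seq_len(nrow(p)), lab)]
    breakdown[[nm]] <- -sum(log(pmax(sel[mask], 1e-12))) / nmask
    if (grad) {
      d <- p
      d[cbind(seq_len(nrow(p)), lab)] <- d[cbind(seq_len(nrow(p)), lab)] - 1
      d[!mask, ] <- 0
      dlogits[[nm]] <- d / nmask
    }
  }
  list(loss = sum(breakdown), breakdown = breakdown, dlogits = dlogits)
}

#' Categorical cross-entropy over the four geometry objectives
#'
#' Equal-weight sum of the per-objective cross-entropies, each averaged
#' over off-diagonal pairs. No-contact pairs are trained as class 0.
#'
#' @param logits a `geometry_logits` (c x c x bins arrays).
#' @param labels a `geometry_labels` with matching length.
#' @return List with `loss` (scalar total) and `breakdown` (named
#'   per-objective means).
#' @export
geometry_loss <- function(logits, labels) {
  c <- dim(logits$dist)[1L]
  if (labels$L != c) {
    stop(sprintf("label length %d does not match logits length %d",
                 labels$L, c))
  }
  mats <- lapply(logits, function(a) matrix(a, nrow = c * c, ncol = dim(a)[3L]))
  out <- geometry_loss_mat(mats, labels, c, grad = FALSE)
  out[c("loss", "breakdown")]
}

zero_like <- function(params) map_params(params, function(x) x * 0)

# One forward/backward on a single training example. Returns loss pieces
# and the full parameter-gradient tree.
train_micro_step <- function(msa, labels, params, net_cfg, tcfg, embedder,
                             step_seed) {
  scfg <- tcfg$subsample
  scfg$seed <- step_seed
  sub <- subsample_training(msa, scfg)
  e <- embed_msa(tokenize(sub), embedder = embedder, seed = tcfg$seed)
  ctx <- build_pair_features_grad(e, params$mlp)
  fw <- net_forward_mat(ctx$mat, params, net_cfg, ctx$c, grad = TRUE)
  ls <- geometry_loss_mat(fw$logits, labels, ctx$c, grad = TRUE)
  bw <- net_backward_mat(ls$dlogits, fw, params, net_cfg, ctx$c)
  gmlp <- pair_features_bwd(bw$dmat[, seq_len(2L * ctx$k), drop = FALSE], ctx)
  list(loss = ls$loss, breakdown = ls$breakdown,
       grads = list(mlp = gmlp, reduce = bw$reduce, trunk = bw$trunk,
                    heads = bw$heads))
}

#' Train the geometry network
#'
#' Runs seeded accumulation training: per micro-step one example is
#' subsampled, embedded (frozen embedder), featurized and pushed through
#' the network; gradients are accumulated over `effective_batch` examples
#' before each RAdam update. Examples longer than `max_length` are skipped
#' with a warning.
#'
#' @param dataset list of examples, each `list(msa = <msa>, labels =
#'   <geometry_labels>)` with `labels$L == msa$c`.
#' @param net_cfg a [net_config()].
#' @param tcfg a [train_config()].
#' @param embedder registered embedder name.
#' @return An object of class `msageom_model`.
#' @export
train_geometry_model <- function(dataset, net_cfg = net_config(),
                                 tcfg = train_config(), embedder = "stub") {
  if (length(dataset) == 0L) stop("empty training dataset")
  keep <- vapply(dataset, function(ex) ex$msa$c <= tcfg$max_length, logical(1))
  if (!all(keep)) {
    warning(sprintf("skipping %d example(s) longer than %d residues",
                    sum(!keep), tcfg$max_length))
    dataset <- dataset[keep]
  }
  if (length(dataset) == 0L) stop("no examples within max_length")
  for (ex in dataset) {
    if (ex$labels$L != ex$msa$c) {
      stop("label length must match query length for every example")
    }
  }
  n <- length(dataset)
  total_steps <- tcfg$steps %||% (tcfg$epochs * n)

  params <- init_network(net_cfg)
  opt <- radam_init(params, lr = tcfg$learning_rate)
  acc <- zero_like(params)
  acc_n <- 0L
  step_loss <- numeric(total_steps)
  step_breakdown <- matrix(0, nrow = total_steps, ncol = 4L,
                           dimnames = list(NULL, names(HEAD_BINS_DEFAULT)))
  order <- integer(0)
  epoch <- 0L
  for (k in seq_len(total_steps)) {
    if (length(order) == 0L) {
      epoch <- epoch + 1L
      order <- with_seed(tcfg$seed + epoch, sample(n))
    }
    ex <- dataset[[order[1L]]]
    order <- order[-1L]
    ms <- train_micro_step(ex$msa, ex$labels, params, net_cfg, tcfg,
                           embedder, step_seed = tcfg$seed + 7919L * k)
    step_loss[k] <- ms$loss
    step_breakdown[k, names(ms$breakdown)] <- ms$breakdown
    acc <- map2_params(acc, ms$grads, `+`)
    acc_n <- acc_n + 1L
    if (acc_n == tcfg$effective_batch || k == total_steps) {
      grads <- map_params(acc, function(g) g / acc_n)
      params <- radam_step(opt, params, grads)
      if (!params_finite(params)) stop("non-finite parameters after update")
      acc <- zero_like(params)
      acc_n <- 0L
    }
  }
  steps_per_epoch <- n
  epoch_id <- ((seq_len(total_steps) - 1L) %/% steps_per_epoch) + 1L
  history <- list(step_loss = step_loss,
                  step_breakdown = step_breakdown,
                  epoch_loss = as.numeric(tapply(step_loss, epoch_id, mean)))
  structure(list(params = params, net_config = net_cfg, train_config = tcfg,
                 embedder = embedder, history = history,
                 version = as.character(utils::packageVersion("msageom"))),
            class = "msageom_model")
}

#' @export
print.msageom_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("msageom geometry model (%d residual blocks, %d channels)\n",
              x$net_config$trunk_blocks, x$net_config$trunk_channels))
  cat(sprintf("  embedder: %s\n", x$embedder))
  if (length(h$step_loss) > 0L) {
    cat(sprintf("  trained %d steps; loss %.3f -> %.3f\n",
                length(h$step_loss), h$step_loss[1L],
                h$step_loss[length(h$step_loss)]))
  }
  invisible(x)
}

#' @export
summary.msageom_model <- function(object, ...) {
  n_par <- 0
  walk <- function(q) {
    if (is.list(q)) lapply(q, walk) else n_par <<- n_par + length(q)
    invisible(NULL)
  }
  walk(object$params)
  h <- object$history
  out <- list(
    trunk_blocks = object$net_config$trunk_blocks,
    trunk_channels = object$net_config$trunk_channels,
    head_bins = object$net_config$head_bins,
    n_parameters = n_par,
    steps = length(h$step_loss),
    initial_loss = if (length(h$step_loss)) h$step_loss[1L] else NA_real_,
    final_loss = if (length(h$step_loss)) {
      h$step_loss[length(h$step_loss)]
    } else NA_real_,
    embedder = object$embedder)
  class(out) <- "summary.msageom_model"
  out
}

#' @export
print.summary.msageom_model <- function(x, ...) {
  cat("msageom geometry model\n")
  cat(sprintf("  trunk: %d blocks x %d channels; heads: %s\n",
              x$trunk_blocks, x$trunk_channels,
              paste(sprintf("%s=%d", names(x$head_bins), x$head_bins),
                    collapse = ", ")))
  cat(sprintf("  parameters: %d\n", x$n_parameters))
  cat(sprintf("  training: %d steps, loss %.4f -> %.4f (embedder: %s)\n",
              x$steps, x$initial_loss, x$final_loss, x$embedder))
  invisible(x)
}

#' @export
coef.msageom_model <- function(object, ...) object$params

#' Plot the training loss history
#'
#' @param x a `msageom_model`.
#' @param ... passed to [plot()].
#' @export
plot.msageom_model <- function(x, ...) {
  loss <- x$history$step_loss
  graphics::plot(seq_along(loss), loss, type = "l",
                 xlab = "accumulation step", ylab = "training loss",
                 main = "msageom training loss", ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a versioned container holding the configuration,
#' parameters and training history; readers reject unknown major format
#' versions.
#'
#' @param model a `msageom_model`.
#' @param path file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "msageom_model"))
  saveRDS(list(format = CHECKPOINT_FORMAT, model = model), path)
  invisible(path)
}

CHECKPOINT_FORMAT <- "msageom-checkpoint/1"

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  obj <- readRDS(path)
  fmt <- obj$format %||% ""
  major <- sub("/.*$", "", fmt)
  if (major != sub("/.*$", "", CHECKPOINT_FORMAT)) {
    stop(sprintf("unknown checkpoint format '%s'", fmt))
  }
  obj$model
}
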