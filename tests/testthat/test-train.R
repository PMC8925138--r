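test_that("cross-entropy loss hits its closed-form anchors", {
  ex <- msageom:::synthetic_example(L = 10L, r = 4L,
                                    architecture = "ideal_helix", seed = 6L)
  lab <- ex$labels
  bins <- c(theta = 25L, phi = 13L, omega = 25L, dist = 37L)

  # probability ~1 on every true bin -> loss ~0
  perfect <- lapply(names(bins), function(nm) {
    a <- array(0, dim = c(10L, 10L, bins[[nm]]))
    for (i in 1:10) for (j in 1:10) a[i, j, lab[[nm]][i, j] + 1L] <- 50
    a
  })
  names(perfect) <- names(bins)
  perfect <- structure(perfect, class = "geometry_logits")
  out <- geometry_loss(perfect, lab)
  expect_lt(out$loss, 1e-8)

  # uniform logits -> per-objective CE is log(bins)
  uniform <- lapply(bins, function(nb) array(0, dim = c(10L, 10L, nb)))
  uniform <- structure(uniform, class = "geometry_logits")
  u <- geometry_loss(uniform, lab)
  expect_equal(u$breakdown[["dist"]], log(37), tolerance = 1e-6 / log(37))
  expect_equal(u$breakdown[["phi"]], log(13), tolerance = 1e-9)
  expect_equal(u$loss, log(37) + log(13) + 2 * log(25), tolerance = 1e-9)

  # scaling one objective's logits moves only its own term
  mixed <- uniform
  mixed$dist <- perfect$dist
  m <- geometry_loss(mixed, lab)
  expect_lt(m$breakdown[["dist"]], 1e-8)
  expect_equal(m$breakdown[["omega"]], u$breakdown[["omega"]])
  expect_equal(m$breakdown[["theta"]], u$breakdown[["theta"]])
  expect_equal(m$breakdown[["phi"]], u$breakdown[["phi"]])

  expect_error(geometry_loss(uniform, random_labels(9L, 1L)), "match")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_net_config()
  ex <- msageom:::synthetic_example(L = 5L, r = 4L,
                                    architecture = "ideal_helix", seed = 2L)
  e <- embed_msa(tokenize(ex$msa), seed = 5L)
  params <- init_network(cfg)
  loss_of <- function(p) {
    ctx <- msageom:::build_pair_features_grad(e, p$mlp)
    fw <- msageom:::net_forward_mat(ctx$mat, p, cfg, ctx$c, grad = TRUE)
    msageom:::geometry_loss_mat(fw$logits, ex$labels, ctx$c, grad = FALSE)$loss
  }
  ctx <- msageom:::build_pair_features_grad(e, params$mlp)
  fw <- msageom:::net_forward_mat(ctx$mat, params, cfg, ctx$c, grad = TRUE)
  ls <- msageom:::geometry_loss_mat(fw$logits, ex$labels, ctx$c, grad = TRUE)
  bw <- msageom:::net_backward_mat(ls$dlogits, fw, params, cfg, ctx$c)
  gmlp <- msageom:::pair_features_bwd(
    bw$dmat[, seq_len(2L * ctx$k), drop = FALSE], ctx)
  grads <- list(mlp = gmlp, reduce = bw$reduce, trunk = bw$trunk,
                heads = bw$heads)
  set.seed(77)
  eps <- 1e-5
  paths <- list(list("mlp", 1L, "w"), list("mlp", 3L, "b"),
                list("reduce", 1L, "w"), list("reduce", 2L, "gamma"),
                list("trunk", 1L, "w1"), list("trunk", 2L, "w2"),
                list("trunk", 2L, "beta"), list("heads", "dist", "w"),
                list("heads", "theta", "b"))
  for (lp in paths) {
    arr <- params[[lp[[1]]]][[lp[[2]]]][[lp[[3]]]]
    ga <- grads[[lp[[1]]]][[lp[[2]]]][[lp[[3]]]]
    for (rep in 1:2) {
      i <- sample(length(arr), 1L)
      p2 <- params
      p2[[lp[[1]]]][[lp[[2]]]][[lp[[3]]]][i] <- arr[i] + eps
      up <- loss_of(p2)
      p2[[lp[[1]]]][[lp[[2]]]][[lp[[3]]]][i] <- arr[i] - eps
      dn <- loss_of(p2)
      num <- (up - dn) / (2 * eps)
      expect_equal(ga[i], num, tolerance = 1e-4,
                   label = paste(unlist(lp), collapse = "/"))
    }
  }
})

test_that("a zero learning rate leaves parameters untouched", {
  cfg <- tiny_net_config()
  ds <- tiny_dataset(L = 8L)
  before <- init_network(cfg)
  m <- train_geometry_model(ds, cfg,
                            train_config(learning_rate = 0,
                                         effective_batch = 2L, steps = 4L,
                                         seed = 1L))
  expect_equal(m$params, before, tolerance = 1e-15)
})

test_that("training is reproducible for a fixed seed", {
  cfg <- tiny_net_config()
  ds <- tiny_dataset(L = 8L)
  tc <- train_config(effective_batch = 2L, steps = 6L, seed = 4L)
  m1 <- train_geometry_model(ds, cfg, tc)
  m2 <- train_geometry_model(ds, cfg, tc)
  expect_identical(m1$history$step_loss, m2$history$step_loss)
  expect_equal(m1$params, m2$params, tolerance = 1e-15)
  expect_true(msageom:::params_finite(m1$params))
})

test_that("accumulated micro-steps equal one step on the mean gradient", {
  cfg <- tiny_net_config()
  ds <- tiny_dataset(L = 8L)
  tc <- train_config(effective_batch = 2L, steps = 2L, seed = 9L)
  m <- train_geometry_model(ds, cfg, tc)

  # replay: same init, same per-step subsample seeds, manual accumulation
  params <- init_network(cfg)
  order <- msageom:::with_seed(tc$seed + 1L, sample(2L))
  g <- NULL
  for (k in 1:2) {
    ex <- ds[[order[k]]]
    ms <- msageom:::train_micro_step(ex$msa, ex$labels, params, cfg, tc,
                                     "stub", step_seed = tc$seed + 7919L * k)
    g <- if (is.null(g)) ms$grads else msageom:::map2_params(g, ms$grads, `+`)
  }
  g <- msageom:::map_params(g, function(x) x / 2)
  opt <- radam_init(params, lr = tc$learning_rate)
  manual <- radam_step(opt, params, g)
  expect_equal(m$params, manual, tolerance = 1e-12)
})

test_that("training rejects bad datasets and skips oversized proteins", {
  cfg <- tiny_net_config()
  expect_error(train_geometry_model(list(), cfg), "empty")
  ds <- tiny_dataset(L = 8L)
  ds_bad <- ds
  ds_bad[[1L]]$labels <- random_labels(9L, 1L)
  expect_error(train_geometry_model(ds_bad, cfg), "match")
  long_msa <- synthetic_msa(c = 30L, r = 3L, seed = 1L)
  ds_long <- list(list(msa = long_msa, labels = random_labels(30L, 2L)),
                  ds[[1L]])
  tc <- train_config(effective_batch = 1L, steps = 1L, max_length = 20L)
  expect_warning(m <- train_geometry_model(ds_long, cfg, tc), "skipping")
  expect_length(m$history$step_loss, 1L)
})

test_that("the loss trends down when overfitting a tiny fixture", {
  cfg <- tiny_net_config(blocks = 4L)
  ds <- tiny_dataset(L = 16L)
  m <- train_geometry_model(
    ds, cfg, train_config(effective_batch = 2L, steps = 120L, seed = 2L))
  h <- m$history$step_loss
  expect_lt(mean(tail(h, 6L)), 0.8 * mean(head(h, 6L)))
  # monotone trend over quarters of the run, allowing local noise
  q <- split(h, rep(1:4, each = 30L))
  expect_true(all(diff(vapply(q, mean, numeric(1))) < 0))
})

test_that("model object methods report the fit", {
  cfg <- tiny_net_config()
  ds <- tiny_dataset(L = 8L)
  m <- train_geometry_model(ds, cfg,
                            train_config(effective_batch = 2L, steps = 2L))
  expect_s3_class(m, "msageom_model")
  expect_output(print(m), "geometry model")
  s <- summary(m)
  expect_gt(s$n_parameters, 0)
  expect_output(print(s), "parameters")
  expect_identical(coef(m), m$params)
  ck <- tmp_file(".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_equal(m2$params, m$params)
  saveRDS(list(format = "other/9", model = m), ck)
  expect_error(load_checkpoint(ck), "unknown checkpoint format")
})
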