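# Two-pathway network: configuration contracts, prediction semantics,
# gradient correctness, parameter scaling, and trainability on a
# separable task.

test_that("configuration invariants are enforced", {
  expect_error(slowfast_config(clip_frames = 60), "divisible")
  expect_error(slowfast_config(alpha = 0), "alpha")
  expect_error(slowfast_config(beta = 0), "beta")
  expect_error(slowfast_config(dropout = 1), "dropout")
  cfg <- slowfast_config()
  expect_equal(cfg$tau, 8L)
  expect_equal(cfg$alpha, 8L)
  expect_equal(cfg$beta, 1 / 8)
  expect_equal(cfg$dropout, 0.5)
})

test_that("pathway frame counts and channel widths follow tau, alpha, beta", {
  cfg <- slowfast_config(clip_frames = 64)
  pf <- pathway_frames(cfg)
  expect_equal(pf$slow, 8)
  expect_equal(pf$fast, 64)
  expect_equal(pf$fast / pf$slow, 8)
  expect_equal(cfg$fast_widths, c(4L, 8L))   # beta * (32, 64)
  # a built model consumes exactly these frame counts
  m <- build_slowfast(slowfast_config(clip_frames = 16, dropout = 0),
                      seed = 1)
  x <- array(rnorm(50 * 50 * 16), dim = c(50, 50, 16, 1, 1))
  fw <- deformcyte:::slowfast_forward(m, x, training = FALSE)
  expect_equal(dim(fw$logits), c(2L, 1L))
})

test_that("fast pathway parameters scale as about beta squared", {
  m <- build_slowfast(slowfast_config(clip_frames = 16), seed = 2)
  np <- count_parameters(m)
  expect_gt(np$slow, np$fast)
  beta <- m$cfg$beta
  for (r in np$stage_ratio) expect_lt(r, 2 * beta^2)
})

test_that("prediction is normalized, deterministic, and shape-checked", {
  cfg <- slowfast_config(clip_frames = 16)
  m <- build_slowfast(cfg, seed = 3)
  clips <- list(blob_clip(6, 1), blob_clip(8, 2), blob_clip(6, 1))
  p <- predict(m, clips)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_identical(p, predict(m, clips))
  expect_equal(p[1, ], p[3, ])  # duplicated clip, identical scores
  m0 <- m
  m0$params$head$w[] <- 0
  m0$params$head$b[] <- 0
  expect_equal(unname(predict(m0, clips[1])), matrix(0.5, 1, 2))
  expect_error(predict(m, list(array(0L, c(50, 50, 8)))), "shape")
})

test_that("analytic gradients match finite differences", {
  cfg <- slowfast_config(tau = 4, alpha = 4, beta = 0.5, clip_frames = 8,
                         clip_size = 20, dropout = 0,
                         widths = c(4L, 6L), blocks = c(1L, 1L))
  m <- build_slowfast(cfg, seed = 3)
  # perturb the zero-initialized residual batch-norm gains so no ReLU sits
  # exactly on its kink (finite differences are ill-defined there)
  for (pw in c("slow", "fast")) {
    for (s in 1:2) {
      m$params[[pw]]$stages[[s]]$blocks[[1]]$conv2$bn$gamma[] <- 0.7
    }
  }
  set.seed(9)
  x <- array(rnorm(20 * 20 * 8 * 2), dim = c(20, 20, 8, 1, 2))
  y <- c(1L, 2L)
  fw <- deformcyte:::slowfast_forward(m, x, training = TRUE)
  sm <- deformcyte:::softmax_ce(fw$logits, y)
  gr <- deformcyte:::slowfast_backward(m, fw$cache, sm$dlogits)
  lossfun <- function(model) {
    deformcyte:::softmax_ce(
      deformcyte:::slowfast_forward(model, x, training = TRUE)$logits,
      y)$loss
  }
  modify <- function(tree, path, i, d) {
    if (length(path) == 0) {
      tree[i] <- tree[i] + d
      return(tree)
    }
    tree[[path[[1]]]] <- modify(tree[[path[[1]]]], path[-1], i, d)
    tree
  }
  paths <- list(
    list("head", "w"),
    list("slow", "stem", "conv", "w"),
    list("slow", "stages", 1L, "blocks", 1L, "conv1", "conv", "w"),
    list("slow", "stages", 2L, "trans", "bn", "gamma"),
    list("fast", "stages", 2L, "blocks", 1L, "conv2", "conv", "w"),
    list("lateral", 1L, "conv", "w"),
    list("lateral", 2L, "bn", "beta"),
    list("slow", "stages", 1L, "blocks", 1L, "proj", "conv", "w"))
  eps <- 1e-5
  for (path in paths) {
    i <- 3L
    mp <- m
    mp$params <- modify(m$params, path, i, eps)
    l1 <- lossfun(mp)
    mp$params <- modify(m$params, path, i, -eps)
    l2 <- lossfun(mp)
    g <- gr
    for (k in path) g <- g[[k]]
    expect_equal((l1 - l2) / (2 * eps), g[i], tolerance = 1e-3,
                 label = paste(unlist(path), collapse = "$"))
  }
})

test_that("tiny preset reaches 95% training accuracy on separable blobs", {
  # two classes of moving blobs differing 30% in size
  ds <- blob_dataset(10, radii = c(6, 7.8))
  cfg <- slowfast_config(clip_frames = 16)
  fit <- slowfast_fit(ds$clips, ds$labels, cfg,
                      hyper = list(lr = 0.05, max_epochs = 20,
                                   restart_period = 20, jitter_px = 0,
                                   jitter_frames = 0),
                      seed = 5)
  expect_lte(fit$epochs_run, 50)
  pred <- fit$classes[max.col(predict(fit, ds$clips), ties.method = "first")]
  expect_gte(mean(pred == ds$labels), 0.95)
})

test_that("training is seed-deterministic at epoch zero", {
  ds <- blob_dataset(3)
  cfg <- slowfast_config(clip_frames = 16)
  f1 <- slowfast_fit(ds$clips, ds$labels, cfg,
                     hyper = list(max_epochs = 1), seed = 9)
  f2 <- slowfast_fit(ds$clips, ds$labels, cfg,
                     hyper = list(max_epochs = 1), seed = 9)
  expect_identical(f1$initial_loss, f2$initial_loss)
  expect_identical(f1$history$loss, f2$history$loss)
})

test_that("validation history records only even epochs", {
  ds <- blob_dataset(4)
  cfg <- slowfast_config(clip_frames = 16)
  fit <- slowfast_fit(ds$clips[1:6], ds$labels[1:6], cfg,
                      val_clips = ds$clips[7:8], val_labels = ds$labels[7:8],
                      hyper = list(max_epochs = 6, patience = 100),
                      seed = 2)
  h <- fit$history
  expect_true(all(is.na(h$val_sensitivity[h$epoch %% 2 == 1])))
  expect_true(all(!is.na(h$val_sensitivity[h$epoch %% 2 == 0])))
})
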