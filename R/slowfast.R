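# Two-pathway spatiotemporal convolutional classifier.
#
# The slow pathway sees every tau-th frame of a clip and carries the bulk
# of the channel capacity (spatial structure); the fast pathway sees alpha
# times more frames at beta times the channel width (motion).  At the stem
# and after every stage but the last, fast features are mapped to the slow
# temporal resolution by a time-strided convolution producing 2*beta*C
# channels and concatenated into the slow pathway.  Both pathways are
# stacks of 3-D residual blocks (two 3x3x3 convolutions with batch norm,
# identity or 1x1x1-projection skip); global average pooling over
# space-time, concatenation of the two pathway features, dropout, and a
# linear softmax head produce the two class scores.

#' Configuration of the two-pathway network
#'
#' @param tau Temporal stride of the slow pathway (default 8: only every
#'   8th frame enters the slow path).
#' @param alpha Frame-rate ratio fast/slow (default 8: the fast pathway
#'   processes 8 frames per slow frame).
#' @param beta Channel-width ratio fast/slow (default 1/8).
#' @param depth Depth preset: `"tiny"` (2 stages of one residual block,
#'   slow widths 32 and 64 — the desk-scale variant) or `"50"`/`"101"`
#'   (4 stages at ResNet-50/101 block counts, two-convolution blocks).
#' @param dropout Dropout probability before the classification head
#'   (default 0.5).
#' @param n_classes Number of classes (default 2).
#' @param clip_frames Clip length T; must be divisible by `tau`.
#' @param clip_size Spatial clip side length (default 50).
#' @param widths,blocks Optional explicit slow-pathway stage widths and
#'   per-stage block counts, overriding the preset.
#' @return An object of class `slowfast_config`.
#' @export
slowfast_config <- function(tau = 8L, alpha = 8L, beta = 1 / 8,
                            depth = c("tiny", "50", "101"),
                            dropout = 0.5, n_classes = 2L,
                            clip_frames = 64L, clip_size = 50L,
                            widths = NULL, blocks = NULL) {
  depth <- match.arg(depth)
  if (alpha < 1 || alpha != round(alpha)) stop("alpha must be an integer >= 1")
  if (tau %% alpha != 0) stop("tau must be a multiple of alpha")
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (clip_frames %% tau != 0) {
    stop("clip_frames (", clip_frames, ") must be divisible by tau (", tau, ")")
  }
  if (is.null(widths)) {
    widths <- switch(depth, tiny = c(32L, 64L), c(64L, 128L, 256L, 512L))
  }
  if (is.null(blocks)) {
    blocks <- switch(depth,
                     tiny = c(1L, 1L),
                     "50" = c(3L, 4L, 6L, 3L),
                     "101" = c(3L, 4L, 23L, 3L))
  }
  stopifnot(length(widths) == length(blocks))
  structure(list(
    tau = as.integer(tau), alpha = as.integer(alpha), beta = beta,
    depth = depth, dropout = dropout, n_classes = as.integer(n_classes),
    clip_frames = as.integer(clip_frames), clip_size = as.integer(clip_size),
    widths = as.integer(widths), blocks = as.integer(blocks),
    fast_widths = pmax(1L, as.integer(round(beta * widths)))
  ), class = "slowfast_config")
}

#' Frame counts consumed by each pathway
#'
#' @param cfg A [slowfast_config()].
#' @return List with `slow` (= `clip_frames / tau`) and `fast`
#'   (= `clip_frames * alpha / tau`) frame counts.
#' @export
pathway_frames <- function(cfg) {
  list(slow = cfg$clip_frames %/% cfg$tau,
       fast = (cfg$clip_frames * cfg$alpha) %/% cfg$tau)
}

init_conv <- function(kh, kw, kt, cin, cout) {
  fan_in <- kh * kw * kt * cin
  list(w = array(rnorm(kh * kw * kt * cin * cout, 0, sqrt(2 / fan_in)),
                 dim = c(kh, kw, kt, cin, cout)),
       b = numeric(cout))
}

init_unit <- function(kh, kw, kt, cin, cout) {
  list(conv = init_conv(kh, kw, kt, cin, cout),
       bn = list(gamma = rep(1, cout), beta = numeric(cout)))
}

init_block <- function(cin, cout) {
  b <- list(conv1 = init_unit(3L, 3L, 3L, cin, cout),
            conv2 = init_unit(3L, 3L, 3L, cout, cout),
            proj = if (cin != cout) init_unit(1L, 1L, 1L, cin, cout) else NULL)
  # zero-init the residual branch's last batch-norm gain so every block
  # starts as (near-)identity; stabilizes early training
  b$conv2$bn$gamma[] <- 0
  b
}

# In-channel bookkeeping for a pathway: `lat_extra[s]` channels are
# concatenated before stage s (from the lateral connection), 0 for the fast
# pathway.
init_pathway <- function(widths, blocks, lat_extra) {
  n_stages <- length(widths)
  stages <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    cin <- if (s == 1) widths[1] + lat_extra[1] else widths[s - 1] + lat_extra[s]
    trans <- if (s > 1) init_unit(3L, 3L, 1L, cin, widths[s]) else NULL
    blist <- vector("list", blocks[s])
    bin <- if (s == 1) cin else widths[s]
    for (b in seq_len(blocks[s])) {
      blist[[b]] <- init_block(bin, widths[s])
      bin <- widths[s]
    }
    stages[[s]] <- list(trans = trans, blocks = blist)
  }
  list(stem = init_unit(5L, 5L, 1L, 1L, widths[1]), stages = stages)
}

#' Build a two-pathway model
#'
#' Initializes all weights (He-scaled Gaussian convolutions, unit-gain
#' batch norm, zero biases) under `seed`.
#'
#' @param cfg A [slowfast_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `slowfast_model`: list with `cfg`, `params`
#'   (nested list of arrays) and `bn` (environment of running statistics).
#' @export
build_slowfast <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "slowfast_config"))
  with_seed(seed, {
    ws <- cfg$widths
    wf <- cfg$fast_widths
    n_stages <- length(ws)
    # lateral k (k = 1 after stem, k = s+1 after stage s < n_stages) maps
    # fast width wf[k] to 2*wf[k] channels at slow temporal resolution
    lat_extra_slow <- c(2L * wf[1], 2L * wf[seq_len(n_stages - 1)])
    params <- list(
      slow = init_pathway(ws, cfg$blocks, lat_extra_slow),
      fast = init_pathway(wf, cfg$blocks, rep(0L, n_stages)),
      lateral = lapply(seq_len(n_stages), function(k) {
        # fusion point k taps the fast stem (k = 1) or fast stage k - 1
        inc <- if (k == 1) wf[1] else wf[k - 1]
        init_unit(1L, 1L, 5L, inc, 2L * inc)
      }),
      head = list(
        w = matrix(rnorm(cfg$n_classes * (ws[n_stages] + wf[n_stages]), 0,
                         sqrt(2 / (ws[n_stages] + wf[n_stages]))),
                   cfg$n_classes, ws[n_stages] + wf[n_stages]),
        b = numeric(cfg$n_classes)
      )
    )
    bn <- new.env(parent = emptyenv())
    register_bn_tree(params, "p", bn)
    structure(list(cfg = cfg, params = params, bn = bn),
              class = "slowfast_model")
  })
}

# Walk the parameter tree and create one running-stats slot per bn leaf,
# named by its path.
register_bn_tree <- function(params, prefix, env) {
  if (!is.list(params)) return(invisible())
  nms <- names(params)
  if (is.null(nms)) nms <- as.character(seq_along(params))
  for (k in seq_along(params)) {
    el <- params[[k]]
    if (is.null(el)) next
    nm <- if (nzchar(nms[k])) nms[k] else as.character(k)
    path <- paste0(prefix, ".", nm)
    if (identical(nm, "bn")) {
      env[[prefix]] <- list(rm = numeric(length(el$gamma)),
                            rv = rep(1, length(el$gamma)))
    } else if (is.list(el)) {
      register_bn_tree(el, path, env)
    }
  }
  invisible()
}

# conv + bn (+ relu) unit forward/backward ------------------------------

# conv -> batch norm (-> fused ReLU); compiled BN kernels
unit_f <- function(x, p, stride, name, env, training, act = TRUE) {
  cv <- conv_f(x, p$conv$w, p$conv$b, stride, keep_col = training)
  st <- env[[name]]
  bn <- .cpp_bn_forward(cv$y, dim(cv$y), p$bn$gamma, p$bn$beta,
                        st$rm, st$rv, training, 0.1, 1e-5, act)
  if (training) env[[name]] <- list(rm = bn$rm, rv = bn$rv)
  list(y = bn$y,
       cache = list(cv = cv$cache, y = bn$y, xhat = bn$xhat, inv = bn$inv,
                    gamma = p$bn$gamma, d = dim(bn$y), act = act))
}

unit_b <- function(cache, dy) {
  bb <- .cpp_bn_backward(dy, cache$y, cache$xhat, cache$inv, cache$gamma,
                         cache$d, TRUE, cache$act)
  cb <- conv_b(cache$cv, bb$dx)
  list(dx = cb$dx,
       g = list(conv = list(w = cb$dw, b = cb$db),
                bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

block_f <- function(x, p, name, env, training) {
  u1 <- unit_f(x, p$conv1, c(1L, 1L, 1L), paste0(name, ".conv1"), env,
               training, act = TRUE)
  u2 <- unit_f(u1$y, p$conv2, c(1L, 1L, 1L), paste0(name, ".conv2"), env,
               training, act = FALSE)
  if (!is.null(p$proj)) {
    sk <- unit_f(x, p$proj, c(1L, 1L, 1L), paste0(name, ".proj"), env,
                 training, act = FALSE)
    s <- sk$y
    skc <- sk$cache
  } else {
    s <- x
    skc <- NULL
  }
  rl <- relu_f(u2$y + s)
  list(y = rl$y, cache = list(u1 = u1$cache, u2 = u2$cache, sk = skc,
                              rl = rl$cache))
}

block_b <- function(cache, dy) {
  dsum <- relu_b(cache$rl, dy)
  b2 <- unit_b(cache$u2, dsum)
  b1 <- unit_b(cache$u1, b2$dx)
  if (!is.null(cache$sk)) {
    bs <- unit_b(cache$sk, dsum)
    dx <- b1$dx + bs$dx
    gproj <- bs$g
  } else {
    dx <- b1$dx + dsum
    gproj <- NULL
  }
  list(dx = dx, g = list(conv1 = b1$g, conv2 = b2$g, proj = gproj))
}

pathway_stem_f <- function(x, p, name, env, training) {
  st <- unit_f(x, p$stem, c(4L, 4L, 1L), paste0(name, ".stem"), env, training)
  pl <- avgpool2_f(st$y)
  list(y = pl$y, cache = list(stem = st$cache, pool = pl$cache))
}

pathway_stem_b <- function(cache, dy) {
  dpool <- avgpool2_b(cache$pool, dy)
  sb <- unit_b(cache$stem, dpool)
  list(dx = sb$dx, g = list(stem = sb$g))
}

stage_f <- function(x, p, name, env, training) {
  caches <- list()
  h <- x
  if (!is.null(p$trans)) {
    tr <- unit_f(h, p$trans, c(2L, 2L, 1L), paste0(name, ".trans"), env,
                 training)
    h <- tr$y
    caches$trans <- tr$cache
  }
  bc <- vector("list", length(p$blocks))
  for (b in seq_along(p$blocks)) {
    bf <- block_f(h, p$blocks[[b]], paste0(name, ".blocks.", b), env,
                  training)
    h <- bf$y
    bc[[b]] <- bf$cache
  }
  caches$blocks <- bc
  list(y = h, cache = caches)
}

stage_b <- function(p, cache, dy) {
  gb <- vector("list", length(p$blocks))
  for (b in rev(seq_along(p$blocks))) {
    bb <- block_b(cache$blocks[[b]], dy)
    dy <- bb$dx
    gb[[b]] <- bb$g
  }
  g <- list(blocks = gb)
  if (!is.null(p$trans)) {
    tb <- unit_b(cache$trans, dy)
    dy <- tb$dx
    g$trans <- tb$g
  } else {
    g["trans"] <- list(NULL)
  }
  list(dx = dy, g = g[c("trans", "blocks")])
}

# Full forward pass.  x: (H, W, T, 1, N) normalized clips.  Returns logits
# plus (in training mode) the caches needed for the backward pass.
slowfast_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  env <- model$bn
  p <- model$params
  TT <- dim(x)[3]
  if (TT %% cfg$tau != 0) stop("clip length not divisible by tau")
  fast_stride <- cfg$tau %/% cfg$alpha
  x_slow <- x[, , seq.int(1L, TT, by = cfg$tau), , , drop = FALSE]
  x_fast <- x[, , seq.int(1L, TT, by = fast_stride), , , drop = FALSE]
  n_stages <- length(cfg$widths)

  # fast pathway, keeping each fusion-point feature
  fstem <- pathway_stem_f(x_fast, p$fast, "p.fast", env, training)
  f_feats <- list(fstem$y)
  fstage_c <- vector("list", n_stages)
  h <- fstem$y
  for (s in seq_len(n_stages)) {
    sf <- stage_f(h, p$fast$stages[[s]], paste0("p.fast.stages.", s), env,
                  training)
    h <- sf$y
    fstage_c[[s]] <- sf$cache
    f_feats[[s + 1]] <- h
  }

  # lateral connections (time-strided conv to slow frame rate)
  lat <- vector("list", n_stages)
  lat_c <- vector("list", n_stages)
  for (k in seq_len(n_stages)) {
    lf <- unit_f(f_feats[[k]], p$lateral[[k]],
                 c(1L, 1L, cfg$alpha), paste0("p.lateral.", k), env, training)
    lat[[k]] <- lf$y
    lat_c[[k]] <- lf$cache
  }

  # slow pathway with fusion
  sstem <- pathway_stem_f(x_slow, p$slow, "p.slow", env, training)
  cc1 <- concat_f(sstem$y, lat[[1]])
  h <- cc1$y
  concat_c <- list(cc1$cache)
  sstage_c <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    sf <- stage_f(h, p$slow$stages[[s]], paste0("p.slow.stages.", s), env,
                  training)
    h <- sf$y
    sstage_c[[s]] <- sf$cache
    if (s < n_stages) {
      cc <- concat_f(h, lat[[s + 1]])
      h <- cc$y
      concat_c[[s + 1]] <- cc$cache
    }
  }

  gs <- gap_f(h)
  gf <- gap_f(f_feats[[n_stages + 1]])
  feat <- rbind(gs$y, gf$y)
  dr <- dropout_f(feat, cfg$dropout, training)
  lin <- linear_f(dr$y, p$head$w, p$head$b)

  cache <- if (training) {
    list(fstem = fstem$cache, fstage = fstage_c, lat = lat_c,
         sstem = sstem$cache, sstage = sstage_c, concat = concat_c,
         gs = gs$cache, gf = gf$cache, dr = dr$cache, lin = lin$cache,
         n_slow_feat = nrow(gs$y))
  } else NULL
  list(logits = lin$y, cache = cache)
}

slowfast_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  p <- model$params
  n_stages <- length(cfg$widths)

  lb <- linear_b(cache$lin, dlogits)
  dfeat <- dropout_b(cache$dr, lb$dx)
  Cs <- cache$n_slow_feat
  dgs <- dfeat[seq_len(Cs), , drop = FALSE]
  dgf <- dfeat[-seq_len(Cs), , drop = FALSE]

  # slow chain backward, collecting lateral gradients at each concat
  dy <- gap_b(cache$gs, dgs)
  dlat <- vector("list", n_stages)
  g_slow_stages <- vector("list", n_stages)
  for (s in rev(seq_len(n_stages))) {
    if (s < n_stages) {
      sp <- concat_b(cache$concat[[s + 1]], dy)
      dy <- sp$da
      dlat[[s + 1]] <- sp$db
    }
    sb <- stage_b(p$slow$stages[[s]], cache$sstage[[s]], dy)
    dy <- sb$dx
    g_slow_stages[[s]] <- sb$g
  }
  sp <- concat_b(cache$concat[[1]], dy)
  dlat[[1]] <- sp$db
  ssb <- pathway_stem_b(cache$sstem, sp$da)
  g_slow <- c(ssb$g, list(stages = g_slow_stages))

  # lateral convs backward -> gradients into fast features
  df_feats <- vector("list", n_stages + 1)
  g_lat <- vector("list", n_stages)
  for (k in seq_len(n_stages)) {
    lbk <- unit_b(cache$lat[[k]], dlat[[k]])
    g_lat[[k]] <- lbk$g
    df_feats[[k]] <- lbk$dx
  }
  df_feats[[n_stages + 1]] <- gap_b(cache$gf, dgf)

  # fast chain backward, accumulating feature gradients
  dy <- df_feats[[n_stages + 1]]
  g_fast_stages <- vector("list", n_stages)
  for (s in rev(seq_len(n_stages))) {
    fb <- stage_b(p$fast$stages[[s]], cache$fstage[[s]], dy)
    dy <- fb$dx
    if (!is.null(df_feats[[s]])) dy <- dy + df_feats[[s]]
    g_fast_stages[[s]] <- fb$g
  }
  fsb <- pathway_stem_b(cache$fstem, dy)
  g_fast <- c(fsb$g, list(stages = g_fast_stages))

  list(slow = g_slow, fast = g_fast, lateral = g_lat,
       head = list(w = lb$dw, b = lb$db))
}

# Normalize a list of integer clips into the (H, W, T, 1, N) input tensor.
clips_to_batch <- function(clips) {
  d <- dim(clips[[1]])
  x <- array(0, dim = c(d[1], d[2], d[3], 1L, length(clips)))
  for (i in seq_along(clips)) x[, , , 1L, i] <- clips[[i]] / 255 - 0.5
  x
}

#' Predict class scores for clips
#'
#' Runs the network in evaluation mode (dropout off, batch-norm running
#' statistics), so predictions are deterministic.
#'
#' @param object A `slowfast_model`.
#' @param clips List of `cell_clip` arrays matching the configured input
#'   shape.
#' @param batch_size Clips per forward batch.
#' @param ... Unused.
#' @return An `N x n_classes` matrix of class probabilities (rows sum
#'   to 1); columns carry the class names once the model has been fitted.
#' @export
predict.slowfast_model <- function(object, clips, batch_size = 16L, ...) {
  cfg <- object$cfg
  for (cl in clips) {
    d <- dim(cl)
    if (d[1] != cfg$clip_size || d[2] != cfg$clip_size ||
        d[3] != cfg$clip_frames) {
      stop(sprintf("clip shape %s does not match configured %dx%dx%d",
                   paste(d, collapse = "x"), cfg$clip_size, cfg$clip_size,
                   cfg$clip_frames))
    }
  }
  n <- length(clips)
  out <- matrix(NA_real_, n, cfg$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- clips_to_batch(clips[i:j])
    fw <- slowfast_forward(object, x, training = FALSE)
    z <- sweep(fw$logits, 2, apply(fw$logits, 2, max), "-")
    ez <- exp(z)
    out[i:j, ] <- t(sweep(ez, 2, colSums(ez), "/"))
    i <- j + 1L
  }
  if (!is.null(object$classes)) colnames(out) <- object$classes
  out
}

#' Count trainable parameters per component
#'
#' @param model A `slowfast_model`.
#' @return List with totals for `slow`, `fast`, `lateral`, `head`, `total`,
#'   and `stage_ratio`, the per-stage fast/slow parameter ratios of the
#'   residual stages.
#' @export
count_parameters <- function(model) {
  cnt <- function(tree) tree_reduce_sum(tree, length)
  p <- model$params
  n_stages <- length(model$cfg$widths)
  stage_ratio <- vapply(seq_len(n_stages), function(s) {
    cnt(p$fast$stages[[s]]) / cnt(p$slow$stages[[s]])
  }, numeric(1))
  list(slow = cnt(p$slow), fast = cnt(p$fast), lateral = cnt(p$lateral),
       head = cnt(p$head), total = cnt(p), stage_ratio = stage_ratio)
}

#' @export
print.slowfast_model <- function(x, ...) {
  cfg <- x$cfg
  pf <- pathway_frames(cfg)
  np <- count_parameters(x)
  cat(sprintf(paste0(
    "<slowfast_model> depth '%s', tau=%d alpha=%d beta=%.3f\n",
    "  clip %dx%dx%d -> slow %d frames / fast %d frames\n",
    "  parameters: slow %d, fast %d, lateral %d, head %d (total %d)\n"),
    cfg$depth, cfg$tau, cfg$alpha, cfg$beta,
    cfg$clip_size, cfg$clip_size, cfg$clip_frames, pf$slow, pf$fast,
    np$slow, np$fast, np$lateral, np$head, np$total))
  invisible(x)
}
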