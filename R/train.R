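# Training loop: stochastic gradient descent with momentum, cross-entropy
# loss, cosine warm-restart learning-rate schedule, validation every second
# epoch with early stopping on macro-sensitivity stagnation.

#' Macro-averaged sensitivity
#'
#' Unweighted mean of per-class recalls over the classes present in
#' `truth`.
#'
#' @param pred,truth Character/factor vectors of predicted and true labels.
#' @return Mean per-class recall in `[0, 1]`.
#' @export
macro_sensitivity <- function(pred, truth) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  mean(vapply(unique(truth), function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

default_hyper <- function() {
  list(lr = 0.01, momentum = 0.9, batch_size = 8L, max_epochs = 250L,
       eval_every = 2L, patience = 10L, restart_period = 10L,
       restart_mult = 2L, lr_min = 1e-4,
       jitter_px = 4L, jitter_frames = 2L, hflip = FALSE)
}

# Train-time augmentation of a single integer clip: spatial jitter (zero
# fill), temporal jitter (edge replication), optional horizontal flip
# (disabled by default: flow direction is physically meaningful).
augment_clip <- function(clip, jitter_px, jitter_frames, hflip) {
  d <- dim(clip)
  if (jitter_px > 0) {
    dr <- sample.int(2 * jitter_px + 1, 1) - jitter_px - 1L
    dc <- sample.int(2 * jitter_px + 1, 1) - jitter_px - 1L
    if (dr != 0 || dc != 0) {
      out <- array(0L, dim = d)
      src_r <- seq_len(d[1]) - dr
      src_c <- seq_len(d[2]) - dc
      rok <- src_r >= 1 & src_r <= d[1]
      cok <- src_c >= 1 & src_c <= d[2]
      out[which(rok), which(cok), ] <- clip[src_r[rok], src_c[cok], ,
                                            drop = FALSE]
      clip <- out
    }
  }
  if (jitter_frames > 0) {
    dt <- sample.int(2 * jitter_frames + 1, 1) - jitter_frames - 1L
    if (dt != 0) {
      idx <- pmin(pmax(seq_len(d[3]) + dt, 1L), d[3])
      clip <- clip[, , idx, drop = FALSE]
    }
  }
  if (hflip && runif(1) < 0.5) {
    clip <- clip[, rev(seq_len(d[2])), , drop = FALSE]
  }
  clip
}

cosine_restart_lr <- function(epoch, lr0, lr_min, period0, mult) {
  # epoch is 1-based; returns the learning rate for that epoch
  t_cur <- epoch - 1
  ti <- period0
  while (t_cur >= ti) {
    t_cur <- t_cur - ti
    ti <- ti * mult
  }
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * t_cur / ti))
}

#' Fit a two-pathway classifier
#'
#' Mini-batch SGD with momentum 0.9 and cross-entropy loss under a cosine
#' warm-restart learning-rate schedule.  If validation clips are supplied,
#' the model is evaluated every `eval_every` epochs (macro sensitivity) and
#' training stops early once `patience` consecutive evaluations bring no
#' improvement; the best-scoring weights are restored.
#'
#' @param clips List of clip arrays (all of the configured shape).
#' @param labels Character/factor class labels, one per clip.
#' @param cfg A [slowfast_config()].
#' @param val_clips,val_labels Optional validation set.
#' @param hyper Named list of hyperparameters overriding the defaults
#'   (`lr = 0.01`, `momentum = 0.9`, `batch_size = 8`, `max_epochs = 250`,
#'   `eval_every = 2`, `patience = 10`, `restart_period = 10`,
#'   `restart_mult = 2`, `lr_min = 1e-4`, `jitter_px = 4`,
#'   `jitter_frames = 2`, `hflip = FALSE`).
#' @param seed Seed controlling initialization, shuffling, dropout and
#'   augmentation.
#' @param verbose Print per-epoch progress.
#' @return An object of class `slowfast_fit`: list with `model`, `history`
#'   (epoch, training loss, learning rate, validation sensitivity at
#'   evaluated epochs), `best_val`, `epochs_run`, `initial_loss`,
#'   `classes`.
#' @export
slowfast_fit <- function(clips, labels, cfg, val_clips = NULL,
                         val_labels = NULL, hyper = list(), seed = NULL,
                         verbose = FALSE) {
  hp <- modifyList(default_hyper(), hyper)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (cfg$n_classes != length(classes)) {
    stop("cfg$n_classes (", cfg$n_classes, ") != number of observed classes (",
         length(classes), ")")
  }
  y <- match(labels, classes)
  model <- build_slowfast(cfg, seed = derive_seed(seed, 1L))
  model$classes <- classes
  vel <- tree_map(model$params, function(a) a * 0)

  n <- length(clips)
  history <- list()
  best_val <- -Inf
  best_params <- NULL
  best_bn <- NULL
  stale <- 0L
  initial_loss <- NA_real_
  epochs_run <- 0L

  with_seed(derive_seed(seed, 2L), {
    for (epoch in seq_len(hp$max_epochs)) {
      lr <- cosine_restart_lr(epoch, hp$lr, hp$lr_min, hp$restart_period,
                              hp$restart_mult)
      ord <- sample.int(n)
      ep_loss <- 0
      n_batches <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + hp$batch_size - 1L, n)
        sel <- ord[i:j]
        bclips <- lapply(clips[sel], augment_clip, jitter_px = hp$jitter_px,
                         jitter_frames = hp$jitter_frames, hflip = hp$hflip)
        x <- clips_to_batch(bclips)
        fw <- slowfast_forward(model, x, training = TRUE)
        sm <- softmax_ce(fw$logits, y[sel])
        if (!is.finite(sm$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               "; reduce the learning rate")
        }
        if (is.na(initial_loss)) initial_loss <- sm$loss
        grads <- slowfast_backward(model, fw$cache, sm$dlogits)
        vel <- tree_map2(vel, grads, function(v, g) hp$momentum * v + g)
        model$params <- tree_map2(model$params, vel,
                                  function(p, v) p - lr * v)
        ep_loss <- ep_loss + sm$loss
        n_batches <- n_batches + 1L
        i <- j + 1L
      }
      epochs_run <- epoch
      val_sens <- NA_real_
      if (!is.null(val_clips) && epoch %% hp$eval_every == 0) {
        probs <- predict(model, val_clips)
        pred <- classes[max.col(probs, ties.method = "first")]
        val_sens <- macro_sensitivity(pred, as.character(val_labels))
        if (val_sens > best_val + 1e-12) {
          best_val <- val_sens
          best_params <- model$params
          best_bn <- as.list(model$bn)
          stale <- 0L
        } else {
          stale <- stale + 1L
        }
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, loss = ep_loss / n_batches, lr = lr,
        val_sensitivity = val_sens)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  lr %.5f  val %s", epoch,
                        ep_loss / n_batches, lr,
                        ifelse(is.na(val_sens), "-",
                               sprintf("%.3f", val_sens))))
      }
      if (!is.null(val_clips) && stale >= hp$patience) break
    }
  })

  if (!is.null(best_params)) {
    model$params <- best_params
    for (nm in names(best_bn)) model$bn[[nm]] <- best_bn[[nm]]
  }
  structure(list(model = model, history = do.call(rbind, history),
                 best_val = if (is.finite(best_val)) best_val else NA_real_,
                 epochs_run = epochs_run, initial_loss = initial_loss,
                 classes = classes, hyper = hp),
            class = "slowfast_fit")
}

#' @export
predict.slowfast_fit <- function(object, clips, ...) {
  predict(object$model, clips, ...)
}

#' @export
print.slowfast_fit <- function(x, ...) {
  cat(sprintf(
    "<slowfast_fit> %d epochs, final loss %.4f, best val sensitivity %s\n",
    x$epochs_run, x$history$loss[nrow(x$history)],
    ifelse(is.na(x$best_val), "-", sprintf("%.3f", x$best_val))))
  invisible(x)
}
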