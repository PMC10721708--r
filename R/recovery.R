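# Desk-scale recovery experiment: can the full pipeline - rendering,
# detection, tracking, clip extraction, donor-disjoint splitting and a
# tiny two-pathway model - recover the planted fetal/adult contrast on a
# strongly separated synthetic cohort?

#' Configuration of the desk-scale synthetic recovery experiment
#'
#' The study conditions used by the package's own end-to-end check:
#' 12 donors (6 per class) of 50 cells each, rendered into 256 x 150 px
#' videos (a shortened channel keeps rendering and detection cheap while
#' preserving the constriction geometry), arrival rate raised so a donor
#' recording stays a few hundred frames; clips standardized to 16 frames;
#' the tiny network preset; training capped at 60 epochs with early
#' stopping (patience 15 evaluations at every second epoch).  Class
#' contrast is the default fetal/adult parameter set: projected-area ratio
#' 1.21^(2/3) plus the deformation-amplitude difference.
#'
#' @param n_per_class Donors per class.
#' @param cells_per_donor Cells per donor.
#' @return Nested configuration list for [run_pipeline()] /
#'   [synthetic_recovery()].
#' @export
recovery_config <- function(n_per_class = 6L, cells_per_donor = 50L) {
  list(
    scene = list(frame_width = 256L, frame_height = 150L, noise_sd = 2,
                 cells_per_second = 40, frame_rate = 500,
                 constriction_start = 110L, constriction_end = 150L,
                 taper = 30L, arrival = "poisson"),
    donors = list(n_per_class = n_per_class,
                  cells_per_donor = cells_per_donor,
                  donor_effect_sd = 0.05),
    tracking = list(min_track_len = 8L, clip_size = 50L, clip_frames = 16L),
    model = list(tau = 8L, alpha = 8L, beta = 1 / 8, depth = "tiny",
                 dropout = 0.5),
    # one monotone cosine cycle at a higher initial rate than the 0.01
    # pipeline default: the tiny model on a few hundred clips needs the
    # larger steps to leave the init basin within its 50-epoch budget
    training = list(lr = 0.05, max_epochs = 60L, patience = 15L,
                    eval_every = 2L, restart_period = 60L,
                    jitter_px = 1L, jitter_frames = 1L),
    splits = list(k = 5L)
  )
}

#' Run the synthetic recovery experiment once
#'
#' Generates the synthetic cohort of [recovery_config()], runs detection,
#' tracking and clip extraction, splits donors disjointly into 5 sets,
#' trains one tiny two-pathway model on three of them with early stopping
#' on the fourth, and reports macro sensitivity on the held-out test
#' split.
#'
#' @param seed Seed for the whole experiment.
#' @param config Configuration overrides merged onto [recovery_config()].
#' @return List: `sensitivity` (macro, on the test split), `accuracy`,
#'   `n_clips`, `n_test`, `fit` (the trained model), `data`, `splits`.
#' @export
synthetic_recovery <- function(seed = 1L, config = list()) {
  cfg <- merge_config(merge_config(default_pipeline_config(),
                                   recovery_config()), config)
  scene <- config_scene(cfg)
  classes <- config_classes(cfg)
  donors <- config_donors(cfg)

  clips <- list()
  labels <- character(0)
  donor_of <- character(0)
  for (i in seq_along(donors)) {
    d <- donors[[i]]
    d$seed <- derive_seed(derive_seed(seed, 1L), i)
    res <- generate_donor_video(scene, d, classes)
    det <- detect_cells(res$sequence, threshold = cfg$detection$threshold,
                        min_area = cfg$detection$min_area,
                        sigma = cfg$detection$sigma,
                        n_background = cfg$detection$n_background,
                        seed = derive_seed(derive_seed(seed, 2L), i))
    tracks <- build_tracks(det, min_len = cfg$tracking$min_track_len,
                           donor_id = d$donor_id, class_label = d$class_label)
    cl <- extract_clips(tracks, res$sequence, size = cfg$tracking$clip_size,
                        n_frames = cfg$tracking$clip_frames)
    clips <- c(clips, cl)
    labels <- c(labels, rep(d$class_label, length(cl)))
    donor_of <- c(donor_of, rep(d$donor_id, length(cl)))
  }
  data <- clip_dataset(clips, labels, donor_of)

  counts <- table(factor(data$donor_ids,
                         levels = vapply(donors, `[[`, "", "donor_id")))
  manifest <- data.frame(
    donor_id = names(counts),
    class = vapply(donors, `[[`, "", "class_label"),
    n_cells = as.integer(counts))
  splits <- make_splits(manifest, k = cfg$splits$k,
                        seed = derive_seed(seed, 3L))
  test_split <- attr(splits, "test_split")
  k <- attr(splits, "k")
  folds <- setdiff(seq_len(k), test_split)
  val_split <- folds[1]
  donor_split <- setNames(splits$split, splits$donor_id)
  clip_split <- donor_split[data$donor_ids]
  train_idx <- which(!clip_split %in% c(val_split, test_split))
  val_idx <- which(clip_split == val_split)
  test_idx <- which(clip_split == test_split)

  sf_cfg <- slowfast_config(
    tau = cfg$model$tau, alpha = cfg$model$alpha, beta = cfg$model$beta,
    depth = cfg$model$depth, dropout = cfg$model$dropout,
    clip_frames = cfg$tracking$clip_frames,
    clip_size = cfg$tracking$clip_size)
  fit <- slowfast_fit(data$clips[train_idx], data$labels[train_idx], sf_cfg,
                      val_clips = data$clips[val_idx],
                      val_labels = data$labels[val_idx],
                      hyper = cfg$training, seed = derive_seed(seed, 4L))
  probs <- predict(fit, data$clips[test_idx])
  pred <- fit$classes[max.col(probs, ties.method = "first")]
  truth <- data$labels[test_idx]
  list(sensitivity = macro_sensitivity(pred, truth),
       accuracy = mean(pred == truth),
       n_clips = length(data$clips), n_test = length(test_idx),
       fit = fit, data = data, splits = splits)
}
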