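# End-to-end pipeline: simulate -> detect -> track -> split -> train ->
# evaluate -> donor stats -> (optional) ramping, driven by one nested
# configuration whose defaults are the analysis constants (threshold 5,
# min area 50, tau = alpha = 8, beta = 1/8, dropout 0.5, batch 8,
# momentum 0.9, max 250 epochs, validation every 2 epochs).

#' Default pipeline configuration
#'
#' @return Nested named list of all pipeline parameters with their default
#'   values.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    write_videos = FALSE,
    scene = list(frame_height = 150L, frame_width = 800L, frame_rate = 500,
                 noise_sd = 2, cells_per_second = 2, arrival = "poisson"),
    classes = list(
      fetal = list(),   # overrides of rbc_class_defaults()$fetal
      adult = list()
    ),
    donors = list(n_per_class = 6L, cells_per_donor = 25L,
                  donor_effect_sd = 0.05),
    detection = list(threshold = 5, min_area = 50L, sigma = 1,
                     connectivity = 8L, n_background = 100L),
    tracking = list(min_track_len = 8L, clip_size = 50L, clip_frames = 64L),
    model = list(tau = 8L, alpha = 8L, beta = 1 / 8, depth = "tiny",
                 dropout = 0.5),
    training = list(lr = 0.01, momentum = 0.9, batch_size = 8L,
                    max_epochs = 250L, eval_every = 2L, patience = 10L,
                    restart_period = 10L, restart_mult = 2L,
                    jitter_px = 4L, jitter_frames = 2L, hflip = FALSE),
    splits = list(k = 5L),
    evaluation = list(positive = "fetal"),
    ramping = list(enabled = FALSE, fractions = seq(0.1, 1, by = 0.1))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a nested list) and injects defaults for
#' every omitted parameter, so a config that leaves out, e.g., the
#' detection threshold or minimum area gets the standard values (5 and 50).
#'
#' @param config Path to a YAML file, or a nested list of overrides;
#'   `NULL` gives the pure defaults.
#' @return Complete configuration list.
#' @export
load_pipeline_config <- function(config = NULL) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- merge_config(base, config)
  stopifnot(cfg$detection$threshold >= 0, cfg$detection$min_area >= 0,
            cfg$tracking$clip_frames %% cfg$model$tau == 0)
  cfg
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

# Donor specs from the config's donors section.
config_donors <- function(cfg) {
  dn <- cfg$donors
  if (!is.null(dn$table)) {
    return(lapply(dn$table, function(r) {
      donor_spec(r$donor_id, r$class, n_cells = r$n_cells,
                 donor_effect_sd = dn$donor_effect_sd %||% 0.05)
    }))
  }
  specs <- list()
  for (cls in c("fetal", "adult")) {
    for (i in seq_len(dn$n_per_class)) {
      specs[[length(specs) + 1L]] <- donor_spec(
        sprintf("%s%02d", substr(cls, 1, 1), i), cls,
        n_cells = dn$cells_per_donor,
        donor_effect_sd = dn$donor_effect_sd %||% 0.05)
    }
  }
  specs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_scene <- function(cfg) do.call(scene_params, cfg$scene)

config_classes <- function(cfg) {
  defaults <- rbc_class_defaults()
  for (cls in names(defaults)) {
    ov <- cfg$classes[[cls]]
    if (length(ov)) {
      defaults[[cls]] <- do.call(class_params,
                                 merge_config(unclass(defaults[[cls]]), ov))
    }
  }
  defaults
}

#' Detect, track and extract clips for a whole cohort
#'
#' @param cohort Result of [generate_cohort()] (with frames kept).
#' @param detection,tracking Parameter lists as in
#'   [default_pipeline_config()].
#' @param seed Seed for background sampling.
#' @return A [clip_dataset()]; clip donor/class labels come from the
#'   cohort manifest.
#' @export
cohort_clips <- function(cohort,
                         detection = default_pipeline_config()$detection,
                         tracking = default_pipeline_config()$tracking,
                         seed = NULL) {
  clips <- list()
  labels <- character(0)
  donors <- character(0)
  for (i in seq_len(nrow(cohort$manifest))) {
    id <- cohort$manifest$donor_id[i]
    cls <- cohort$manifest$class[i]
    seq_ <- cohort$videos[[id]]
    det <- detect_cells(seq_, threshold = detection$threshold,
                        min_area = detection$min_area,
                        sigma = detection$sigma,
                        connectivity = detection$connectivity,
                        n_background = detection$n_background,
                        seed = derive_seed(seed, i))
    tracks <- build_tracks(det, min_len = tracking$min_track_len,
                           donor_id = id, class_label = cls)
    cl <- extract_clips(tracks, seq_, size = tracking$clip_size,
                        n_frames = tracking$clip_frames)
    clips <- c(clips, cl)
    labels <- c(labels, rep(cls, length(cl)))
    donors <- c(donors, rep(id, length(cl)))
  }
  clip_dataset(clips, labels, donors)
}

#' Run the full pipeline
#'
#' Simulate a synthetic cohort, detect and track cells, extract clips,
#' split donors disjointly, train the cross-validated two-pathway
#' classifier, evaluate on the held-out test split, run the donor-effect
#' statistics, and optionally the ramping experiment.  Any stage failure
#' halts with the stage name in the error.
#'
#' @param config Configuration (path, list, or `NULL` for defaults), see
#'   [load_pipeline_config()].
#' @param out_dir Output directory for result tables, JSON summaries and
#'   the run summary; `NULL` returns results only.
#' @param seed Overrides the config seed.
#' @return List with `manifest`, `splits`, `cv`, `metrics`, `donor_acc`,
#'   `donor_stats`, `ramping` (or `NULL`), `summary`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL) {
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  seed <- cfg$seed
  times <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  scene <- config_scene(cfg)
  classes <- config_classes(cfg)
  donors <- config_donors(cfg)
  # one donor at a time: render, detect, track, extract clips, then drop
  # the frames, so memory stays flat in the cohort size
  data <- stage("simulate_detect_track", {
    manifest0 <- cohort_manifest(donors)
    video_dir <- if (isTRUE(cfg$write_videos) && !is.null(out_dir)) {
      dir.create(file.path(out_dir, "videos"), recursive = TRUE,
                 showWarnings = FALSE)
      file.path(out_dir, "videos")
    }
    clips <- list()
    labels <- character(0)
    donor_of <- character(0)
    for (i in seq_along(donors)) {
      d <- donors[[i]]
      if (is.na(d$seed)) d$seed <- derive_seed(derive_seed(seed, 1L), i)
      res <- generate_donor_video(scene, d, classes)
      if (!is.null(video_dir)) {
        write_video_tiff(res$sequence,
                         file.path(video_dir, paste0(d$donor_id, ".tiff")))
        write_ground_truth_json(
          res$ground_truth,
          file.path(video_dir, paste0(d$donor_id, "_truth.json")))
      }
      det <- detect_cells(res$sequence, threshold = cfg$detection$threshold,
                          min_area = cfg$detection$min_area,
                          sigma = cfg$detection$sigma,
                          connectivity = cfg$detection$connectivity,
                          n_background = cfg$detection$n_background,
                          seed = derive_seed(derive_seed(seed, 2L), i))
      tracks <- build_tracks(det, min_len = cfg$tracking$min_track_len,
                             donor_id = d$donor_id,
                             class_label = d$class_label)
      cl <- extract_clips(tracks, res$sequence,
                          size = cfg$tracking$clip_size,
                          n_frames = cfg$tracking$clip_frames)
      clips <- c(clips, cl)
      labels <- c(labels, rep(d$class_label, length(cl)))
      donor_of <- c(donor_of, rep(d$donor_id, length(cl)))
    }
    attr(manifest0, "dataset") <- clip_dataset(clips, labels, donor_of)
    manifest0
  })
  manifest <- data
  data <- attr(manifest, "dataset")
  attr(manifest, "dataset") <- NULL

  clip_counts <- table(factor(data$donor_ids, levels = manifest$donor_id))
  manifest$n_clips <- as.integer(clip_counts)
  splits <- stage("split", make_splits(
    data.frame(donor_id = manifest$donor_id, class = manifest$class,
               n_cells = manifest$n_clips),
    k = cfg$splits$k, seed = derive_seed(seed, 3L)))

  sf_cfg <- slowfast_config(
    tau = cfg$model$tau, alpha = cfg$model$alpha, beta = cfg$model$beta,
    depth = cfg$model$depth, dropout = cfg$model$dropout,
    clip_frames = cfg$tracking$clip_frames,
    clip_size = cfg$tracking$clip_size)
  cv <- stage("train", run_cv(data, splits, sf_cfg, hyper = cfg$training,
                              seed = derive_seed(seed, 4L)))
  metrics <- stage("evaluate", compute_metrics(
    cv$test_scores, cv$test_labels, positive = cfg$evaluation$positive))
  donor_acc <- stage("evaluate_donors", per_donor_accuracy(
    cv$test_scores, cv$test_labels, cv$test_donors,
    positive = cfg$evaluation$positive))

  donor_stats <- NULL
  if (ncol(donor_acc$acc) >= 2 && !anyNA(donor_acc$acc) &&
      all(table(donor_acc$donor_class) >= 2)) {
    donor_stats <- stage("donor_stats", list(
      lrt = lrt_random_effect(donor_acc),
      donor_anova = anova_donor_fixed(donor_acc),
      class_anova = anova_class_difference(rowMeans(donor_acc$acc),
                                           donor_acc$donor_class)))
  }

  ramping <- NULL
  if (isTRUE(cfg$ramping$enabled)) {
    ramping <- stage("ramp", run_ramping(
      data, splits, sf_cfg, hyper = cfg$training,
      fractions = cfg$ramping$fractions, seed = derive_seed(seed, 5L)))
  }

  summary <- list(
    config_hash = config_hash(cfg), seed = seed,
    package_version = as.character(packageVersion("deformcyte")),
    r_version = R.version.string,
    n_clips = length(data$clips), n_donors = nrow(manifest),
    stage_seconds = as.list(times))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    write.csv(as.data.frame(splits), file.path(out_dir, "splits.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(metrics = as.list(metrics$metrics), ci = as.list(metrics$ci),
           per_class_recall = as.list(metrics$per_class_recall),
           n = metrics$n, n_folds = metrics$n_folds),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    write.csv(as.data.frame(metrics$confusion),
              file.path(out_dir, "confusion.csv"), row.names = FALSE)
    write.csv(data.frame(donor_id = rownames(donor_acc$acc),
                         class = donor_acc$donor_class, donor_acc$acc),
              file.path(out_dir, "per_donor_accuracy.csv"),
              row.names = FALSE)
    if (!is.null(donor_stats)) {
      jsonlite::write_json(list(
        sigma2_A = donor_stats$lrt$sigma2_A,
        sigma2 = donor_stats$lrt$sigma2,
        LRT = donor_stats$lrt$LRT,
        p_boundary = donor_stats$lrt$p_boundary,
        donor_anova = as.data.frame(donor_stats$donor_anova),
        class_anova = as.data.frame(donor_stats$class_anova)),
        file.path(out_dir, "donor_stats.json"), auto_unbox = TRUE,
        digits = NA)
    }
    if (!is.null(ramping)) {
      write.csv(ramping, file.path(out_dir, "ramping.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(manifest = manifest, splits = splits, cv = cv,
                 metrics = metrics, donor_acc = donor_acc,
                 donor_stats = donor_stats, ramping = ramping,
                 summary = summary))
}
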