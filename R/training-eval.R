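# Donor-disjoint splitting, cross-validated training, the classification
# metric suite with normal-approximation confidence intervals, per-donor
# accuracies, and the data-ramping experiment.

#' Bundle clips with their labels and donors
#'
#' @param clips List of clip arrays.
#' @param labels Class label per clip.
#' @param donor_ids Donor identifier per clip.
#' @return An object of class `clip_dataset`.
#' @export
clip_dataset <- function(clips, labels, donor_ids) {
  stopifnot(length(clips) == length(labels),
            length(clips) == length(donor_ids))
  structure(list(clips = clips, labels = as.character(labels),
                 donor_ids = as.character(donor_ids)),
            class = "clip_dataset")
}

#' @export
print.clip_dataset <- function(x, ...) {
  cat(sprintf("<clip_dataset> %d clips, %d donors (%s)\n", length(x$clips),
              length(unique(x$donor_ids)),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Donor-disjoint split assignment
#'
#' Partitions donors into `k` splits whose total cell counts are as close
#' to `1/k` of the total as greedy balancing achieves: donors are sorted by
#' descending cell count (ties in seeded random order) and each is assigned
#' to the currently smallest split.  Every donor lands in exactly one
#' split.  One split is designated the test set (the one whose cell total
#' is closest to `1/k` of the total; ties toward the lowest index); the
#' remaining `k - 1` are the cross-validation folds.
#'
#' @param manifest Data frame with columns `donor_id`, `class`, `n_cells`.
#' @param k Number of splits (default 5).
#' @param seed Seed for tie ordering.
#' @return An object of class `split_assignment`: data frame
#'   (`donor_id`, `class`, `n_cells`, `split`) with attributes
#'   `test_split` and `k`.
#' @export
make_splits <- function(manifest, k = 5L, seed = NULL) {
  stopifnot(all(c("donor_id", "class", "n_cells") %in% names(manifest)))
  if (anyDuplicated(manifest$donor_id)) stop("duplicate donor_id in manifest")
  n_donors <- nrow(manifest)
  if (n_donors < k) {
    stop("fewer donors (", n_donors, ") than splits (", k, ")")
  }
  ord <- with_seed(seed, {
    jitter <- sample.int(n_donors)
    order(-manifest$n_cells, jitter)
  })
  # class-stratified greedy: balance every class's cells across the splits
  # (so no split ends up class-pure), tie-breaking on the overall totals
  split <- integer(n_donors)
  totals <- numeric(k)
  class_totals <- matrix(0, k, length(unique(manifest$class)),
                         dimnames = list(NULL, sort(unique(manifest$class))))
  for (i in ord) {
    cl <- manifest$class[i]
    s <- order(class_totals[, cl], totals)[1]
    split[i] <- s
    totals[s] <- totals[s] + manifest$n_cells[i]
    class_totals[s, cl] <- class_totals[s, cl] + manifest$n_cells[i]
  }
  target <- sum(manifest$n_cells) / k
  both <- rowSums(class_totals > 0) == ncol(class_totals)
  cand <- if (any(both)) which(both) else seq_len(k)
  test_split <- cand[which.min(abs(totals[cand] - target))]
  out <- data.frame(donor_id = manifest$donor_id, class = manifest$class,
                    n_cells = manifest$n_cells, split = split,
                    stringsAsFactors = FALSE)
  structure(out, test_split = test_split, k = k,
            class = c("split_assignment", "data.frame"))
}

#' @export
print.split_assignment <- function(x, ...) {
  k <- attr(x, "k")
  cat(sprintf("<split_assignment> %d donors into %d splits (test = %d)\n",
              nrow(x), k, attr(x, "test_split")))
  agg <- stats::aggregate(n_cells ~ split, data = as.data.frame(x), FUN = sum)
  nd <- as.integer(table(factor(x$split, levels = seq_len(k))))
  for (s in seq_len(k)) {
    cat(sprintf("  split %d: %d donors, %d cells (%.2f%%)\n", s, nd[s],
                agg$n_cells[s], 100 * agg$n_cells[s] / sum(x$n_cells)))
  }
  invisible(x)
}

split_donors <- function(splits, which_split) {
  splits$donor_id[splits$split %in% which_split]
}

#' Cross-validated training with donor-disjoint folds
#'
#' Trains one model per cross-validation fold: each fold's model trains on
#' the other `k - 2` non-test splits, validates on the fold's split (early
#' stopping on macro sensitivity, evaluated every second epoch), and the
#' test split stays untouched.  Each fold's model then scores the test
#' clips.
#'
#' @param data A [clip_dataset()].
#' @param splits A [make_splits()] assignment covering the data's donors.
#' @param cfg A [slowfast_config()].
#' @param hyper Hyperparameter overrides, see [slowfast_fit()].
#' @param seed Base seed; fold f trains under a seed derived from it.
#' @param verbose Passed to [slowfast_fit()].
#' @return Object of class `slowfast_cv`: `fits` (per fold), `fold_splits`,
#'   `test_scores` (matrix: test clips x folds, probability of the first
#'   class in `classes`), `test_labels`, `test_donors`, `classes`.
#' @export
run_cv <- function(data, splits, cfg, hyper = list(), seed = NULL,
                   verbose = FALSE) {
  stopifnot(inherits(data, "clip_dataset"),
            inherits(splits, "split_assignment"))
  k <- attr(splits, "k")
  test_split <- attr(splits, "test_split")
  folds <- setdiff(seq_len(k), test_split)
  donor_split <- setNames(splits$split, splits$donor_id)
  clip_split <- donor_split[data$donor_ids]
  if (anyNA(clip_split)) stop("clips from donors absent from the split table")
  test_idx <- which(clip_split == test_split)
  classes <- sort(unique(data$labels))

  fits <- list()
  test_scores <- matrix(NA_real_, length(test_idx), length(folds))
  for (fi in seq_along(folds)) {
    f <- folds[fi]
    val_idx <- which(clip_split == f)
    train_idx <- which(!clip_split %in% c(f, test_split))
    fit <- slowfast_fit(data$clips[train_idx], data$labels[train_idx], cfg,
                        val_clips = data$clips[val_idx],
                        val_labels = data$labels[val_idx],
                        hyper = hyper, seed = derive_seed(seed, 100L + fi),
                        verbose = verbose)
    fits[[fi]] <- fit
    probs <- predict(fit, data$clips[test_idx])
    pos_col <- if ("fetal" %in% fit$classes) {
      which(fit$classes == "fetal")
    } else 1L
    test_scores[, fi] <- probs[, pos_col]
  }
  positive <- if ("fetal" %in% classes) "fetal" else classes[1]
  structure(list(fits = fits, fold_splits = folds,
                 test_scores = test_scores,
                 test_labels = data$labels[test_idx],
                 test_donors = data$donor_ids[test_idx],
                 classes = classes, positive = positive,
                 test_split = test_split),
            class = "slowfast_cv")
}

# Metric computations on a single score vector ---------------------------

rank_auc <- function(scores, positive_mask) {
  nP <- sum(positive_mask)
  nN <- sum(!positive_mask)
  if (nP == 0 || nN == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive_mask]) - nP * (nP + 1) / 2) / (nP * nN)
}

hanley_mcneil_se <- function(auc, nP, nN) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (nP - 1) * (q1 - auc^2) +
        (nN - 1) * (q2 - auc^2)) / (nP * nN))
}

metric_suite_one <- function(scores, labels, positive, z = 1.959964) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  pos_mask <- labels == positive
  other <- setdiff(classes, positive)
  pred <- ifelse(scores > 0.5, positive,
                 if (length(other)) other[1] else positive)
  n <- length(labels)
  cm_classes <- sort(unique(c(labels, positive)))
  cm <- table(factor(labels, levels = cm_classes),
              factor(pred, levels = cm_classes))
  recalls <- vapply(cm_classes, function(cl) {
    tot <- sum(labels == cl)
    if (tot == 0) NA_real_ else sum(pred == cl & labels == cl) / tot
  }, numeric(1))
  acc <- mean(pred == labels)
  sens <- mean(recalls, na.rm = TRUE)
  tp <- sum(pred == positive & labels == positive)
  fp <- sum(pred == positive & labels != positive)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec_pos <- recalls[[positive]]
  f1 <- if (is.na(prec) || is.na(rec_pos) || prec + rec_pos == 0) {
    NA_real_
  } else 2 * prec * rec_pos / (prec + rec_pos)
  auc <- rank_auc(scores, pos_mask)
  wald <- function(p) if (is.na(p)) NA_real_ else z * sqrt(p * (1 - p) / n)
  auc_ci <- if (is.na(auc)) NA_real_ else {
    z * hanley_mcneil_se(auc, sum(pos_mask), sum(!pos_mask))
  }
  list(auc = auc, sensitivity = sens, accuracy = acc, precision = prec,
       f1 = f1,
       ci = c(auc = auc_ci, sensitivity = wald(sens), accuracy = wald(acc),
              precision = wald(prec), f1 = wald(f1)),
       recalls = recalls, confusion = unclass(cm), n = n)
}

#' Classification metric suite
#'
#' AUC (rank statistic), macro-averaged sensitivity (unweighted mean of
#' per-class recalls), accuracy, precision and F1 for the positive
#' (`fetal`) class, all in percent with symmetric 95% confidence intervals
#' from the normal approximation (Wald for proportion-type metrics,
#' Hanley-McNeil variance for the AUC).  Given a score matrix with one
#' column per cross-validation fold, per-fold metrics are averaged
#' (fold-mean reporting) and the confusion matrix is the entrywise mean
#' across folds; pooled metrics over the concatenated folds are attached
#' alongside.
#'
#' @param scores Probability of the positive class: numeric vector, or a
#'   matrix with one column per fold.
#' @param labels True class labels (one per clip).
#' @param positive Positive class name (default `"fetal"`).
#' @return Object of class `metrics_report`: `metrics` (percent),
#'   `ci` (95% half-widths, percentage points), `confusion`
#'   (fold-averaged counts, rows = true class), `per_class_recall`,
#'   `n`, `n_folds`, and `pooled` (same suite over concatenated folds;
#'   `NULL` for vector input).  With single-class labels the AUC is
#'   reported as `NA`.
#' @export
compute_metrics <- function(scores, labels, positive = "fetal") {
  if (is.matrix(scores)) {
    stopifnot(nrow(scores) == length(labels))
    per_fold <- lapply(seq_len(ncol(scores)), function(f) {
      metric_suite_one(scores[, f], labels, positive)
    })
    keys <- c("auc", "sensitivity", "accuracy", "precision", "f1")
    mm <- vapply(per_fold, function(m) unlist(m[keys]), numeric(5))
    metrics <- rowMeans(mm)
    ci <- rowMeans(vapply(per_fold, function(m) m$ci, numeric(5)))
    names(ci) <- keys
    confusion <- Reduce(`+`, lapply(per_fold, `[[`, "confusion")) /
      length(per_fold)
    recalls <- rowMeans(vapply(per_fold, function(m) m$recalls,
                               numeric(length(per_fold[[1]]$recalls))))
    pooled <- metric_suite_one(as.vector(scores),
                               rep(labels, ncol(scores)), positive)
    n_folds <- ncol(scores)
    n <- length(labels)
  } else {
    m <- metric_suite_one(scores, labels, positive)
    metrics <- unlist(m[c("auc", "sensitivity", "accuracy", "precision",
                          "f1")])
    ci <- m$ci
    confusion <- m$confusion
    recalls <- m$recalls
    pooled <- NULL
    n_folds <- 1L
    n <- m$n
  }
  structure(list(metrics = 100 * metrics, ci = 100 * ci,
                 confusion = confusion, per_class_recall = 100 * recalls,
                 n = n, n_folds = n_folds, positive = positive,
                 pooled = pooled),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metrics_report> n = %d clips, %d fold(s)\n", x$n, x$n_folds))
  for (k in names(x$metrics)) {
    cat(sprintf("  %-12s %7.3f %% +/- %.3f\n", k, x$metrics[[k]],
                x$ci[[k]]))
  }
  cat("  per-class recall:",
      paste(sprintf("%s %.1f%%", names(x$per_class_recall),
                    x$per_class_recall), collapse = ", "), "\n")
  cat("  fold-averaged confusion (rows = truth):\n")
  print(round(x$confusion, 2))
  invisible(x)
}

#' Per-donor, per-fold accuracy table
#'
#' Accuracy of each fold's model on each donor's test clips, plus the
#' class-level summary of donor-averaged accuracies (each donor weighted
#' equally): lowest, mean and highest per class.
#'
#' @param scores Matrix of positive-class probabilities, test clips x
#'   folds.
#' @param labels True labels per clip.
#' @param donor_ids Donor per clip.
#' @param positive Positive class (default `"fetal"`).
#' @return Object of class `accuracy_table`: `acc` (donors x folds matrix),
#'   `donor_class` (named), `summary` (data frame with lowest / mean /
#'   highest donor-averaged accuracy per class).
#' @export
per_donor_accuracy <- function(scores, labels, donor_ids,
                               positive = "fetal") {
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = 1)
  labels <- as.character(labels)
  donor_ids <- as.character(donor_ids)
  classes <- sort(unique(labels))
  other <- setdiff(classes, positive)
  donors <- unique(donor_ids)
  empty <- setdiff(donors, donor_ids)
  if (length(empty)) {
    warning("donors with zero clips excluded: ", paste(empty, collapse = ", "))
    donors <- setdiff(donors, empty)
  }
  acc <- matrix(NA_real_, length(donors), ncol(scores),
                dimnames = list(donors, paste0("fold", seq_len(ncol(scores)))))
  for (f in seq_len(ncol(scores))) {
    pred <- ifelse(scores[, f] > 0.5, positive,
                   if (length(other)) other[1] else positive)
    ok <- pred == labels
    acc[, f] <- vapply(donors, function(d) mean(ok[donor_ids == d]),
                       numeric(1))
  }
  donor_class <- vapply(donors, function(d) labels[donor_ids == d][1],
                        character(1))
  donor_avg <- rowMeans(acc)
  summary <- do.call(rbind, lapply(sort(unique(donor_class)), function(cl) {
    v <- donor_avg[donor_class == cl]
    data.frame(class = cl, lowest = min(v), mean = mean(v),
               highest = max(v), n_donors = length(v))
  }))
  structure(list(acc = acc, donor_class = donor_class, summary = summary),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat(sprintf("<accuracy_table> %d donors x %d folds\n", nrow(x$acc),
              ncol(x$acc)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Data-ramping experiment
#'
#' Holds out the test split, allocates about 10% of the training data
#' (donor-disjoint, greedy by cell count) as a validation set for early
#' stopping, then trains one model per fraction of the remaining training
#' clips and measures macro sensitivity on the test split.  With the
#' published bookkeeping (20% test, 10% validation) the fraction grid
#' \{10%, ..., 100%\} of the remaining training data corresponds to
#' \{7%, ..., 70%\} of the total, reported in `fraction_total_pct`.
#'
#' @param data A [clip_dataset()].
#' @param splits A [make_splits()] assignment (its test split is held out).
#' @param cfg,hyper,seed,verbose As in [run_cv()].
#' @param fractions Fractions of the remaining training clips to use.
#' @return Data frame with `fraction`, `fraction_total_pct`, `n_train`,
#'   `sensitivity`; skipped single-class fractions carry `NA` sensitivity.
#' @export
run_ramping <- function(data, splits, cfg, hyper = list(),
                        fractions = seq(0.1, 1, by = 0.1), seed = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(data, "clip_dataset"),
            inherits(splits, "split_assignment"))
  test_split <- attr(splits, "test_split")
  donor_split <- setNames(splits$split, splits$donor_id)
  clip_split <- donor_split[data$donor_ids]
  test_idx <- which(clip_split == test_split)
  train_donors <- splits$donor_id[splits$split != test_split]

  # validation: greedily collect donors until ~10% of training cells
  dcells <- splits$n_cells[match(train_donors, splits$donor_id)]
  ord <- with_seed(derive_seed(seed, 3L), sample(seq_along(train_donors)))
  target <- 0.1 * sum(dcells)
  val_donors <- character(0)
  got <- 0
  for (i in ord) {
    if (got >= target) break
    val_donors <- c(val_donors, train_donors[i])
    got <- got + dcells[i]
  }
  val_idx <- which(data$donor_ids %in% val_donors)
  pool_idx <- which(!clip_split %in% test_split &
                    !data$donor_ids %in% val_donors)

  rows <- list()
  for (fi in seq_along(fractions)) {
    frac <- fractions[fi]
    n_sub <- max(1L, round(frac * length(pool_idx)))
    sub <- with_seed(derive_seed(seed, 10L + fi),
                     sort(sample(pool_idx, n_sub)))
    sens <- NA_real_
    if (length(unique(data$labels[sub])) < 2) {
      warning(sprintf("fraction %.0f%%: single-class training subset, skipped",
                      100 * frac))
    } else {
      fit <- slowfast_fit(data$clips[sub], data$labels[sub], cfg,
                          val_clips = data$clips[val_idx],
                          val_labels = data$labels[val_idx],
                          hyper = hyper, seed = derive_seed(seed, 20L + fi),
                          verbose = verbose)
      probs <- predict(fit, data$clips[test_idx])
      pred <- fit$classes[max.col(probs, ties.method = "first")]
      sens <- macro_sensitivity(pred, data$labels[test_idx])
    }
    rows[[fi]] <- data.frame(fraction = frac,
                             fraction_total_pct = 70 * frac,
                             n_train = n_sub, sensitivity = sens)
  }
  do.call(rbind, rows)
}
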