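# Donor-disjoint splitting, the metric suite, per-donor accuracies, and
# the ramping bookkeeping.

test_that("equal donors split one per fold at exactly 20%", {
  manifest <- data.frame(donor_id = paste0("d", 1:5),
                         class = c("fetal", "adult", "fetal", "adult",
                                   "fetal"),
                         n_cells = rep(40L, 5))
  sp <- make_splits(manifest, k = 5, seed = 1)
  expect_setequal(sp$split, 1:5)
  agg <- tapply(sp$n_cells, sp$split, sum)
  expect_true(all(agg == 40))
  expect_error(make_splits(manifest[1:3, ], k = 5), "fewer donors")
})

test_that("splits partition donors disjointly and balance classes", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(12:40, 1)
    manifest <- data.frame(
      donor_id = paste0("d", seq_len(n)),
      class = sample(c("fetal", "adult"), n, TRUE, prob = c(0.4, 0.6)),
      n_cells = sample(50:250, n, TRUE))
    k <- sample(3:5, 1)
    sp <- make_splits(manifest, k = k, seed = rep)
    expect_setequal(sp$donor_id, manifest$donor_id)
    expect_equal(anyDuplicated(sp$donor_id), 0)
    expect_true(all(sp$split %in% seq_len(k)))
    # every split's cell share near 1/k
    shares <- tapply(sp$n_cells, factor(sp$split, levels = seq_len(k)), sum)
    shares[is.na(shares)] <- 0
    expect_lt(max(abs(shares / sum(sp$n_cells) - 1 / k)), 0.12)
    # no class-pure split when both classes have >= k donors
    if (min(table(manifest$class)) >= k) {
      for (s in seq_len(k)) {
        expect_equal(length(unique(sp$class[sp$split == s])), 2)
      }
    }
  }
})

test_that("perfect predictions give perfect metrics", {
  labels <- rep(c("fetal", "adult"), each = 5)
  scores <- rep(c(0.9, 0.1), each = 5)
  m <- compute_metrics(scores, labels)
  expect_equal(unname(m$metrics[c("sensitivity", "accuracy", "precision",
                                  "f1", "auc")]),
               rep(100, 5))
  expect_equal(sum(m$confusion) - sum(diag(m$confusion)), 0)
})

test_that("a hand-computed confusion matrix yields the printed metrics", {
  # rows true adult/fetal: [[8, 2], [1, 9]]
  labels <- c(rep("adult", 10), rep("fetal", 10))
  scores <- c(rep(0.1, 8), rep(0.9, 2),   # adult: 8 right, 2 wrong
              rep(0.1, 1), rep(0.9, 9))   # fetal: 9 right, 1 wrong
  m <- compute_metrics(scores, labels)
  expect_equal(unname(m$metrics["accuracy"]), 85)
  expect_equal(unname(m$per_class_recall["adult"]), 80)
  expect_equal(unname(m$per_class_recall["fetal"]), 90)
  expect_equal(unname(m$metrics["sensitivity"]), 85)
  expect_equal(unname(m$confusion), matrix(c(8, 1, 2, 9), 2))
})

test_that("macro sensitivity equals the brute-force per-class mean", {
  set.seed(11)
  for (rep in 1:10) {
    truth <- sample(c("a", "b"), 40, TRUE)
    pred <- sample(c("a", "b"), 40, TRUE)
    brute <- mean(c(sum(pred == "a" & truth == "a") / sum(truth == "a"),
                    sum(pred == "b" & truth == "b") / sum(truth == "b")))
    expect_equal(macro_sensitivity(pred, truth), brute)
  }
})

test_that("rank AUC agrees with pROC and handles one-class input", {
  set.seed(12)
  labels <- sample(c("fetal", "adult"), 60, TRUE)
  scores <- runif(60) + 0.3 * (labels == "fetal")
  m <- compute_metrics(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("adult", "fetal"),
    direction = "<", quiet = TRUE)))
  expect_equal(unname(m$metrics["auc"]) / 100, ref, tolerance = 1e-12)
  one <- compute_metrics(runif(5), rep("fetal", 5))
  expect_true(is.na(one$metrics["auc"]))
})

test_that("metric identities hold on random confusion draws", {
  set.seed(13)
  for (rep in 1:10) {
    labels <- sample(c("fetal", "adult"), 50, TRUE)
    scores <- runif(50)
    m <- compute_metrics(scores, labels)
    cm <- m$confusion  # rows truth (adult, fetal), cols predicted
    n <- sum(cm)
    expect_equal(unname(m$metrics["accuracy"]) / 100, sum(diag(cm)) / n)
    P <- cm["fetal", "fetal"] / sum(cm[, "fetal"])
    R <- cm["fetal", "fetal"] / sum(cm["fetal", ])
    expect_equal(unname(m$metrics["f1"]) / 100, 2 * P * R / (P + R))
    expect_equal(unname(m$metrics["precision"]) / 100, P)
  }
})

test_that("fold-averaged confusion matrices sum to the clip count", {
  set.seed(14)
  labels <- sample(c("fetal", "adult"), 30, TRUE)
  scores <- matrix(runif(30 * 4), 30, 4)
  m <- compute_metrics(scores, labels)
  expect_equal(sum(m$confusion), 30)
  expect_equal(m$n_folds, 4)
  expect_false(is.null(m$pooled))
})

test_that("per-donor accuracies weight donors equally", {
  labels <- c(rep("fetal", 10), rep("adult", 2))
  donors <- c(rep("dA", 10), rep("dB", 2))
  # dA 80% correct, dB 100% correct, very different cell counts
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.1, 2))
  pda <- per_donor_accuracy(scores, labels, donors)
  expect_equal(unname(pda$acc[, 1]), c(0.8, 1.0))
  # donors weighted equally: mean donor accuracy 0.9, not the 10:2
  # cell-weighted 0.833
  expect_equal(mean(rowMeans(pda$acc)), 0.9)
  expect_equal(pda$summary$mean[pda$summary$class == "adult"], 1.0)
  expect_equal(pda$summary$mean[pda$summary$class == "fetal"], 0.8)
  # complete grid: 32 donors x 4 folds
  set.seed(15)
  labels32 <- rep(c("fetal", "adult"), each = 64)
  donors32 <- rep(sprintf("d%02d", 1:32), each = 4)
  scores32 <- matrix(runif(128 * 4), 128, 4)
  g <- per_donor_accuracy(scores32, labels32, donors32)
  expect_equal(dim(g$acc), c(32L, 4L))
  expect_equal(sum(!is.na(g$acc)), 128)
  # all-correct: summary collapses to 1
  perfect <- per_donor_accuracy(ifelse(labels32 == "fetal", 0.9, 0.1),
                                labels32, donors32)
  expect_true(all(perfect$summary[, c("lowest", "mean", "highest")] == 1))
})

test_that("ramping reports the documented fraction grid", {
  fr <- seq(0.1, 1, by = 0.1)
  expect_length(fr, 10)
  expect_equal(max(fr) * 70, 70)
  # structural run on a micro dataset
  ds <- blob_dataset(8)
  donors <- rep(paste0("d", 1:4), each = 4)
  data <- clip_dataset(ds$clips, ds$labels, donors)
  manifest <- data.frame(donor_id = paste0("d", 1:4),
                         class = ds$labels[c(1, 5, 9, 13)],
                         n_cells = rep(4L, 4))
  splits <- make_splits(manifest, k = 3, seed = 2)
  cfg <- slowfast_config(clip_frames = 16)
  out <- suppressWarnings(
    run_ramping(data, splits, cfg,
                hyper = list(max_epochs = 2, patience = 1),
                fractions = c(0.5, 1), seed = 4))
  expect_equal(out$fraction, c(0.5, 1))
  expect_equal(out$fraction_total_pct, c(35, 70))
  expect_true(all(out$sensitivity >= 0 & out$sensitivity <= 1, na.rm = TRUE))
  expect_true(out$n_train[2] > out$n_train[1])
})
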