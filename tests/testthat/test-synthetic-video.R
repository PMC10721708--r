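# Synthetic video generator: planted ground truth, determinism, class
# contrast, parameter validation.

test_that("empty donor yields pure background and empty ground truth", {
  scene <- tiny_scene(noise_sd = 0)
  res <- generate_donor_video(scene, donor_spec("d0", "adult", 0, seed = 1),
                              n_frames = 6)
  expect_equal(nrow(res$ground_truth$cells), 0)
  # background stationarity: all frames identical without noise
  f <- res$sequence$frames
  for (t in 2:dim(f)[3]) expect_identical(f[, , t], f[, , 1])
  # walls present: two intensity levels only
  expect_setequal(unique(as.vector(f[, , 1])),
                  c(scene$background_level, scene$wall_level))
})

test_that("planted masks carry every cell at close to the target area", {
  scene <- tiny_scene(noise_sd = 0)
  classes <- rbc_class_defaults()
  classes$adult$projected_area_cv <- 0
  classes$adult$contrast <- -40
  donor <- donor_spec("d5", "adult", 5, donor_effect_sd = 0, seed = 11)
  res <- generate_donor_video(scene, donor, classes)
  gt <- res$ground_truth
  expect_setequal(gt$cells$cell_id, 1:5)
  # pixel counts of planted masks away from the constriction within 10%
  target <- classes$adult$projected_area_mean
  pre_taper <- scene$constriction_start - scene$taper
  checked <- 0
  for (fr in gt$frames) {
    for (e in fr) {
      col <- e$centroid[2]
      if (col > 12 && col < pre_taper - 12) {
        expect_lt(abs(length(e$pixels) - target) / target, 0.1)
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 10)
})

test_that("fetal/adult defaults implement the volume-derived area ratio", {
  expect_equal(fetal_adult_area_ratio(), 1.21^(2 / 3))
  cls <- rbc_class_defaults()
  expect_equal(cls$fetal$projected_area_mean / cls$adult$projected_area_mean,
               1.21^(2 / 3))
})

test_that("rendered fetal cells are larger than adult cells", {
  # >= 100 cells per class; compare rendered mask areas before the taper
  scene <- tiny_scene(noise_sd = 0, cells_per_second = 50)
  pre_area <- function(class_label, seed) {
    donor <- donor_spec("d", class_label, 100, donor_effect_sd = 0,
                        seed = seed)
    gt <- generate_donor_video(scene, donor)$ground_truth
    best <- list()
    lim <- scene$constriction_start - scene$taper - 12
    for (fr in gt$frames) {
      for (e in fr) {
        if (e$centroid[2] > 12 && e$centroid[2] < lim) {
          id <- as.character(e$cell_id)
          best[[id]] <- max(best[[id]] %||% 0, length(e$pixels))
        }
      }
    }
    unlist(best)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  af <- pre_area("fetal", 21)
  aa <- pre_area("adult", 22)
  expect_gt(length(af), 90)
  tt <- t.test(af, aa, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  expect_equal(mean(af) / mean(aa), 1.21^(2 / 3), tolerance = 0.1)
})

test_that("generation is deterministic in (scene, donor, seed)", {
  scene <- tiny_scene(noise_sd = 2, arrival = "poisson")
  donor <- donor_spec("dd", "fetal", 4, seed = 77)
  a <- generate_donor_video(scene, donor)
  b <- generate_donor_video(scene, donor)
  expect_identical(a$sequence$frames, b$sequence$frames)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("oversized cells are rejected with a clear message", {
  scene <- tiny_scene()
  classes <- rbc_class_defaults()
  classes$adult$projected_area_mean <- 2000
  expect_error(
    generate_donor_video(scene, donor_spec("d", "adult", 2, seed = 1),
                         classes),
    "diameter")
})

test_that("cohort manifest totals and duplicate checks", {
  donors <- list(donor_spec("a", "adult", 3, seed = 1),
                 donor_spec("b", "fetal", 3, seed = 2))
  m <- cohort_manifest(donors)
  expect_equal(nrow(m), 2)
  expect_equal(sum(m$n_cells), 6)
  expect_error(cohort_manifest(list(donors[[1]], donors[[1]])), "duplicate")
})

test_that("cohort generation round-trips through TIFF and JSON", {
  scene <- tiny_scene(noise_sd = 1)
  donors <- list(donor_spec("a", "adult", 2, seed = 1),
                 donor_spec("b", "fetal", 2, seed = 2))
  out <- withr::local_tempdir()
  res <- generate_cohort(donors, scene, out_dir = out)
  expect_true(all(file.exists(res$manifest$path)))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  rt <- read_video_tiff(res$manifest$path[1], donor_id = "a")
  expect_identical(rt$frames, res$videos[["a"]]$frames)
  gt <- read_ground_truth_json(res$manifest$gt_path[1])
  orig <- res$ground_truth[["a"]]
  expect_equal(gt$cells$cell_id, orig$cells$cell_id)
  # masks survive the run-length round trip
  t1 <- which(vapply(orig$frames, length, 1L) > 0)[1]
  expect_setequal(gt$frames[[t1]][[1]]$pixels, orig$frames[[t1]][[1]]$pixels)
})

test_that("same seeds give byte-identical cohort manifests", {
  scene <- tiny_scene(noise_sd = 1)
  donors <- list(donor_spec("a", "adult", 2), donor_spec("b", "fetal", 2))
  r1 <- generate_cohort(donors, scene, seed = 5, keep_frames = FALSE)
  r2 <- generate_cohort(donors, scene, seed = 5, keep_frames = FALSE)
  expect_identical(r1$manifest, r2$manifest)
  expect_identical(r1$ground_truth, r2$ground_truth)
})
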