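# Largest-shared-area matching, track chaining, clip extraction.

test_that("identical region lists map to the identity pairing", {
  mask <- matrix(FALSE, 20, 20)
  mask[3:6, 3:6] <- TRUE
  mask[12:15, 10:13] <- TRUE
  regs <- mask_regions(mask)
  expect_equal(match_regions(regs, regs), seq_along(regs))
})

test_that("translated region with majority overlap is matched", {
  m1 <- matrix(FALSE, 20, 30)
  m1[5:12, 5:14] <- TRUE
  m2 <- matrix(FALSE, 20, 30)
  m2[5:12, 10:19] <- TRUE   # shifted 5 px, 50% overlap, no competitors
  p <- match_regions(mask_regions(m1), mask_regions(m2))
  expect_equal(p, 1L)
  expect_equal(p, exhaustive_match(mask_regions(m1), mask_regions(m2)))
})

test_that("equal-overlap ties break toward the smaller bbox corner", {
  prev <- matrix(FALSE, 30, 30)
  prev[10:15, 14:17] <- TRUE
  # two disjoint next regions overlapping prev by the same 2x4 strip each
  nxt <- matrix(FALSE, 30, 30)
  nxt[7:11, 14:17] <- TRUE    # overlaps prev rows 10-11
  nxt[14:18, 14:17] <- TRUE   # overlaps prev rows 14-15
  pr <- mask_regions(prev)
  nr <- mask_regions(nxt)
  ov <- vapply(nr, function(r) length(intersect(pr[[1]]$pixels, r$pixels)),
               1L)
  expect_equal(ov[1], ov[2])  # a genuine tie, confirmed by enumeration
  p <- match_regions(pr, nr)
  corners <- t(vapply(nr, function(r) r$bbox[1:2], numeric(2)))
  expect_equal(p, which.min(corners[, 1]))
})

test_that("greedy pairing never claims a next region twice", {
  set.seed(4)
  for (rep in 1:6) {
    m1 <- matrix(runif(400) < 0.4, 20, 20)
    m2 <- m1
    m2[sample(400, 60)] <- !m2[sample(400, 60)]
    p <- match_regions(mask_regions(m1), mask_regions(m2))
    p <- p[!is.na(p)]
    expect_equal(anyDuplicated(p), 0)
  }
})

test_that("tracks follow planted cells without identity switches", {
  scene <- tiny_scene(noise_sd = 0)
  res <- generate_donor_video(scene, donor_spec("d", "adult", 2, seed = 31))
  det <- detect_cells(res$sequence, seed = 1)
  tracks <- build_tracks(det, min_len = 8, donor_id = "d",
                         class_label = "adult")
  expect_length(tracks, 2)
  for (tr in tracks) {
    expect_true(all(diff(tr$frames) == 1))
    cols <- vapply(tr$regions, function(r) r$centroid[2], numeric(1))
    expect_true(all(diff(cols) > 0))  # monotone left-to-right motion
  }
  expect_equal(build_tracks(list(list(), list(), list())), list())
})

test_that("clip windows cut raw pixels and zero-pad outside the frame", {
  frames <- array(0L, dim = c(150, 800, 3))
  set.seed(6)
  frames[, , 1] <- sample.int(255, 150 * 800, TRUE)
  region <- function(r, c) {
    list(area = 60, centroid = c(r, c), bbox = c(r - 3, c - 3, r + 4, c + 4),
         pixels = 1L)
  }
  track <- structure(list(frames = 0L, regions = list(region(75, 400)),
                          track_id = 1, donor_id = "d",
                          class_label = "adult"),
                     class = "cell_track")
  clip <- extract_clip(track, frames, size = 50)
  expect_equal(dim(clip), c(50, 50, 1))
  # interior: exact raw sub-image, 0-based half-open window [50, 100) x ...
  expect_identical(clip[, , 1], frames[51:100, 376:425, 1])
  # 10 px from the left edge: leftmost 15 columns zero
  track$regions <- list(region(75, 10))
  clip2 <- extract_clip(track, frames, size = 50)
  expect_true(all(clip2[, 1:15, 1] == 0))
  expect_identical(clip2[, 16:50, 1], frames[51:100, 1:35, 1])
  track$regions <- list()
  track$frames <- integer(0)
  expect_error(extract_clip(track, frames), "empty")
})

test_that("temporal standardization resamples or pads to length", {
  clip <- array(seq_len(10 * 10 * 5), dim = c(10, 10, 5))
  up <- standardize_clip(clip, 8)
  expect_equal(dim(up)[3], 8)
  expect_identical(up[, , 8], clip[, , 5])  # trailing edge replication
  down <- standardize_clip(array(1, c(10, 10, 20)), 8)
  expect_equal(dim(down)[3], 8)
  expect_identical(standardize_clip(clip, 5), clip)
})

test_that("clip content is invariant to horizontal frame translation", {
  scene <- tiny_scene(noise_sd = 0)
  res <- generate_donor_video(scene, donor_spec("d", "adult", 1, seed = 12))
  f <- res$sequence$frames
  k <- 7L
  shifted <- array(0L, dim = dim(f))
  shifted[, (k + 1):dim(f)[2], ] <- f[, 1:(dim(f)[2] - k), ]
  shifted[, 1:k, ] <- f[, 1, ]  # replicate the wall/background edge
  d1 <- build_tracks(detect_cells(f, seed = 2), min_len = 8,
                     donor_id = "d", class_label = "adult")
  d2 <- build_tracks(detect_cells(shifted, seed = 2), min_len = 8,
                     donor_id = "d", class_label = "adult")
  # compare clips over the frames where the cell is interior in both
  c1 <- extract_clip(d1[[1]], f)
  c2 <- extract_clip(d2[[1]], shifted)
  mid <- intersect(which(d1[[1]]$frames %in% d2[[1]]$frames),
                   5:(dim(c1)[3] - 5))
  expect_gt(length(mid), 3)
  off <- match(d1[[1]]$frames[mid[1]], d2[[1]]$frames) - mid[1]
  for (t in mid[2:4]) expect_identical(c1[, , t], c2[, , t + off])
})

test_that("clip counts equal planted cells meeting the track minimum", {
  scene <- tiny_scene(noise_sd = 0)
  res <- generate_donor_video(scene, donor_spec("d", "fetal", 5, seed = 41))
  det <- detect_cells(res$sequence, seed = 4)
  tracks <- build_tracks(det, min_len = 8, donor_id = "d",
                         class_label = "fetal")
  clips <- extract_clips(tracks, res$sequence, n_frames = 16)
  expect_length(clips, nrow(res$ground_truth$cells))
  for (cl in clips) {
    expect_equal(dim(cl)[1:2], c(50, 50))
    expect_equal(dim(cl)[3], 16)
    expect_equal(attr(cl, "class_label"), "fetal")
    expect_equal(attr(cl, "donor_id"), "d")
  }
})
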