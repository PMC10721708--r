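# Overlap-based multi-object tracking and fixed-size clip extraction.
#
# Regions in consecutive frames are paired by largest shared pixel area
# (exact pixel-set intersection), resolved greedily in descending overlap
# with a deterministic tie-break, and chained into tracks.  Each track is
# turned into a T x 50 x 50 video clip by cutting a window centred on the
# region centroid out of the raw frames, zero-padding outside the frame.

#' Match regions between two consecutive frames by largest shared area
#'
#' Each region of `prev` is paired with the region of `next_` sharing the
#' largest pixel-set intersection.  Pairs are claimed greedily in
#' descending overlap so that no `next_` region is claimed twice; zero
#' overlap never matches.  Ties are broken deterministically toward the
#' candidate region with the smaller `(min_row, min_col)` bounding-box
#' corner (and then the smaller previous-region corner).
#'
#' @param prev,next_ Region lists as returned by [detect_regions()].
#' @return Integer vector of length `length(prev)`: for each previous
#'   region, the index of its matched region in `next_`, or `NA`.
#' @export
match_regions <- function(prev, next_) {
  np <- length(prev)
  nn <- length(next_)
  out <- rep(NA_integer_, np)
  if (np == 0 || nn == 0) return(out)
  cand <- list()
  for (i in seq_len(np)) {
    for (j in seq_len(nn)) {
      ov <- length(intersect(prev[[i]]$pixels, next_[[j]]$pixels))
      if (ov > 0) {
        cand[[length(cand) + 1L]] <- c(i, j, ov,
                                       next_[[j]]$bbox[1], next_[[j]]$bbox[2],
                                       prev[[i]]$bbox[1], prev[[i]]$bbox[2])
      }
    }
  }
  if (length(cand) == 0) return(out)
  cm <- do.call(rbind, cand)
  ord <- order(-cm[, 3], cm[, 4], cm[, 5], cm[, 6], cm[, 7])
  cm <- cm[ord, , drop = FALSE]
  taken_prev <- rep(FALSE, np)
  taken_next <- rep(FALSE, nn)
  for (k in seq_len(nrow(cm))) {
    i <- cm[k, 1]
    j <- cm[k, 2]
    if (taken_prev[i] || taken_next[j]) next
    out[i] <- j
    taken_prev[i] <- TRUE
    taken_next[j] <- TRUE
  }
  out
}

#' Chain per-frame regions into cell tracks
#'
#' Applies [match_regions()] to every consecutive frame pair; a region with
#' no match starts (or ends) a track.  Tracks span strictly consecutive
#' frames with no gaps.
#'
#' @param frames_regions List of per-frame region lists (frame `t` at list
#'   position `t`; frame indices reported 0-based), e.g. the `regions`
#'   component of a [detect_cells()] result.
#' @param min_len Minimum track length in frames; shorter tracks are
#'   dropped (default 8, the slow pathway's frame requirement).
#' @param donor_id,class_label Labels attached to every track.
#' @return List of objects of class `cell_track`: each with `track_id`,
#'   `frames` (0-based indices), `regions` (same length), `donor_id`,
#'   `class_label`.
#' @export
build_tracks <- function(frames_regions, min_len = 8L,
                         donor_id = NA_character_,
                         class_label = NA_character_) {
  if (inherits(frames_regions, "detection_result")) {
    if (is.na(donor_id)) donor_id <- frames_regions$donor_id
    frames_regions <- frames_regions$regions
  }
  TT <- length(frames_regions)
  open <- list()   # active tracks: list(frames, regions)
  done <- list()
  for (t in seq_len(TT)) {
    regs <- frames_regions[[t]]
    if (length(open) > 0) {
      prev_regs <- lapply(open, function(tr) tr$regions[[length(tr$regions)]])
      m <- match_regions(prev_regs, regs)
    } else {
      m <- integer(0)
    }
    next_open <- list()
    claimed <- rep(FALSE, length(regs))
    for (k in seq_along(open)) {
      if (!is.na(m[k])) {
        tr <- open[[k]]
        tr$frames <- c(tr$frames, t - 1L)
        tr$regions[[length(tr$regions) + 1L]] <- regs[[m[k]]]
        next_open[[length(next_open) + 1L]] <- tr
        claimed[m[k]] <- TRUE
      } else {
        done[[length(done) + 1L]] <- open[[k]]
      }
    }
    for (j in seq_along(regs)) {
      if (!claimed[j]) {
        next_open[[length(next_open) + 1L]] <- list(
          frames = t - 1L, regions = list(regs[[j]]))
      }
    }
    open <- next_open
  }
  done <- c(done, open)
  done <- Filter(function(tr) length(tr$frames) >= min_len, done)
  # stable, order-independent presentation: sort by first frame, then
  # first-region bounding box corner
  if (length(done) > 1) {
    key1 <- vapply(done, function(tr) tr$frames[1], numeric(1))
    key2 <- vapply(done, function(tr) tr$regions[[1]]$bbox[2], numeric(1))
    key3 <- vapply(done, function(tr) tr$regions[[1]]$bbox[1], numeric(1))
    done <- done[order(key1, key2, key3)]
  }
  lapply(seq_along(done), function(i) {
    structure(c(done[[i]], list(track_id = i, donor_id = donor_id,
                                class_label = class_label)),
              class = "cell_track")
  })
}

#' Extract the fixed-size video clip of one track
#'
#' For each frame of the track, a `size x size` window centred on the
#' region centroid (rounded to the nearest pixel) is cut from the raw
#' (unsmoothed) frame; window parts outside the frame are zero-filled.
#'
#' @param track A `cell_track`.
#' @param seq The source `frame_sequence` (or plain array).
#' @param size Window side length in px (default 50).
#' @return An object of class `cell_clip`: `size x size x T` integer array
#'   with attributes `track_id`, `donor_id`, `class_label`.
#' @export
extract_clip <- function(track, seq, size = 50L) {
  stopifnot(inherits(track, "cell_track"))
  if (length(track$frames) == 0) stop("empty track")
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  H <- dim(frames)[1]
  W <- dim(frames)[2]
  half <- size %/% 2L
  TT <- length(track$frames)
  clip <- array(0L, dim = c(size, size, TT))
  for (k in seq_len(TT)) {
    ctr <- round(track$regions[[k]]$centroid)  # 0-based (row, col)
    r0 <- ctr[1] - half                        # half-open window [r0, r0+size)
    c0 <- ctr[2] - half
    rr <- seq.int(r0, r0 + size - 1L)          # 0-based source rows
    cc <- seq.int(c0, c0 + size - 1L)
    rok <- rr >= 0 & rr < H
    cok <- cc >= 0 & cc < W
    if (any(rok) && any(cok)) {
      clip[which(rok), which(cok), k] <-
        frames[rr[rok] + 1L, cc[cok] + 1L, track$frames[k] + 1L]
    }
  }
  structure(clip, class = "cell_clip", track_id = track$track_id,
            donor_id = track$donor_id, class_label = track$class_label)
}

#' Standardize a clip to a fixed number of frames
#'
#' Longer clips are uniformly resampled in time; shorter clips are padded
#' by replicating the last frame.  Needed because the two-pathway network
#' requires a fixed clip length divisible by its temporal stride.
#'
#' @param clip A `cell_clip` (or plain `H x W x T` array).
#' @param n_frames Target frame count (default 64).
#' @return The standardized clip, attributes preserved.
#' @export
standardize_clip <- function(clip, n_frames = 64L) {
  TT <- dim(clip)[3]
  if (TT == n_frames) return(clip)
  idx <- if (TT > n_frames) {
    round(seq(1, TT, length.out = n_frames))
  } else {
    c(seq_len(TT), rep(TT, n_frames - TT))
  }
  out <- clip[, , idx, drop = FALSE]
  attributes(out) <- c(list(dim = dim(out)),
                       attributes(clip)[c("class", "track_id", "donor_id",
                                          "class_label")])
  out
}

#' Extract standardized clips for all tracks of a sequence
#'
#' @param tracks List of `cell_track` (from [build_tracks()]).
#' @param seq Source `frame_sequence`.
#' @param size Spatial window size (default 50).
#' @param n_frames Standardized temporal length (default 64); `NULL` keeps
#'   native track lengths.
#' @return List of `cell_clip` objects.
#' @export
extract_clips <- function(tracks, seq, size = 50L, n_frames = 64L) {
  lapply(tracks, function(tr) {
    cl <- extract_clip(tr, seq, size = size)
    if (!is.null(n_frames)) cl <- standardize_clip(cl, n_frames)
    cl
  })
}
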