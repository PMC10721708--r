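# Shared fixtures: a small fast scene, clip generators, and brute-force
# oracles (flood fill, exhaustive overlap matching) kept independent of the
# package's implementation paths.

# A short channel rendered quickly; geometry (walls, taper, constriction)
# preserved.
tiny_scene <- function(...) {
  args <- modifyList(list(
    frame_width = 160L, frame_height = 100L, noise_sd = 0,
    channel_halfwidth = 35, constriction_halfwidth = 14,
    constriction_start = 72L, constriction_end = 88L, taper = 24L,
    cells_per_second = 40, frame_rate = 500, arrival = "uniform"
  ), list(...))
  do.call(scene_params, args)
}

# Moving dark blob clips with a controlled radius; linearly separable by
# size.
blob_clip <- function(radius, seed, n_frames = 16L, size = 50L) {
  set.seed(seed)
  arr <- array(0L, dim = c(size, size, n_frames))
  cy <- size / 2 + runif(1, -3, 3)
  cx <- size / 2 + runif(1, -3, 3)
  for (t in seq_len(n_frames)) {
    img <- matrix(150, size, size)
    d2 <- outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+")
    img[d2 <= radius^2] <- 90
    arr[, , t] <- as.integer(pmin(pmax(round(img + rnorm(size^2, 0, 2)), 0),
                                  255))
  }
  arr
}

blob_dataset <- function(n_per_class, radii = c(6, 7.8), n_frames = 16L) {
  clips <- c(lapply(seq_len(n_per_class), function(i) {
    blob_clip(radii[1], i, n_frames)
  }), lapply(seq_len(n_per_class), function(i) {
    blob_clip(radii[2], 1000 + i, n_frames)
  }))
  list(clips = clips,
       labels = rep(c("small", "large"), each = n_per_class))
}

# Brute-force connected components by repeated flood fill (recursive
# frontier expansion), independent of the package's labelling code.
flood_fill_labels <- function(mask, connectivity = 8L) {
  H <- nrow(mask)
  W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 8) {
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  } else {
    nb <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(W)) {
    for (i in seq_len(H)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      cur <- cur + 1L
      frontier <- matrix(c(i, j), ncol = 2)
      lab[i, j] <- cur
      while (nrow(frontier) > 0) {
        nxt <- NULL
        for (r in seq_len(nrow(frontier))) {
          for (q in seq_len(nrow(nb))) {
            ii <- frontier[r, 1] + nb$dr[q]
            jj <- frontier[r, 2] + nb$dc[q]
            if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
                mask[ii, jj] && lab[ii, jj] == 0L) {
              lab[ii, jj] <- cur
              nxt <- rbind(nxt, c(ii, jj))
            }
          }
        }
        frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 2) else nxt
      }
    }
  }
  lab
}

# Exhaustive best-overlap pairing: enumerate all (prev, next) pixel
# intersections and assign greedily by descending overlap.
exhaustive_match <- function(prev, next_) {
  np <- length(prev)
  nn <- length(next_)
  ov <- matrix(0L, max(np, 1), max(nn, 1))
  for (i in seq_len(np)) {
    for (j in seq_len(nn)) {
      ov[i, j] <- length(intersect(prev[[i]]$pixels, next_[[j]]$pixels))
    }
  }
  out <- rep(NA_integer_, np)
  used <- rep(FALSE, nn)
  repeat {
    best <- which(ov == max(ov), arr.ind = TRUE)
    if (np == 0 || nn == 0 || max(ov) == 0) break
    i <- best[1, 1]
    j <- best[1, 2]
    out[i] <- j
    ov[i, ] <- -1L
    ov[, j] <- -1L
    used[j] <- TRUE
    if (all(ov <= 0)) break
  }
  out
}

# Regions from a plain logical mask without the area filter (for matcher
# tests).
mask_regions <- function(mask) {
  detect_regions(mask, min_area = 0L)
}
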