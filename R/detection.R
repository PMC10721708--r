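# Cell detection by temporal-median background subtraction.
#
# Procedure: each frame is Gaussian-smoothed; a background image is the
# per-pixel median of (up to) 100 randomly sampled smoothed frames; a frame
# is binarized by |smoothed - background| > 5 (strict, sign-symmetric); the
# connected components of the binary mask with pixel area strictly greater
# than 50 are taken as cells.
#
# Coordinate convention everywhere: (row, col), 0-based, bounding boxes
# half-open `[min_row, max_row) x [min_col, max_col)`.

#' Gaussian-smooth a single frame
#'
#' Separable Gaussian filter with edge-replicate boundary handling and
#' kernel radius `ceiling(3 * sigma)`.
#'
#' @param frame Numeric matrix.
#' @param sigma Kernel standard deviation in px; `sigma = 0` returns the
#'   frame unchanged.
#' @return Smoothed numeric matrix of the same shape.
#' @export
gauss_smooth <- function(frame, sigma = 1) {
  stopifnot(is.matrix(frame))
  stopifnot_scalar_number(sigma, "sigma", 0)
  .cpp_gauss_blur(frame * 1.0, sigma)
}

#' Estimate the temporal-median background of a sequence
#'
#' Samples `n` frames uniformly without replacement (all frames if the
#' sequence is shorter), Gaussian-smooths each, and takes the per-pixel
#' median.  Pixels only rarely covered by a moving cell therefore recover
#' their cell-free background value.
#'
#' @param seq A `frame_sequence` (or plain `H x W x T` array).
#' @param n Number of frames to sample (default 100).
#' @param seed Seed for the frame sampling.
#' @param sigma Gaussian smoothing sigma applied to each sampled frame.
#' @return An object of class `median_background`: list with `background`
#'   (numeric matrix), `n_sampled`, and `sample_indices` (0-based frame
#'   indices used).
#' @export
estimate_background <- function(seq, n = 100L, seed = NULL, sigma = 1) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  stopifnot(length(dim(frames)) == 3)
  TT <- dim(frames)[3]
  if (TT == 0) stop("empty frame sequence")
  n_sampled <- min(n, TT)
  idx <- with_seed(seed, sort(sample.int(TT, n_sampled)))
  H <- dim(frames)[1]
  W <- dim(frames)[2]
  stack <- matrix(0, H * W, n_sampled)
  for (k in seq_along(idx)) {
    stack[, k] <- as.vector(gauss_smooth(frames[, , idx[k]] * 1.0, sigma))
  }
  bg <- matrix(.cpp_stack_median(stack), H, W)
  structure(list(background = bg, n_sampled = n_sampled,
                 sample_indices = idx - 1L, sigma = sigma),
            class = "median_background")
}

#' Binarize a frame against a median background
#'
#' Foreground where `|smoothed(frame) - background| > threshold`, with a
#' strict inequality; the absolute value makes the mask symmetric in the
#' sign of the cell contrast.
#'
#' @param frame Numeric matrix (one raw frame).
#' @param background A `median_background` (or plain matrix of the same
#'   shape).
#' @param threshold Intensity threshold (default 5, strict `>`).
#' @param sigma Smoothing sigma applied to the frame before subtraction;
#'   `sigma = 0` disables smoothing.
#' @return Logical matrix mask.
#' @export
binarize <- function(frame, background, threshold = 5, sigma = 1) {
  bg <- if (inherits(background, "median_background")) {
    background$background
  } else background
  if (!all(dim(frame) == dim(bg))) {
    stop("frame and background shapes differ")
  }
  sm <- gauss_smooth(frame * 1.0, sigma)
  abs(sm - bg) > threshold
}

#' Detect cell regions in a binary mask
#'
#' Connected components (4- or 8-connectivity) with pixel area strictly
#' greater than `min_area`, reported sorted by bounding-box `min_col`, then
#' `min_row`.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum area, strict (a component of exactly `min_area`
#'   pixels is discarded).
#' @param connectivity 4 or 8 (default 8).
#' @return List of regions; each region is a list with `area`, `centroid`
#'   (`c(row, col)`, 0-based), `bbox` (`c(min_row, min_col, max_row,
#'   max_col)`, half-open, 0-based) and `pixels` (1-based linear indices
#'   into the mask, an implementation detail used for overlap tracking).
#' @export
detect_regions <- function(mask, min_area = 50L, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(list())
  lab <- .cpp_label_components(mask, as.integer(connectivity))
  H <- nrow(mask)
  nlab <- max(lab)
  regions <- list()
  for (l in seq_len(nlab)) {
    pix <- which(lab == l)
    if (length(pix) <= min_area) next
    rows <- (pix - 1L) %% H
    cols <- (pix - 1L) %/% H
    regions[[length(regions) + 1L]] <- list(
      area = length(pix),
      centroid = c(mean(rows), mean(cols)),
      bbox = c(min(rows), min(cols), max(rows) + 1L, max(cols) + 1L),
      pixels = pix
    )
  }
  if (length(regions) == 0) return(list())
  ord <- order(vapply(regions, function(r) r$bbox[2], numeric(1)),
               vapply(regions, function(r) r$bbox[1], numeric(1)))
  regions[ord]
}

#' Run detection over a whole sequence
#'
#' Convenience wrapper: estimates the background, then binarizes and
#' extracts regions frame by frame.
#'
#' @param seq A `frame_sequence`.
#' @param threshold,min_area,sigma,connectivity Detection parameters, see
#'   [binarize()] and [detect_regions()].
#' @param n_background,seed Background sampling parameters, see
#'   [estimate_background()].
#' @return An object of class `detection_result`: list with `regions` (one
#'   region list per frame), `background` and the parameters used.
#' @export
detect_cells <- function(seq, threshold = 5, min_area = 50L, sigma = 1,
                         connectivity = 8L, n_background = 100L,
                         seed = NULL) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  bg <- estimate_background(frames, n = n_background, seed = seed,
                            sigma = sigma)
  TT <- dim(frames)[3]
  regions <- vector("list", TT)
  for (t in seq_len(TT)) {
    m <- binarize(frames[, , t] * 1.0, bg, threshold = threshold,
                  sigma = sigma)
    regions[[t]] <- detect_regions(m, min_area = min_area,
                                   connectivity = connectivity)
  }
  structure(list(regions = regions, background = bg,
                 threshold = threshold, min_area = min_area,
                 sigma = sigma, connectivity = connectivity,
                 donor_id = if (inherits(seq, "frame_sequence")) seq$donor_id
                            else NA_character_),
            class = "detection_result")
}

#' Tabulate detected regions
#'
#' @param det A `detection_result`.
#' @return Data frame with one row per region: `frame` (0-based),
#'   `area`, `centroid_row`, `centroid_col`, and half-open bounding box
#'   columns (`bbox_min_row`, `bbox_min_col`, `bbox_max_row`,
#'   `bbox_max_col`), all 0-based.
#' @export
regions_to_table <- function(det) {
  stopifnot(inherits(det, "detection_result"))
  rows <- list()
  for (t in seq_along(det$regions)) {
    for (r in det$regions[[t]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t - 1L, area = r$area,
        centroid_row = r$centroid[1], centroid_col = r$centroid[2],
        bbox_min_row = r$bbox[1], bbox_min_col = r$bbox[2],
        bbox_max_row = r$bbox[3], bbox_max_col = r$bbox[4]
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(frame = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      bbox_min_row = integer(0), bbox_min_col = integer(0),
                      bbox_max_row = integer(0), bbox_max_col = integer(0)))
  }
  do.call(rbind, rows)
}
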