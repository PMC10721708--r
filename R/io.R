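# Readers/writers for the pipeline's on-disk formats: multi-page TIFF
# videos, ground-truth JSON (masks stored as row run-lengths, 0-based
# coordinates), region tables and manifests as CSV.

#' Write a frame sequence as a multi-page 8-bit TIFF
#'
#' @param seq A `frame_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  maxval <- 2^seq$bit_depth - 1
  pages <- lapply(seq_len(dim(seq$frames)[3]),
                  function(t) seq$frames[, , t] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a frame sequence
#'
#' @param path TIFF file path.
#' @param donor_id Donor identifier to attach.
#' @param frame_rate Nominal frame rate to attach (metadata only).
#' @return A `frame_sequence` with 8-bit integer frames.
#' @export
read_video_tiff <- function(path, donor_id = NA_character_, frame_rate = 500) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                              length(pages)))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (length(dim(p)) == 3) p <- p[, , 1]  # grayscale stored in channel 1
    frames[, , t] <- as.integer(round(p * 255))
  }
  structure(list(frames = frames, donor_id = donor_id,
                 frame_rate = frame_rate, bit_depth = 8L),
            class = "frame_sequence")
}

# Encode a set of 1-based linear pixel indices (into an H x W frame) as
# 0-based row runs: list of c(row, col_start, col_end), half-open columns.
pixels_to_runs <- function(pixels, H) {
  if (length(pixels) == 0) return(list())
  rows <- (pixels - 1L) %% H
  cols <- (pixels - 1L) %/% H
  ord <- order(rows, cols)
  rows <- rows[ord]
  cols <- cols[ord]
  runs <- list()
  start <- 1L
  for (i in seq_along(rows)) {
    last <- i == length(rows)
    if (last || rows[i + 1L] != rows[i] || cols[i + 1L] != cols[i] + 1L) {
      runs[[length(runs) + 1L]] <- c(rows[start], cols[start], cols[i] + 1L)
      start <- i + 1L
    }
  }
  runs
}

runs_to_pixels <- function(runs, H) {
  if (length(runs) == 0) return(integer(0))
  unlist(lapply(runs, function(r) {
    cols <- seq.int(r[2], r[3] - 1L)
    (r[1] + 1L) + cols * H
  }))
}

#' Write ground truth as JSON
#'
#' Masks are stored as 0-based row run-lengths (`[row, col_start, col_end)`)
#' to keep files small and text-only.
#'
#' @param gt A `ground_truth` object.
#' @param path Output JSON path.
#' @param H Frame height (defaults to the height recorded in the masks'
#'   stride; required, inferred from attribute if present).
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(gt, path, H = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.null(H)) {
    H <- attr(gt, "frame_height")
    if (is.null(H)) {
      # infer from the largest seen linear index is unsafe; require explicit
      # height when masks exist and attribute is missing
      allpix <- unlist(lapply(gt$frames, function(fr) {
        lapply(fr, function(e) e$pixels)
      }))
      H <- if (length(allpix)) attr(gt, "frame_height") else 1L
      if (is.null(H)) stop("frame height needed to serialize masks; pass H")
    }
  }
  frames <- lapply(gt$frames, function(fr) {
    lapply(fr, function(e) {
      list(cell_id = e$cell_id, centroid = round(e$centroid, 3),
           mask_runs = pixels_to_runs(e$pixels, H))
    })
  })
  obj <- list(donor_id = gt$donor_id, frame_height = H,
              cells = gt$cells, frames = frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth JSON written by [write_ground_truth_json()]
#'
#' @param path JSON path.
#' @return A `ground_truth` object.
#' @export
read_ground_truth_json <- function(path) {
  obj <- jsonlite::read_json(path)
  H <- obj$frame_height
  frames <- lapply(obj$frames, function(fr) {
    lapply(fr, function(e) {
      runs <- lapply(e$mask_runs, function(r) as.integer(unlist(r)))
      list(cell_id = e$cell_id,
           centroid = as.numeric(unlist(e$centroid)),
           pixels = as.integer(runs_to_pixels(runs, H)))
    })
  })
  cells <- do.call(rbind, lapply(obj$cells, function(r) {
    data.frame(cell_id = r$cell_id, class_label = r$class_label,
               area_target = r$area_target, entry_frame = r$entry_frame,
               exit_frame = r$exit_frame, stringsAsFactors = FALSE)
  }))
  structure(list(cells = cells, frames = frames, donor_id = obj$donor_id),
            class = "ground_truth")
}
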