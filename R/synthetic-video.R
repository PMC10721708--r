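# Synthetic microfluidic deformation videos with planted ground truth.
#
# The generator emulates the recordings the analysis was designed for:
# a static channel background (straight walls narrowing into a central
# constriction) plus Gaussian sensor noise, with cells entering on the left,
# translating with constant speed, elongating while inside the constriction
# and relaxing exponentially after leaving it.  Two classes differ in mean
# projected area (fetal/adult area ratio 1.21^(2/3), the projected-area
# consequence of a +21% volume difference under isotropic scaling) and in
# deformation dynamics.  A log-normal multiplicative donor effect on area
# and deformation amplitude, drawn once per donor, creates the within-donor
# correlation that donor-disjoint splitting exists to guard against.

#' Scene parameters for synthetic channel videos
#'
#' Geometry and imaging parameters of the rendered scene.  Defaults match
#' the recording conditions the pipeline targets: 800x150 px 8-bit frames
#' at a nominal 500 frames/s with a throughput of about 2 cells/s.
#'
#' @param frame_height,frame_width Frame size in pixels.
#' @param bit_depth Bits per pixel (intensities span `[0, 2^bit_depth - 1]`).
#' @param frame_rate Frames per second (nominal; controls the mapping from
#'   `cells_per_second` to per-frame arrival rate).
#' @param background_level Intensity of the open channel background.
#' @param wall_level Intensity of the static channel walls.
#' @param noise_sd Gaussian sensor noise standard deviation (intensity units).
#' @param channel_halfwidth Channel half-height in pixels outside the
#'   constriction (distance from centerline to wall).
#' @param constriction_halfwidth Channel half-height inside the constriction.
#' @param constriction_start,constriction_end Column range (0-based,
#'   half-open) of the constricted segment; defaults to the central tenth of
#'   the frame.
#' @param taper Length in columns of the linear taper on both sides of the
#'   constriction.
#' @param cells_per_second Mean cell throughput.
#' @param arrival `"poisson"` for exponential inter-arrival times,
#'   `"uniform"` for deterministic equal spacing (useful when planted cells
#'   must never co-occur or touch).
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(frame_height = 150L, frame_width = 800L,
                         bit_depth = 8L, frame_rate = 500,
                         background_level = 180, wall_level = 90,
                         noise_sd = 2,
                         channel_halfwidth = 55,
                         constriction_halfwidth = 20,
                         constriction_start = NULL, constriction_end = NULL,
                         taper = 40,
                         cells_per_second = 2,
                         arrival = c("poisson", "uniform")) {
  stopifnot_scalar_number(frame_height, "frame_height", 1)
  stopifnot_scalar_number(frame_width, "frame_width", 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)
  stopifnot_scalar_number(frame_rate, "frame_rate", 0, strict_min = TRUE)
  stopifnot_scalar_number(cells_per_second, "cells_per_second", 0,
                          strict_min = TRUE)
  if (constriction_halfwidth >= channel_halfwidth) {
    stop("constriction_halfwidth must be smaller than channel_halfwidth")
  }
  if (2 * channel_halfwidth >= frame_height) {
    stop("channel (2 * channel_halfwidth) does not fit into frame_height")
  }
  if (is.null(constriction_start)) {
    constriction_start <- round(frame_width * 0.45)
  }
  if (is.null(constriction_end)) {
    constriction_end <- round(frame_width * 0.55)
  }
  if (constriction_start >= constriction_end ||
      constriction_start < taper ||
      constriction_end + taper > frame_width) {
    stop("constriction range (with taper) must lie inside the frame")
  }
  structure(list(
    frame_height = as.integer(frame_height),
    frame_width = as.integer(frame_width),
    bit_depth = as.integer(bit_depth),
    frame_rate = frame_rate,
    background_level = background_level,
    wall_level = wall_level,
    noise_sd = noise_sd,
    channel_halfwidth = channel_halfwidth,
    constriction_halfwidth = constriction_halfwidth,
    constriction_start = constriction_start,
    constriction_end = constriction_end,
    taper = taper,
    cells_per_second = cells_per_second,
    arrival = match.arg(arrival)
  ), class = "scene_params")
}

#' Fetal/adult projected-area ratio implied by a volume ratio
#'
#' Converts a cell volume ratio into the projected (2-D) area ratio under
#' isotropic scaling: `ratio_area = ratio_volume^(2/3)`.  The default volume
#' ratio of 1.21 (fetal volume 21% above adult) gives an area ratio of about
#' 1.136.
#'
#' @param volume_ratio Fetal/adult mean volume ratio.
#' @return The implied projected-area ratio.
#' @export
fetal_adult_area_ratio <- function(volume_ratio = 1.21) {
  stopifnot_scalar_number(volume_ratio, "volume_ratio", 0, strict_min = TRUE)
  volume_ratio^(2 / 3)
}

#' Per-class cell appearance and dynamics parameters
#'
#' @param projected_area_mean Mean projected cell area in px^2.  Must exceed
#'   the downstream detection area threshold (50 px^2).
#' @param projected_area_cv Coefficient of variation of per-cell areas
#'   (log-normal).
#' @param deformation_amplitude Elongation factor (major/minor aspect ratio)
#'   reached inside the constriction; must be >= 1.
#' @param deformation_relaxation Relaxation time constant in frames for the
#'   exponential return to a circular outline after the constriction.
#' @param contrast Signed intensity offset of the cell relative to
#'   background; negative renders cells darker than background.
#' @param speed_px_per_frame Horizontal cell speed in px/frame.
#' @return An object of class `class_params`.
#' @export
class_params <- function(projected_area_mean = 120,
                         projected_area_cv = 0.1,
                         deformation_amplitude = 1.3,
                         deformation_relaxation = 6,
                         contrast = -40,
                         speed_px_per_frame = 8) {
  stopifnot_scalar_number(projected_area_mean, "projected_area_mean", 50,
                          strict_min = TRUE)
  stopifnot_scalar_number(projected_area_cv, "projected_area_cv", 0)
  stopifnot_scalar_number(deformation_amplitude, "deformation_amplitude", 1)
  stopifnot_scalar_number(deformation_relaxation, "deformation_relaxation", 0,
                          strict_min = TRUE)
  stopifnot_scalar_number(speed_px_per_frame, "speed_px_per_frame", 0,
                          strict_min = TRUE)
  structure(list(
    projected_area_mean = projected_area_mean,
    projected_area_cv = projected_area_cv,
    deformation_amplitude = deformation_amplitude,
    deformation_relaxation = deformation_relaxation,
    contrast = contrast,
    speed_px_per_frame = speed_px_per_frame
  ), class = "class_params")
}

#' Default class parameters for fetal and adult red blood cells
#'
#' Adult cells default to a projected area of 120 px^2 and a deformation
#' amplitude of 1.3; fetal cells are larger by the projected-area ratio
#' [fetal_adult_area_ratio()] (about +13.6%, the 2-D consequence of a +21%
#' volume difference) and deform more (amplitude 1.6, slower relaxation),
#' reflecting their smaller extensional and bending moduli.
#'
#' @param area_ratio Fetal/adult projected-area ratio override.
#' @return Named list with `class_params` entries `fetal` and `adult`.
#' @export
rbc_class_defaults <- function(area_ratio = fetal_adult_area_ratio()) {
  adult <- class_params()
  fetal <- class_params(
    projected_area_mean = adult$projected_area_mean * area_ratio,
    deformation_amplitude = 1.6,
    deformation_relaxation = 9
  )
  list(fetal = fetal, adult = adult)
}

#' Specification of one synthetic donor recording
#'
#' @param donor_id Unique donor identifier (character).
#' @param class_label `"fetal"` or `"adult"`; every cell of the donor
#'   carries this label.
#' @param n_cells Number of cells in the recording (>= 0).
#' @param donor_effect_sd Standard deviation (log scale) of the log-normal
#'   multiplicative donor effect applied once per donor to mean projected
#'   area and to the deformation amplitude excess.
#' @param seed Integer seed for this donor's randomness; if `NA` it is
#'   derived from the cohort seed in [generate_cohort()].
#' @return An object of class `donor_spec`.
#' @export
donor_spec <- function(donor_id, class_label = c("fetal", "adult"),
                       n_cells = 150L, donor_effect_sd = 0.05, seed = NA) {
  class_label <- match.arg(class_label)
  stopifnot_scalar_number(n_cells, "n_cells", 0)
  stopifnot_scalar_number(donor_effect_sd, "donor_effect_sd", 0)
  structure(list(
    donor_id = as.character(donor_id),
    class_label = class_label,
    n_cells = as.integer(n_cells),
    donor_effect_sd = donor_effect_sd,
    seed = if (is.na(seed)) NA_integer_ else as.integer(seed)
  ), class = "donor_spec")
}

# Channel half-height as a function of (0-based) column index.
channel_halfwidth_profile <- function(scene, cols) {
  cs <- scene$constriction_start
  ce <- scene$constriction_end
  tp <- scene$taper
  hw0 <- scene$channel_halfwidth
  hw1 <- scene$constriction_halfwidth
  hw <- rep(hw0, length(cols))
  ramp_in <- cols >= cs - tp & cols < cs
  hw[ramp_in] <- hw0 - (hw0 - hw1) * (cols[ramp_in] - (cs - tp)) / tp
  hw[cols >= cs & cols < ce] <- hw1
  ramp_out <- cols >= ce & cols < ce + tp
  hw[ramp_out] <- hw1 + (hw0 - hw1) * (cols[ramp_out] - ce) / tp
  hw
}

# Static background (walls + channel) for a scene, without noise.
render_background <- function(scene) {
  H <- scene$frame_height
  W <- scene$frame_width
  centre <- (H - 1) / 2
  hw <- channel_halfwidth_profile(scene, seq_len(W) - 1)
  bg <- matrix(scene$background_level, H, W)
  rows <- seq_len(H) - 1
  for (j in seq_len(W)) {
    wall <- abs(rows - centre) > hw[j]
    bg[wall, j] <- scene$wall_level
  }
  bg
}

# Elongation factor at horizontal position x for a given class/donor
# parameter set (function of position only: ramp in across the taper,
# full amplitude inside, exponential relaxation measured in frames after
# the constriction exit).
elongation_at <- function(x, scene, amplitude, relaxation, speed) {
  cs <- scene$constriction_start
  ce <- scene$constriction_end
  tp <- scene$taper
  if (x < cs - tp) return(1)
  if (x < cs) return(1 + (amplitude - 1) * (x - (cs - tp)) / tp)
  if (x < ce) return(amplitude)
  frames_out <- (x - ce) / speed
  1 + (amplitude - 1) * exp(-frames_out / relaxation)
}

# Rasterize one elliptical cell into `img` (modified in place by value
# semantics: returns list(img, pixels, centroid)).  Centre (cy, cx) 0-based,
# semi-axes (ax horizontal, ay vertical), signed contrast, Gaussian edge
# softening of about 1 px.
render_cell <- function(img, cy, cx, ax, ay, contrast, edge = 0.8) {
  H <- nrow(img)
  W <- ncol(img)
  r0 <- max(0L, floor(cy - ay - 3))
  r1 <- min(H - 1L, ceiling(cy + ay + 3))
  c0 <- max(0L, floor(cx - ax - 3))
  c1 <- min(W - 1L, ceiling(cx + ax + 3))
  if (r0 > r1 || c0 > c1) {
    return(list(img = img, pixels = integer(0), centroid = NULL))
  }
  rr <- r0:r1
  cc <- c0:c1
  dy <- (rr - cy) / ay
  dx <- (cc - cx) / ax
  rho <- sqrt(outer(dy^2, dx^2, "+"))
  cover <- stats::pnorm((1 - rho) * min(ax, ay) / edge)
  sub <- img[rr + 1L, cc + 1L, drop = FALSE]
  img[rr + 1L, cc + 1L] <- sub + contrast * cover
  inside <- rho <= 1
  if (!any(inside)) {
    return(list(img = img, pixels = integer(0), centroid = NULL))
  }
  idx <- which(inside, arr.ind = TRUE)
  rows0 <- rr[idx[, 1]]
  cols0 <- cc[idx[, 2]]
  pixels <- (rows0 + 1L) + (cols0) * H  # 1-based linear index into H x W
  list(img = img, pixels = as.integer(pixels),
       centroid = c(mean(rows0), mean(cols0)))
}

#' Generate one donor's synthetic video with ground truth
#'
#' Renders `donor$n_cells` cells translating left to right through the
#' channel, elongating inside the constriction and relaxing afterwards,
#' on a static background with Gaussian sensor noise, quantized to the
#' scene's bit depth.  All randomness derives from `donor$seed`.
#'
#' @param scene A [scene_params()] object.
#' @param donor A [donor_spec()] object with a non-`NA` seed.
#' @param classes Named list of [class_params()] for `"fetal"` and
#'   `"adult"`; defaults to [rbc_class_defaults()].
#' @param n_frames Number of frames; defaults to the smallest count that
#'   lets every spawned cell traverse the full frame.
#' @return A list with components `sequence` (class `frame_sequence`: 8-bit
#'   frames as an `H x W x T` integer array plus metadata) and
#'   `ground_truth` (class `ground_truth`: per-frame planted masks and
#'   centroids, per-cell class labels and entry/exit frames; all
#'   coordinates 0-based).
#' @export
generate_donor_video <- function(scene, donor,
                                 classes = rbc_class_defaults(),
                                 n_frames = NULL) {
  stopifnot(inherits(scene, "scene_params"), inherits(donor, "donor_spec"))
  if (is.na(donor$seed)) {
    stop("donor seed must be set (directly or via generate_cohort)")
  }
  cp <- classes[[donor$class_label]]
  if (is.null(cp)) stop("no class_params for label ", donor$class_label)

  with_seed(donor$seed, {
    # donor-level multiplicative perturbation, drawn once
    area_factor <- exp(rnorm(1, 0, donor$donor_effect_sd))
    amp_factor <- exp(rnorm(1, 0, donor$donor_effect_sd))
    area_mean <- cp$projected_area_mean * area_factor
    amplitude <- 1 + (cp$deformation_amplitude - 1) * amp_factor

    n <- donor$n_cells
    speed <- cp$speed_px_per_frame
    # per-cell draws (before any frame-dependent randomness)
    areas <- area_mean * exp(rnorm(n, 0, cp$projected_area_cv))
    r0 <- sqrt(areas / pi)
    max_r <- if (n > 0) max(r0) else sqrt(area_mean / pi)
    # reject geometrically impossible parameters
    if (max_r / sqrt(amplitude) + 1 > scene$constriction_halfwidth) {
      stop("cell diameter exceeds the constriction height: reduce ",
           "projected_area_mean or widen constriction_halfwidth")
    }
    if (max_r + 1 > scene$channel_halfwidth) {
      stop("cell diameter exceeds the channel height: reduce ",
           "projected_area_mean or widen channel_halfwidth")
    }

    frames_per_cell <- scene$frame_rate / scene$cells_per_second
    t0 <- if (n == 0) {
      numeric(0)
    } else if (scene$arrival == "poisson") {
      cumsum(rexp(n, rate = 1 / frames_per_cell))
    } else {
      frames_per_cell * seq_len(n)
    }
    dyfrac <- if (n > 0) runif(n, -0.4, 0.4) else numeric(0)

    W <- scene$frame_width
    H <- scene$frame_height
    centre <- (H - 1) / 2
    x_start <- -2 * max_r - 2
    crossing <- (W + 4 * max_r + 4) / speed
    if (is.null(n_frames)) {
      n_frames <- if (n == 0) 16L else as.integer(ceiling(max(t0) + crossing) + 2L)
    }
    n_frames <- as.integer(n_frames)

    bg <- render_background(scene)
    maxval <- 2^scene$bit_depth - 1
    frames <- array(0L, dim = c(H, W, n_frames))
    gt_frames <- vector("list", n_frames)
    entry <- rep(NA_integer_, n)
    exit <- rep(NA_integer_, n)

    for (t in seq_len(n_frames)) {
      img <- bg
      entries <- list()
      if (n > 0) {
        for (i in seq_len(n)) {
          dt <- (t - 1) - t0[i]
          if (dt < 0) next
          cx <- x_start + speed * dt
          if (cx - 2 * max_r - 3 > W) next
          e <- elongation_at(cx, scene, amplitude, cp$deformation_relaxation,
                             speed)
          ax <- r0[i] * sqrt(e)
          ay <- r0[i] / sqrt(e)
          hw_here <- channel_halfwidth_profile(scene, max(0, min(W - 1, cx)))
          cy <- centre + dyfrac[i] * max(0, hw_here - ay - 2)
          res <- render_cell(img, cy, cx, ax, ay, cp$contrast)
          img <- res$img
          if (length(res$pixels) > 0) {
            f0 <- t - 1L  # 0-based frame index
            if (is.na(entry[i])) entry[i] <- f0
            exit[i] <- f0
            entries[[length(entries) + 1L]] <- list(
              cell_id = i, centroid = res$centroid, pixels = res$pixels)
          }
        }
      }
      frames[, , t] <- .cpp_finalize_frame(img, scene$noise_sd, maxval)
      gt_frames[[t]] <- entries
    }

    seq_obj <- structure(list(
      frames = frames, donor_id = donor$donor_id,
      frame_rate = scene$frame_rate, bit_depth = scene$bit_depth
    ), class = "frame_sequence")
    keep <- !is.na(entry)
    gt <- structure(list(
      cells = data.frame(
        cell_id = seq_len(n)[keep],
        class_label = rep(donor$class_label, sum(keep)),
        area_target = areas[keep],
        entry_frame = entry[keep],
        exit_frame = exit[keep],
        stringsAsFactors = FALSE
      ),
      frames = gt_frames,
      donor_id = donor$donor_id
    ), class = "ground_truth")
    attr(gt, "frame_height") <- H
    list(sequence = seq_obj, ground_truth = gt)
  })
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> donor %s: %d frames of %dx%d px (%d-bit)\n",
              x$donor_id, d[3], d[1], d[2], x$bit_depth))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> donor %s: %d cells over %d frames\n",
              x$donor_id, nrow(x$cells), length(x$frames)))
  invisible(x)
}

#' Build a cohort manifest from donor specifications
#'
#' @param donors List of [donor_spec()] objects with unique `donor_id`s.
#' @return A data frame with columns `donor_id`, `class`, `n_cells`, `seed`,
#'   `path`, `gt_path` (paths `NA` until written by [generate_cohort()]).
#' @export
cohort_manifest <- function(donors) {
  stopifnot(length(donors) > 0)
  ids <- vapply(donors, function(d) d$donor_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate donor_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(
    donor_id = ids,
    class = vapply(donors, function(d) d$class_label, character(1)),
    n_cells = vapply(donors, function(d) d$n_cells, integer(1)),
    seed = vapply(donors, function(d) d$seed, integer(1)),
    path = NA_character_,
    gt_path = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Generate a cohort of donor videos
#'
#' One video and ground-truth record per donor.  Donors with an `NA` seed
#' get one derived deterministically from `seed` and their position, so a
#' fixed `(donors, scene, seed)` triple reproduces the cohort exactly.
#'
#' @param donors List of [donor_spec()] objects (unique ids).
#' @param scene A [scene_params()] object.
#' @param classes Named list of [class_params()] per class label.
#' @param seed Cohort seed used to fill in missing donor seeds.
#' @param out_dir If non-`NULL`, writes one multi-page TIFF and one ground
#'   truth JSON per donor plus `manifest.csv` into this directory.
#' @return List with `manifest` (data frame), `videos` (named list of
#'   `frame_sequence`, unless `keep_frames = FALSE`), and `ground_truth`
#'   (named list).
#' @param keep_frames Keep rendered frames in memory (set `FALSE` to only
#'   write files).
#' @export
generate_cohort <- function(donors, scene, classes = rbc_class_defaults(),
                            seed = NULL, out_dir = NULL, keep_frames = TRUE) {
  manifest <- cohort_manifest(donors)
  videos <- list()
  gts <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(donors)) {
    d <- donors[[i]]
    if (is.na(d$seed)) {
      if (is.null(seed)) {
        stop("donor ", d$donor_id, " has no seed and no cohort seed given")
      }
      d$seed <- derive_seed(seed, i)
      manifest$seed[i] <- d$seed
    }
    res <- generate_donor_video(scene, d, classes)
    if (!is.null(out_dir)) {
      vp <- file.path(out_dir, paste0(d$donor_id, ".tiff"))
      gp <- file.path(out_dir, paste0(d$donor_id, "_truth.json"))
      write_video_tiff(res$sequence, vp)
      write_ground_truth_json(res$ground_truth, gp)
      manifest$path[i] <- vp
      manifest$gt_path[i] <- gp
    }
    if (keep_frames) videos[[d$donor_id]] <- res$sequence
    gts[[d$donor_id]] <- res$ground_truth
  }
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(manifest = manifest, videos = videos, ground_truth = gts)
}
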