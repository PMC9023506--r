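#' Select the analysis channel for a stimulus
#'
#' The image analysis works in the color channel in which the visual
#' stimulus and the projected background have the most similar
#' intensities, so the moving lines vanish from the difference images:
#' the channel minimizing `|stimulus_c - background_c|`, ties broken by
#' the lowest channel index. With no stimulus all differences are zero
#' and the first channel is used.
#'
#' @param frame_rgb A `h x w x 3` array (only its channel count is
#'   checked; may be `NULL`).
#' @param stimulus_rgb Nominal stimulus RGB triple (background triple
#'   when no stimulus is shown).
#' @param background_rgb Background RGB triple.
#' @return Channel index in 1..3 (R's 1-based convention; the first
#'   channel is the red one).
#' @examples
#' select_channel(NULL, c(255, 0, 0), c(210, 210, 210)) # 1 (red)
#' select_channel(NULL, c(0, 0, 230), c(210, 210, 210)) # 3 (blue)
#' @export
select_channel <- function(frame_rgb, stimulus_rgb, background_rgb) {
  if (!is.null(frame_rgb)) {
    if (length(dim(frame_rgb)) != 3L || dim(frame_rgb)[3] != 3L) {
      stop("frame must have 3 channels", call. = FALSE)
    }
  }
  stopifnot(length(stimulus_rgb) == 3L, length(background_rgb) == 3L)
  which.min(abs(as.numeric(stimulus_rgb) - as.numeric(background_rgb)))
}

#' Frame-differencing mask
#'
#' Subtracting subsequent images removes the static background and
#' highlights larvae that move; the threshold is applied inclusively
#' (a difference of exactly 40 counts). `mode = "absolute"` marks
#' `|curr - prev| >= threshold` (detects both the vacated and the newly
#' occupied position); `mode = "onesided"` marks `prev - curr >=
#' threshold`, i.e. pixels that got darker — the newly occupied position
#' of a dark larva on the light background, as in an image-processing
#' environment that clamps negative differences to zero.
#'
#' @param prev_channel,curr_channel Numeric matrices (same dimensions),
#'   one color channel each.
#' @param threshold Inclusive threshold (default 40 on the 0-255 scale).
#' @param mode `"absolute"` or `"onesided"`.
#' @return Logical matrix.
#' @export
difference_mask <- function(prev_channel, curr_channel, threshold = 40,
                            mode = c("absolute", "onesided")) {
  mode <- match.arg(mode)
  if (!identical(dim(prev_channel), dim(curr_channel))) {
    stop("frame dimension mismatch", call. = FALSE)
  }
  if (mode == "absolute") {
    abs(curr_channel - prev_channel) >= threshold
  } else {
    (prev_channel - curr_channel) >= threshold
  }
}

#' Measure a well's detection in a difference mask
#'
#' Area = number of set pixels inside the circular ROI; centroid = their
#' mean (row, col); an empty ROI yields area 0 and no centroid.
#'
#' @param mask Logical matrix from [difference_mask()].
#' @param roi One ROI row (data.frame with `cx`, `cy`, `radius_px`), or a
#'   list with those fields.
#' @return List with `area_px` and `centroid` (`c(row, col)` or `NULL`).
#' @export
measure_well <- function(mask, roi) {
  h <- nrow(mask)
  w <- ncol(mask)
  if (roi$cy - roi$radius_px < 0 || roi$cy + roi$radius_px > h + 1 ||
    roi$cx - roi$radius_px < 0 || roi$cx + roi$radius_px > w + 1) {
    stop("ROI outside image bounds", call. = FALSE)
  }
  idx <- roi_pixels(roi, h, w)
  set <- idx[mask[idx$lin], , drop = FALSE]
  if (nrow(set) == 0L) {
    return(list(area_px = 0L, centroid = NULL))
  }
  list(
    area_px = nrow(set),
    centroid = c(row = mean(set$row), col = mean(set$col))
  )
}

# Pixel coordinates inside a circular ROI (centers at integer - 0.5).
roi_pixels <- function(roi, h, w) {
  rows <- max(1L, floor(roi$cy - roi$radius_px)):min(h, ceiling(roi$cy + roi$radius_px))
  cols <- max(1L, floor(roi$cx - roi$radius_px)):min(w, ceiling(roi$cx + roi$radius_px))
  g <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
  keep <- (g$row - 0.5 - roi$cy)^2 + (g$col - 0.5 - roi$cx)^2 <= roi$radius_px^2
  g <- g[keep, , drop = FALSE]
  g$lin <- g$row + (g$col - 1L) * h
  g
}

#' Movement call from a detection
#'
#' @param det Detection from [measure_well()].
#' @param min_area_px Minimum changed area (inclusive) to call a
#'   movement; default 3 px.
#' @return Logical.
#' @export
call_movement <- function(det, min_area_px = 3L) {
  stopifnot(min_area_px >= 1L)
  det$area_px >= min_area_px
}

#' Update the "up" location state
#'
#' The location state is evaluated after each movement — the larva is
#' "up" when the detection centroid lies in the upper half of the well
#' (centroid row strictly above the boundary row; a centroid exactly on
#' the boundary counts as lower half) — and carried forward between
#' movements. Before the first movement the state is undefined (`NA`).
#'
#' @param prev_up Previous state (`TRUE`/`FALSE`/`NA`).
#' @param det Detection from [measure_well()].
#' @param moved Movement call for this frame.
#' @param roi ROI row with `boundary_row`.
#' @return Updated state.
#' @export
update_location <- function(prev_up, det, moved, roi) {
  if (!moved) {
    return(prev_up)
  }
  if (is.null(det$centroid)) {
    stop("movement without a centroid", call. = FALSE)
  }
  unname(det$centroid["row"] < roi$boundary_row)
}

#' Tracking configuration
#'
#' @param threshold Differencing threshold (default 40).
#' @param min_area_px Minimum changed area for a movement call (default
#'   3).
#' @param diff_mode Mask mode for movement detection, `"absolute"`
#'   (default; detects vacated and occupied positions) or `"onesided"`.
#' @param centroid_mode Where the location centroid is measured after a
#'   movement call: `"body"` (default) uses the dark body pixels of the
#'   current frame inside the ROI (below `body_threshold`; in the
#'   selected channel only the larva is dark, so this is its position
#'   even when old and new body positions overlap); `"dark"` uses the
#'   newly darkened one-sided difference component (the new position
#'   when the displacement exceeds the body size); `"mask"` uses the
#'   movement mask itself.
#' @param body_threshold Intensity below which a pixel counts as larva
#'   body for `centroid_mode = "body"` (default 135, halfway between the
#'   body at ~60 and the background at 210).
#' @return List of class `track_config`.
#' @export
track_config <- function(threshold = 40, min_area_px = 3L,
                         diff_mode = c("absolute", "onesided"),
                         centroid_mode = c("body", "dark", "mask"),
                         body_threshold = 135) {
  structure(
    list(
      threshold = threshold, min_area_px = min_area_px,
      diff_mode = match.arg(diff_mode),
      centroid_mode = match.arg(centroid_mode),
      body_threshold = body_threshold
    ),
    class = "track_config"
  )
}

#' Track larvae across an image sequence
#'
#' Re-implements the plate-video analysis: for every pair of subsequent
#' frames, selects the analysis channel for the active period's stimulus,
#' computes the difference mask, and measures area, centroid, movement
#' and location state for every well. One observation row is produced per
#' well per frame pair (`wells x (n - 1)` rows; the first frame has no
#' predecessor). Results do not depend on the well processing order.
#'
#' @param frames The image sequence: a list of `h x w x 3` arrays, a
#'   directory of PNG frames (lexicographic order), or a `function(i)`
#'   returning the 1-based i-th frame (then `n_images` is required).
#' @param rois ROI map from [make_rois()] or [read_rois_csv()].
#' @param schedule The `assay_schedule` (frame i of the sequence is
#'   schedule frame `i - 1`).
#' @param config A [track_config()].
#' @param n_images Number of frames when `frames` is a function.
#' @param start_frame Schedule frame index of the first image (default 0;
#'   set this when tracking a subsequence of a recording).
#' @return Data.frame: `well`, `frame` (0-based schedule index of the
#'   current frame), `period`, `moved`, `up`, `area_px`, `centroid_row`,
#'   `centroid_col`.
#' @export
track_frames <- function(frames, rois, schedule, config = track_config(),
                         n_images = NULL, start_frame = 0L) {
  get_frame <- frame_getter(frames)
  if (is.null(n_images)) n_images <- attr(get_frame, "n")
  if (is.null(n_images)) {
    stop("n_images is required when frames is a function", call. = FALSE)
  }
  if (n_images < 2L) stop("need at least 2 frames", call. = FALSE)
  if (start_frame + n_images > n_frames(schedule)) {
    stop("more frames than the schedule has", call. = FALSE)
  }
  nw <- nrow(rois)
  first <- get_frame(1L)
  h <- dim(first)[1]
  w <- dim(first)[2]
  if (length(dim(first)) != 3L || dim(first)[3] != 3L) {
    stop("frames must have 3 channels", call. = FALSE)
  }
  pix <- lapply(seq_len(nw), function(i) roi_pixels(rois[i, ], h, w))

  res <- vector("list", n_images - 1L)
  up_state <- rep(NA, nw)
  prev <- first
  prev_period <- -1L
  ch <- 1L
  for (t in 2:n_images) {
    curr <- get_frame(t)
    f0 <- start_frame + t - 1L # schedule frame index of the current image
    per <- period_of_frame(schedule, f0)
    if (per$index != prev_period) {
      stim <- if (!is.null(per$visual)) per$visual$color_rgb else schedule$background_rgb
      ch <- select_channel(curr, stim, schedule$background_rgb)
      prev_period <- per$index
    }
    pc <- prev[, , ch]
    cc <- curr[, , ch]
    move_mask <- difference_mask(pc, cc, config$threshold, config$diff_mode)
    loc_mask <- switch(config$centroid_mode,
      body = cc < config$body_threshold,
      dark = difference_mask(pc, cc, config$threshold, "onesided"),
      mask = move_mask
    )
    rows <- data.frame(
      well = rois$well, frame = f0, period = per$index,
      moved = NA, up = NA, area_px = NA_integer_,
      centroid_row = NA_real_, centroid_col = NA_real_
    )
    for (i in seq_len(nw)) {
      lin <- pix[[i]]$lin
      area <- sum(move_mask[lin])
      moved <- area >= config$min_area_px
      cr <- cc_col <- NA_real_
      if (moved) {
        use <- loc_mask[lin]
        if (!any(use)) use <- move_mask[lin]
        cr <- mean(pix[[i]]$row[use] - 0.5)
        cc_col <- mean(pix[[i]]$col[use] - 0.5)
        up_state[i] <- cr < rois$boundary_row[i]
      }
      rows$moved[i] <- moved
      rows$up[i] <- up_state[i]
      rows$area_px[i] <- area
      rows$centroid_row[i] <- cr
      rows$centroid_col[i] <- cc_col
    }
    res[[t - 1L]] <- rows
    prev <- curr
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

frame_getter <- function(frames) {
  if (is.function(frames)) {
    return(frames)
  }
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames)) {
    paths <- sort(list.files(frames, pattern = "\\.png$", full.names = TRUE))
    f <- function(i) {
      img <- png::readPNG(paths[i])
      img * 255
    }
    attr(f, "n") <- length(paths)
    return(f)
  }
  if (is.list(frames)) {
    f <- function(i) frames[[i]]
    attr(f, "n") <- length(frames)
    return(f)
  }
  stop("frames must be a list of arrays, a PNG directory, or a function",
    call. = FALSE
  )
}

#' The 15-column per-well observation table
#'
#' The analysis logs, for every well in every image, information on the
#' image, the well, larval movement and larval location — 15 columns:
#' image name, plate, well id, row, column, frame index, period, analysis
#' channel, changed area, centroid row/col, movement call, location
#' state, and the well-centered position in mm. A full four-plate, 3-h
#' recording has 384 x 1800 = 691,200 such rows.
#'
#' @param obs Tracking output ([track_frames()]) merged with an ROI map,
#'   or any data.frame carrying the needed columns.
#' @param rois ROI map (for plate/row/col and mm conversion).
#' @param path TSV path.
#' @param image_prefix Prefix used to form image names.
#' @return The path, invisibly.
#' @export
write_results_file <- function(obs, rois, path, image_prefix = "frame") {
  m <- match(obs$well, rois$well)
  ppm <- attr(rois, "pixels_per_mm")
  tab <- data.frame(
    image = sprintf("%s_%04d", image_prefix, obs$frame),
    plate = rois$plate[m],
    well = obs$well,
    row = rois$row[m],
    col = rois$col[m],
    frame = obs$frame,
    period = obs$period,
    channel = if ("channel" %in% names(obs)) obs$channel else NA_integer_,
    area_px = obs$area_px,
    centroid_row = obs$centroid_row,
    centroid_col = obs$centroid_col,
    moved = obs$moved,
    up = obs$up,
    x_mm = (obs$centroid_col - rois$cx[m]) / ppm,
    y_mm = (rois$cy[m] - obs$centroid_row) / ppm
  )
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results_file
#' @return `read_results_file()` returns the table with logical
#'   `moved`/`up` columns, ready for [summarize_periods()].
#' @export
read_results_file <- function(path) {
  tab <- utils::read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE
  )
  tab$moved <- as.logical(tab$moved)
  tab$up <- as.logical(tab$up)
  tab
}
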