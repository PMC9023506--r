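#' Well ROI map for a rendered plate image
#'
#' Circular well regions of interest on a pixel grid. Plates are tiled
#' two per row (plate 1 top-left, 2 top-right, 3 bottom-left, 4
#' bottom-right); within a plate, wells sit on a regular grid with the
#' given pitch, rows A-H top to bottom, columns 1-12 left to right. Row
#' indices increase downward, so "upper half" means smaller row indices
#' (the well as seen on screen); the boundary row passes through the well
#' center.
#'
#' @param n_plates Number of 96-well plates (1-4).
#' @param geometry A [well_geometry()] (radius and pixels/mm).
#' @param pitch_mm Well center spacing (default 9 mm).
#' @return Data.frame with `plate`, `row`, `col`, `well`, `cx`, `cy`
#'   (pixel center, x = column, y = row), `radius_px`, `boundary_row`,
#'   plus attributes `width`/`height` (image size in pixels).
#' @export
make_rois <- function(n_plates = 1, geometry = well_geometry(),
                      pitch_mm = 9) {
  stopifnot(n_plates >= 1, n_plates <= 4)
  ppm <- geometry$pixels_per_mm
  plate_w <- 12 * pitch_mm * ppm
  plate_h <- 8 * pitch_mm * ppm
  tiles_x <- if (n_plates > 1) 2 else 1
  tiles_y <- if (n_plates > 2) 2 else 1
  grid <- expand.grid(
    col = 1:12, row = LETTERS[1:8], plate = seq_len(n_plates),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tx <- (grid$plate - 1) %% 2
  ty <- (grid$plate - 1) %/% 2
  grid$cx <- tx * plate_w + ((grid$col - 0.5) * pitch_mm) * ppm
  grid$cy <- ty * plate_h + ((match(grid$row, LETTERS) - 0.5) * pitch_mm) * ppm
  grid$well <- sprintf("P%d-%s%02d", grid$plate, grid$row, grid$col)
  grid$radius_px <- geometry$inner_diameter_mm / 2 * ppm
  grid$boundary_row <- grid$cy
  out <- grid[, c(
    "plate", "row", "col", "well", "cx", "cy",
    "radius_px", "boundary_row"
  )]
  attr(out, "width") <- as.integer(ceiling(tiles_x * plate_w))
  attr(out, "height") <- as.integer(ceiling(tiles_y * plate_h))
  attr(out, "pixels_per_mm") <- ppm
  out
}

#' Read/write ROI maps as CSV
#' @param rois ROI data.frame from [make_rois()].
#' @param path CSV path.
#' @return The path / the ROI data.frame (with image-size attributes
#'   restored from the `# width height ppm` comment line).
#' @export
write_rois_csv <- function(rois, path) {
  con <- file(path, "w")
  writeLines(sprintf(
    "# %d %d %g", attr(rois, "width"), attr(rois, "height"),
    attr(rois, "pixels_per_mm")
  ), con)
  utils::write.csv(as.data.frame(rois), con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_rois_csv
#' @export
read_rois_csv <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- as.numeric(strsplit(sub("^#\\s*", "", first), "\\s+")[[1]])
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(out, "width") <- as.integer(meta[1])
  attr(out, "height") <- as.integer(meta[2])
  attr(out, "pixels_per_mm") <- meta[3]
  out
}

# Rendered intensities for a stimulus color: the camera exposure is
# matched so that in the selected channel (the one where stimulus and
# background are closest) the lines differ from the background by less
# than the differencing threshold. Nominal red (255) would differ by 45
# >= 40; it is acquired at 240.
camera_rgb <- function(color_rgb, background_rgb = c(210, 210, 210),
                       max_dev = 30) {
  ch <- select_channel(NULL, color_rgb, background_rgb)
  out <- as.numeric(color_rgb)
  dev <- out[ch] - background_rgb[ch]
  if (abs(dev) > max_dev) {
    out[ch] <- background_rgb[ch] + sign(dev) * max_dev
  }
  out
}

#' Render one plate image
#'
#' Draws the projected background (210,210,210), the active period's
#' stimulus lines at their scheduled phase (horizontal lines moving down
#' or up; intensities as acquired by the exposure-matched camera, see the
#' methods vignette), and each larva as a dark horizontal ellipse
#' (intensity 60, body size from the geometry) at its track position in
#' its well.
#'
#' @param tracks List of `larva_track`s, one per ROI row (matched by
#'   position).
#' @param rois ROI map from [make_rois()].
#' @param schedule The `assay_schedule`.
#' @param geometry The [well_geometry()] used for simulation.
#' @param frame 0-based frame index.
#' @return `height x width x 3` numeric array with values in 0--255.
#' @export
render_frame <- function(tracks, rois, schedule, geometry, frame) {
  stopifnot(length(tracks) == nrow(rois))
  w <- attr(rois, "width")
  h <- attr(rois, "height")
  ppm <- attr(rois, "pixels_per_mm")
  img <- array(rep(as.numeric(schedule$background_rgb), each = w * h),
    dim = c(h, w, 3)
  )
  per <- period_of_frame(schedule, frame)
  if (!is.null(per$visual)) {
    v <- per$visual
    t_s <- frame * schedule$frame_interval_s
    # line phase in mm; down = lines advance toward larger row indices
    dir <- if (v$direction == "down") 1 else -1
    phase <- (dir * v$speed_mm_per_s * t_s) %% v$line_spacing_mm
    row_mm <- (seq_len(h) - 0.5) / ppm
    on <- ((row_mm - phase) %% v$line_spacing_mm) < v$line_thickness_mm
    col_acq <- camera_rgb(v$color_rgb, schedule$background_rgb)
    for (ch in 1:3) img[on, , ch] <- col_acq[ch]
  }
  a <- geometry$larva_length_mm / 2 * ppm
  b <- geometry$larva_width_mm / 2 * ppm
  for (i in seq_len(nrow(rois))) {
    tr <- tracks[[i]]
    k <- match(frame, tr$frame)
    if (is.na(k)) next
    cx <- rois$cx[i] + tr$x_mm[k] * ppm
    cy <- rois$cy[i] - tr$y_mm[k] * ppm
    rows <- max(1L, floor(cy - b)):min(h, ceiling(cy + b))
    cols <- max(1L, floor(cx - a)):min(w, ceiling(cx + a))
    ell <- outer(
      ((rows - 0.5 - cy) / b)^2, ((cols - 0.5 - cx) / a)^2, `+`
    ) <= 1
    for (ch in 1:3) {
      sub <- img[rows, cols, ch]
      sub[ell] <- 60
      img[rows, cols, ch] <- sub
    }
  }
  img
}

#' Render an image sequence
#'
#' @inheritParams render_frame
#' @param frames 0-based frame indices (default: all frames of the
#'   schedule).
#' @param dir If given, write PNG files `frame_0000.png`, ... there and
#'   return the paths; otherwise return a list of arrays (mind memory for
#'   long sequences — prefer `dir` or the on-demand function interface of
#'   [track_frames()]).
#' @return List of arrays, or character vector of paths.
#' @export
render_frames <- function(tracks, rois, schedule, geometry,
                          frames = NULL, dir = NULL) {
  if (is.null(frames)) frames <- 0:(n_frames(schedule) - 1L)
  if (is.null(dir)) {
    return(lapply(frames, function(f) {
      render_frame(tracks, rois, schedule, geometry, f)
    }))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vapply(frames, function(f) {
    img <- render_frame(tracks, rois, schedule, geometry, f)
    path <- file.path(dir, sprintf("frame_%04d.png", f))
    png::writePNG(img / 255, path)
    path
  }, character(1))
}
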