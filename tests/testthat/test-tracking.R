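test_that("channel selection minimizes stimulus-background contrast", {
  bg <- c(210, 210, 210)
  expect_equal(select_channel(NULL, c(255, 0, 0), bg), 1) # |45| < |210|
  expect_equal(select_channel(NULL, c(0, 180, 0), bg), 2)
  expect_equal(select_channel(NULL, c(0, 0, 230), bg), 3)
  expect_equal(select_channel(NULL, bg, bg), 1) # tie -> first channel
  expect_error(
    select_channel(array(0, c(4, 4, 2)), c(255, 0, 0), bg),
    "3 channels"
  )
})

test_that("difference masks threshold inclusively and detect sign-symmetric change", {
  a <- matrix(100, 5, 5)
  expect_false(any(difference_mask(a, a)))
  b <- a
  b[2, 3] <- 139
  expect_false(any(difference_mask(a, b))) # delta 39 < 40
  b[2, 3] <- 140
  m <- difference_mask(a, b)
  expect_equal(which(m), which(matrix(seq_len(25), 5, 5) == (2 + 5 * 2)))
  expect_equal(sum(m), 1)

  # toy pair with exactly 3 changed pixels over threshold
  c1 <- matrix(50, 5, 5)
  c2 <- c1
  c2[1, 1] <- 120
  c2[3, 3] <- 0
  c2[5, 2] <- 95
  c2[4, 4] <- 60 # below threshold
  m2 <- difference_mask(c1, c2)
  expect_equal(sum(m2), 3)
  expect_true(all(m2[cbind(c(1, 3, 5), c(1, 3, 2))]))
  # absolute differencing: inverting the change leaves the mask unchanged
  expect_equal(difference_mask(c2, c1), m2)
  # one-sided mode keeps only darkening pixels
  m3 <- difference_mask(c1, c2, mode = "onesided")
  expect_equal(sum(m3), 1)
  expect_true(m3[3, 3])
  expect_error(difference_mask(a, matrix(0, 4, 4)), "mismatch")
})

test_that("well measurement counts ROI pixels and averages their coordinates", {
  mask <- matrix(FALSE, 10, 10)
  roi <- list(cx = 5, cy = 5, radius_px = 4.5, boundary_row = 5)
  expect_equal(measure_well(mask, roi)$area_px, 0)
  expect_null(measure_well(mask, roi)$centroid)

  mask[1 + 1, 1 + 1] <- TRUE # pixel (row 2, col 2) etc; use inner pixels
  mask[] <- FALSE
  mask[cbind(c(3, 3, 5), c(3, 5, 4))] <- TRUE
  det <- measure_well(mask, roi)
  expect_equal(det$area_px, 3L)
  expect_equal(unname(det$centroid), c(mean(c(3, 3, 5)), mean(c(3, 5, 4))))

  # pixels of a blob falling outside the ROI are not counted
  roi_small <- list(cx = 3, cy = 3, radius_px = 1.2, boundary_row = 3)
  det2 <- measure_well(mask, roi_small)
  expect_equal(det2$area_px, 1L)
  expect_error(
    measure_well(mask, list(cx = 1, cy = 1, radius_px = 5)),
    "outside"
  )
})

test_that("a blob split across two wells is counted by each ROI separately", {
  mask <- matrix(FALSE, 10, 20)
  mask[5, 9:12] <- TRUE # straddles the boundary between two ROIs
  roi_a <- list(cx = 5, cy = 5, radius_px = 4.6, boundary_row = 5)
  roi_b <- list(cx = 15, cy = 5, radius_px = 4.6, boundary_row = 5)
  da <- measure_well(mask, roi_a)
  db <- measure_well(mask, roi_b)
  expect_equal(da$area_px + db$area_px, 4L)
  expect_true(all(da$centroid["col"] <= 10, db$centroid["col"] > 10))
})

test_that("movement calls use an inclusive minimum area", {
  expect_false(call_movement(list(area_px = 0)))
  expect_true(call_movement(list(area_px = 3), 3))
  expect_false(call_movement(list(area_px = 2), 3))
  expect_error(call_movement(list(area_px = 5), 0), "min_area_px")
})

test_that("the location state updates on movement and carries forward", {
  roi <- list(boundary_row = 10)
  up_det <- list(area_px = 5, centroid = c(row = 4, col = 3))
  down_det <- list(area_px = 5, centroid = c(row = 14, col = 3))
  edge_det <- list(area_px = 5, centroid = c(row = 10, col = 3))
  expect_true(update_location(NA, up_det, TRUE, roi))
  expect_false(update_location(TRUE, down_det, TRUE, roi))
  expect_false(update_location(TRUE, edge_det, TRUE, roi)) # boundary = lower half
  expect_true(update_location(TRUE, down_det, FALSE, roi)) # carried forward
  expect_true(is.na(update_location(NA, list(area_px = 0, centroid = NULL), FALSE, roi)))
  expect_error(
    update_location(NA, list(area_px = 4, centroid = NULL), TRUE, roi),
    "centroid"
  )
})

test_that("a static rendered plate yields no movement anywhere", {
  s <- small_schedule()
  geom <- well_geometry(pixels_per_mm = 5)
  rois <- make_rois(1, geom)
  lay <- plate_layout(
    data.frame(
      plate = 1L, row = rep(LETTERS[1:8], each = 12),
      col = rep(1:12, 8), label = "DMSO"
    ),
    controls = "DMSO"
  )
  tracks <- simulate_screen(lay, list(DMSO = phenotype(p_move_base = 0)), s,
    geometry = geom, seed = 2
  )
  frames <- render_frames(tracks, rois, s, geom, frames = 0:5)
  obs <- track_frames(frames, rois, s)
  expect_equal(nrow(obs), 96 * 5)
  expect_false(any(obs$moved))
  expect_true(all(is.na(obs$up)))
})

test_that("moving stimulus lines are invisible in the selected channel", {
  s <- default_schedule()
  geom <- well_geometry(pixels_per_mm = 5)
  rois <- make_rois(1, geom)
  lay <- plate_layout(
    data.frame(
      plate = 1L, row = rep(LETTERS[1:8], each = 12),
      col = rep(1:12, 8), label = "DMSO"
    ),
    controls = "DMSO"
  )
  tracks <- simulate_screen(lay, list(DMSO = phenotype(p_move_base = 0)), s,
    geometry = geom, seed = 2
  )
  # red (period 7, frames 600+), green (period 9), blue (period 11) and
  # fast red (period 13): static larvae, moving lines
  for (f0 in c(600, 800, 1000, 1200)) {
    frames <- render_frames(tracks, rois, s, geom, frames = f0 + 0:2)
    obs <- track_frames(frames, rois, s, start_frame = f0)
    expect_false(any(obs$moved))
  }
  # standard-speed lines visibly move between frames (fast red advances
  # exactly 12 line spacings per 6-s frame and aliases to static)
  for (f0 in c(600, 800, 1000)) {
    frames <- render_frames(tracks, rois, s, geom, frames = f0 + 0:1)
    expect_false(identical(frames[[1]], frames[[2]]))
  }
})

test_that("tracking a rendered screen matches ground truth movement and position", {
  s <- small_schedule()
  geom <- well_geometry(pixels_per_mm = 6)
  rois <- make_rois(1, geom)
  lay <- plate_layout(
    data.frame(
      plate = 1L, row = rep(LETTERS[1:2], each = 6),
      col = rep(1:6, 2), label = "DMSO"
    ),
    controls = "DMSO"
  )
  rois <- rois[match(lay$well, rois$well), ]
  attr(rois, "width") <- 6 * 9 * 6
  attr(rois, "height") <- 2 * 9 * 6
  tracks <- simulate_screen(lay, list(DMSO = phenotype(p_move_base = 0.35, omr_gain = 0.4)),
    s,
    geometry = geom, seed = 6
  )
  n_img <- 40
  get_frame <- function(i) render_frame(tracks, rois, s, geom, i - 1L)
  obs <- track_frames(get_frame, rois, s, n_images = n_img)
  expect_equal(nrow(obs), nrow(lay) * (n_img - 1))

  agree <- err <- 0
  n_pos <- 0
  # centroid accuracy is asserted for larvae whose body lies fully
  # inside the circular ROI (edge-clipped bodies shift the measurable
  # centroid; real wells have walls)
  r_full <- geom$inner_diameter_mm / 2 - geom$larva_length_mm / 2
  for (i in seq_len(nrow(lay))) {
    tr <- tracks[[i]]
    sub <- obs[obs$well == lay$well[i], ]
    truth <- tr$moved[2:n_img]
    agree <- agree + sum(sub$moved == truth)
    mv <- which(sub$moved & truth)
    mv <- mv[sqrt(tr$x_mm[mv + 1]^2 + tr$y_mm[mv + 1]^2) <= r_full]
    if (length(mv)) {
      cx <- rois$cx[i] + tr$x_mm[mv + 1] * geom$pixels_per_mm
      cy <- rois$cy[i] - tr$y_mm[mv + 1] * geom$pixels_per_mm
      err <- max(err, max(abs(sub$centroid_col[mv] - cx), abs(sub$centroid_row[mv] - cy)))
      n_pos <- n_pos + length(mv)
    }
  }
  expect_gte(agree / (nrow(lay) * (n_img - 1)), 0.99)
  expect_gt(n_pos, 20)
  expect_lte(err, 1)
})

test_that("well processing order does not change the observations", {
  s <- small_schedule()
  geom <- well_geometry(pixels_per_mm = 5)
  rois <- make_rois(1, geom)[1:6, ]
  attr(rois, "width") <- 648L
  attr(rois, "height") <- 360L
  attr(rois, "pixels_per_mm") <- 5
  lay <- plate_layout(
    data.frame(plate = 1L, row = "A", col = 1:6, label = "DMSO"),
    controls = "DMSO"
  )
  tracks <- simulate_screen(lay, list(DMSO = phenotype(p_move_base = 0.5)), s,
    geometry = geom, seed = 9
  )
  frames <- render_frames(tracks, rois, s, geom, frames = 0:6)
  obs1 <- track_frames(frames, rois, s)
  perm <- c(4, 2, 6, 1, 3, 5)
  rois2 <- rois[perm, ]
  attr(rois2, "width") <- attr(rois, "width")
  attr(rois2, "height") <- attr(rois, "height")
  attr(rois2, "pixels_per_mm") <- 5
  obs2 <- track_frames(frames, rois2, s)
  obs1 <- obs1[order(obs1$well, obs1$frame), ]
  obs2 <- obs2[order(obs2$well, obs2$frame), ]
  rownames(obs1) <- rownames(obs2) <- NULL
  expect_equal(obs1, obs2)
})

test_that("a displaced blob's difference centroid lands on the new position", {
  s <- small_schedule()
  geom <- well_geometry(pixels_per_mm = 6)
  rois <- make_rois(1, geom)[1, , drop = FALSE]
  attr(rois, "width") <- 108L
  attr(rois, "height") <- 108L
  attr(rois, "pixels_per_mm") <- 6
  # hand-built track: one 10-px vertical displacement at frame 1 (beyond
  # the 6-px body height, so old and new body positions are disjoint and
  # the one-sided difference is exactly the new position)
  tr <- data.frame(
    frame = 0:1, moved = c(FALSE, TRUE),
    x_mm = c(0, 0), y_mm = c(-10 / 6 / 2, 10 / 6 / 2)
  )
  attr(tr, "well") <- rois$well[1]
  class(tr) <- c("larva_track", "data.frame")
  f0 <- render_frame(list(tr), rois, s, geom, 0)
  f1 <- render_frame(list(tr), rois, s, geom, 1)
  dark <- difference_mask(f0[, , 1], f1[, , 1], mode = "onesided")
  det <- measure_well(dark, rois[1, ])
  cx_new <- rois$cx[1] + tr$x_mm[2] * 6
  cy_new <- rois$cy[1] - tr$y_mm[2] * 6
  expect_lt(abs(det$centroid[["col"]] - cx_new), 1)
  expect_lt(abs(det$centroid[["row"]] - cy_new), 1)
  # without movement the in-well difference is empty
  f1b <- render_frame(list(tr), rois, s, geom, 0)
  expect_equal(measure_well(difference_mask(f0[, , 1], f1b[, , 1]), rois[1, ])$area_px, 0)
})

test_that("the 15-column results file round-trips through TSV", {
  s <- small_schedule()
  geom <- well_geometry(pixels_per_mm = 5)
  rois <- make_rois(1, geom)
  lay <- plate_layout(
    data.frame(
      plate = 1L, row = rep(LETTERS[1:8], each = 12),
      col = rep(1:12, 8), label = "DMSO"
    ),
    controls = "DMSO"
  )
  tracks <- simulate_screen(lay, list(DMSO = phenotype(p_move_base = 0.4)), s,
    geometry = geom, seed = 10
  )
  frames <- render_frames(tracks, rois, s, geom, frames = 0:4)
  obs <- track_frames(frames, rois, s)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_file(obs, rois, path)
  back <- read_results_file(path)
  expect_equal(ncol(back), 15)
  expect_equal(nrow(back), 96 * 4)
  expect_equal(back$moved, obs$moved)
  expect_equal(back$frame, obs$frame)
  # readable by the metrics stage
  one <- back[back$well == back$well[1], c("frame", "moved", "up")]
  ps <- summarize_periods(one, s, min_total_pct = 0)
  expect_equal(sum(ps$summaries$n_frames), 4)
})

test_that("ROI maps round-trip through CSV", {
  geom <- well_geometry(pixels_per_mm = 5)
  rois <- make_rois(2, geom)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rois_csv(rois, path)
  back <- read_rois_csv(path)
  expect_equal(back$cx, rois$cx)
  expect_equal(back$well, rois$well)
  expect_equal(attr(back, "width"), attr(rois, "width"))
  expect_equal(attr(back, "pixels_per_mm"), 5)
})

test_that("PNG frame directories can be tracked directly", {
  s <- small_schedule()
  geom <- well_geometry(pixels_per_mm = 5)
  rois <- make_rois(1, geom)[1:3, ]
  attr(rois, "width") <- 540L
  attr(rois, "height") <- 360L
  attr(rois, "pixels_per_mm") <- 5
  lay <- plate_layout(
    data.frame(plate = 1L, row = "A", col = 1:3, label = "DMSO"),
    controls = "DMSO"
  )
  tracks <- simulate_screen(lay, list(DMSO = phenotype(p_move_base = 0.5)), s,
    geometry = geom, seed = 12
  )
  dir <- withr::local_tempdir()
  render_frames(tracks, rois, s, geom, frames = 0:4, dir = dir)
  obs_dir <- track_frames(dir, rois, s)
  obs_mem <- track_frames(
    render_frames(tracks, rois, s, geom, frames = 0:4), rois, s
  )
  expect_equal(obs_dir$moved, obs_mem$moved)
  expect_equal(obs_dir$area_px, obs_mem$area_px)
})
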