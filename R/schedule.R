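#' Visual stimulus: moving colored lines
#'
#' A field of parallel horizontal lines projected through the plate bottom,
#' moving down or up. Standard lines are 1 mm thick, 7 mm apart, and move
#' 7 mm per 8 s; "fast red" lines move 7 mm per 0.5 s (16 times faster).
#'
#' @param class One of `"red"`, `"green"`, `"blue"`, `"fast_red"`.
#' @param direction `"down"` or `"up"`.
#' @param color_rgb Integer RGB triple in 0--255. Defaults to the assay
#'   colors: red (255,0,0), green (0,180,0), blue (0,0,230).
#' @param speed_mm_per_s Line speed. Defaults to 7/8 mm/s (7/0.5 for
#'   `"fast_red"`).
#' @param line_thickness_mm,line_spacing_mm Line geometry (defaults 1 and 7).
#' @return An object of class `visual_stimulus`.
#' @export
visual_stimulus <- function(class = c("red", "green", "blue", "fast_red"),
                            direction = c("down", "up"),
                            color_rgb = NULL,
                            speed_mm_per_s = NULL,
                            line_thickness_mm = 1,
                            line_spacing_mm = 7) {
  class <- match.arg(class)
  direction <- match.arg(direction)
  if (is.null(color_rgb)) {
    color_rgb <- switch(class,
      red = c(255L, 0L, 0L),
      fast_red = c(255L, 0L, 0L),
      green = c(0L, 180L, 0L),
      blue = c(0L, 0L, 230L)
    )
  }
  if (is.null(speed_mm_per_s)) {
    speed_mm_per_s <- if (class == "fast_red") 7 / 0.5 else 7 / 8
  }
  stopifnot(
    length(color_rgb) == 3L, all(color_rgb >= 0), all(color_rgb <= 255),
    length(speed_mm_per_s) == 1L
  )
  if (!is.finite(speed_mm_per_s) || speed_mm_per_s <= 0) {
    stop("invalid visual stimulus: speed must be a positive real", call. = FALSE)
  }
  if (line_thickness_mm <= 0 || line_spacing_mm <= 0) {
    stop("invalid visual stimulus: line geometry must be positive", call. = FALSE)
  }
  structure(
    list(
      class = class, direction = direction,
      color_rgb = as.integer(color_rgb),
      speed_mm_per_s = speed_mm_per_s,
      line_thickness_mm = line_thickness_mm,
      line_spacing_mm = line_spacing_mm
    ),
    class = "visual_stimulus"
  )
}

#' Acoustic stimulus: repeated pulses
#'
#' Brief sine-wave pulses (100 ms, 400 Hz) delivered at a fixed interval;
#' the default schedule uses 20-s and 1-s intervals.
#'
#' @param pulse_interval_s Interval between pulses in seconds.
#' @param pulse_duration_ms Pulse duration (default 100 ms).
#' @param frequency_hz Pulse frequency (default 400 Hz).
#' @return An object of class `acoustic_stimulus`.
#' @export
acoustic_stimulus <- function(pulse_interval_s,
                              pulse_duration_ms = 100,
                              frequency_hz = 400) {
  stopifnot(
    length(pulse_interval_s) == 1L, pulse_interval_s > 0,
    pulse_duration_ms > 0, frequency_hz > 0
  )
  structure(
    list(
      pulse_interval_s = pulse_interval_s,
      pulse_duration_ms = pulse_duration_ms,
      frequency_hz = frequency_hz
    ),
    class = "acoustic_stimulus"
  )
}

#' One 10-minute recording period
#'
#' @param index 1-based period index.
#' @param n_frames Number of frames in the period.
#' @param visual Optional [visual_stimulus()].
#' @param acoustic Optional [acoustic_stimulus()]. A period never carries
#'   both a visual and an acoustic stimulus.
#' @return An object of class `schedule_period`.
#' @export
schedule_period <- function(index, n_frames, visual = NULL, acoustic = NULL) {
  stopifnot(index >= 1, n_frames >= 1)
  if (!is.null(visual) && !is.null(acoustic)) {
    stop("a period cannot have both a visual and an acoustic stimulus",
      call. = FALSE
    )
  }
  if (!is.null(visual)) stopifnot(inherits(visual, "visual_stimulus"))
  if (!is.null(acoustic)) stopifnot(inherits(acoustic, "acoustic_stimulus"))
  structure(
    list(
      index = as.integer(index), n_frames = as.integer(n_frames),
      visual = visual, acoustic = acoustic
    ),
    class = "schedule_period"
  )
}

#' The 3-h, 18-period stimulus schedule
#'
#' The default assay records one frame every 6 s for 3 h, divided into
#' eighteen 10-min periods: 1--6 baseline (no stimuli), 7--14 moving-line
#' visual stimuli (red, green, blue, fast red; each color first down then
#' up), 15 rest, 16 acoustic pulses at 20-s intervals, 17 acoustic pulses
#' at 1-s intervals, 18 acoustic pulses at 20-s intervals. Period length in
#' frames is derived as 600 s / `frame_interval_s`, so reduced-scale
#' schedules (larger frame intervals) keep the same structure.
#'
#' At the 6-s frame interval individual 1-s pulses are sub-frame events;
#' the acoustic blocks are therefore modeled (and simulated) as
#' period-level elevations of movement probability rather than per-pulse
#' events, matching how the outcome measures read the data.
#'
#' @param frame_interval_s Seconds between frames (default 6; 600 must be
#'   divisible into at least one frame per period).
#' @param background_rgb Projected background color (default 210,210,210).
#' @return An object of class `assay_schedule`: list of 18
#'   [schedule_period()]s plus frame bookkeeping.
#' @examples
#' sched <- default_schedule()
#' n_frames(sched) # 1800
#' sched$periods[[17]]$acoustic$pulse_interval_s # 1
#' @export
default_schedule <- function(frame_interval_s = 6,
                             background_rgb = c(210L, 210L, 210L)) {
  stopifnot(frame_interval_s > 0)
  npf <- as.integer(round(600 / frame_interval_s))
  if (npf < 1) stop("frame interval too long: empty periods", call. = FALSE)
  vis <- function(class, dir) visual_stimulus(class, dir)
  specs <- list(
    NULL, NULL, NULL, NULL, NULL, NULL,
    vis("red", "down"), vis("red", "up"),
    vis("green", "down"), vis("green", "up"),
    vis("blue", "down"), vis("blue", "up"),
    vis("fast_red", "down"), vis("fast_red", "up"),
    NULL,
    acoustic_stimulus(20), acoustic_stimulus(1), acoustic_stimulus(20)
  )
  periods <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    if (inherits(s, "visual_stimulus")) {
      schedule_period(i, npf, visual = s)
    } else if (inherits(s, "acoustic_stimulus")) {
      schedule_period(i, npf, acoustic = s)
    } else {
      schedule_period(i, npf)
    }
  })
  new_schedule(periods, frame_interval_s, background_rgb)
}

new_schedule <- function(periods, frame_interval_s, background_rgb) {
  n <- vapply(periods, function(p) p$n_frames, integer(1))
  structure(
    list(
      periods = periods,
      frame_interval_s = frame_interval_s,
      background_rgb = as.integer(background_rgb),
      period_end = cumsum(n)
    ),
    class = "assay_schedule"
  )
}

#' Total number of frames in a schedule
#' @param schedule An `assay_schedule`.
#' @return Integer frame count (1800 under defaults).
#' @export
n_frames <- function(schedule) {
  stopifnot(inherits(schedule, "assay_schedule"))
  as.integer(schedule$period_end[length(schedule$period_end)])
}

#' Map frames to periods
#'
#' Frames are 0-based (the first acquired image is frame 0); periods are
#' 1-based, matching the "period 15/16/17" naming of the assay.
#'
#' @param schedule An `assay_schedule`.
#' @param frame_index Integer vector of 0-based frame indices.
#' @return Integer vector of 1-based period indices.
#' @examples
#' period_index_of_frame(default_schedule(), c(0, 950, 1799)) # 1, 10, 18
#' @export
period_index_of_frame <- function(schedule, frame_index) {
  stopifnot(inherits(schedule, "assay_schedule"))
  if (any(frame_index < 0 | frame_index >= n_frames(schedule))) {
    stop("frame index out of range [0, ", n_frames(schedule) - 1L, "]",
      call. = FALSE
    )
  }
  findInterval(frame_index, schedule$period_end) + 1L
}

#' @rdname period_index_of_frame
#' @return `period_of_frame()` returns the `schedule_period` containing a
#'   single frame.
#' @export
period_of_frame <- function(schedule, frame_index) {
  stopifnot(length(frame_index) == 1L)
  schedule$periods[[period_index_of_frame(schedule, frame_index)]]
}

#' 0-based frame indices belonging to one period
#' @param schedule An `assay_schedule`.
#' @param index 1-based period index.
#' @return Integer vector of 0-based frame indices.
#' @export
frames_of_period <- function(schedule, index) {
  stopifnot(index >= 1, index <= length(schedule$periods))
  hi <- schedule$period_end[index]
  lo <- if (index == 1L) 0L else schedule$period_end[index - 1L]
  seq.int(lo, hi - 1L)
}

#' Speed ratio between two visual stimuli
#'
#' The fast red lines of the default assay move 7 mm per 0.5 s, 16 times
#' the standard 7 mm per 8 s.
#'
#' @param fast,standard [visual_stimulus()] objects.
#' @return `fast$speed / standard$speed`.
#' @examples
#' stimulus_speed_ratio(
#'   visual_stimulus("fast_red", "down"),
#'   visual_stimulus("red", "down")
#' ) # 16
#' @export
stimulus_speed_ratio <- function(fast, standard) {
  stopifnot(
    inherits(fast, "visual_stimulus"),
    inherits(standard, "visual_stimulus")
  )
  fast$speed_mm_per_s / standard$speed_mm_per_s
}

#' @export
print.assay_schedule <- function(x, ...) {
  cat(
    "Assay schedule:", length(x$periods), "periods,",
    n_frames(x), "frames at", x$frame_interval_s, "s/frame\n"
  )
  for (p in x$periods) {
    what <- if (!is.null(p$visual)) {
      sprintf(
        "%s lines moving %s (%.3g mm/s)",
        p$visual$class, p$visual$direction, p$visual$speed_mm_per_s
      )
    } else if (!is.null(p$acoustic)) {
      sprintf("acoustic pulses at %g-s intervals", p$acoustic$pulse_interval_s)
    } else {
      "no stimulus"
    }
    cat(sprintf("  %2d: %4d frames  %s\n", p$index, p$n_frames, what))
  }
  invisible(x)
}

# ---- schedule structure queries used by the metrics module -----------------

# Period indices of the leading stimulus-free block (default: 1..6).
baseline_periods <- function(schedule) {
  idx <- integer(0)
  for (p in schedule$periods) {
    if (is.null(p$visual) && is.null(p$acoustic)) idx <- c(idx, p$index) else break
  }
  idx
}

# The stimulus-free rest period between the visual and acoustic blocks.
rest_period <- function(schedule) {
  free <- vapply(
    schedule$periods,
    function(p) is.null(p$visual) && is.null(p$acoustic), logical(1)
  )
  idx <- setdiff(which(free), baseline_periods(schedule))
  if (length(idx) == 0L) stop("schedule has no rest period", call. = FALSE)
  idx[1L]
}

# First acoustic period at the slow (startle) interval / the fast
# (excitability/habituation) interval.
startle_period <- function(schedule) {
  acoustic_period(schedule, fast = FALSE, which = 1L)
}
excitability_period <- function(schedule) {
  acoustic_period(schedule, fast = TRUE, which = 1L)
}
acoustic_period <- function(schedule, fast, which = 1L) {
  idx <- integer(0)
  for (p in schedule$periods) {
    if (!is.null(p$acoustic)) {
      is_fast <- p$acoustic$pulse_interval_s <= 1
      if (is_fast == fast) idx <- c(idx, p$index)
    }
  }
  if (length(idx) < which) stop("schedule lacks the requested acoustic period", call. = FALSE)
  idx[which]
}

# Named list of (down, up) period-index pairs per visual class, in
# schedule order: list(red = c(7, 8), green = c(9, 10), ...).
omr_period_pairs <- function(schedule) {
  vis <- Filter(function(p) !is.null(p$visual), schedule$periods)
  pairs <- list()
  for (p in vis) {
    cl <- p$visual$class
    if (is.null(pairs[[cl]])) pairs[[cl]] <- c(down = NA_integer_, up = NA_integer_)
    pairs[[cl]][p$visual$direction] <- p$index
  }
  pairs <- Filter(function(x) !anyNA(x), pairs)
  if (length(pairs) == 0L) {
    stop("schedule has no complete down/up visual period pair", call. = FALSE)
  }
  pairs
}

# ---- serialization ---------------------------------------------------------

#' Serialize a schedule to YAML (and back)
#'
#' The config lists one entry per period with the active stimulus; the
#' default schedule round-trips exactly.
#'
#' @param schedule An `assay_schedule`.
#' @param path File path; for `schedule_to_yaml()` omit to get the YAML
#'   string.
#' @return `schedule_to_yaml()`: the path (or YAML string, invisibly);
#'   `schedule_from_yaml()`: an `assay_schedule`.
#' @export
schedule_to_yaml <- function(schedule, path = NULL) {
  stopifnot(inherits(schedule, "assay_schedule"))
  rep_period <- function(p) {
    out <- list(index = p$index, n_frames = p$n_frames)
    if (!is.null(p$visual)) {
      v <- p$visual
      out$visual <- list(
        class = v$class, direction = v$direction,
        rgb = as.integer(v$color_rgb),
        speed_mm_per_s = v$speed_mm_per_s,
        line_thickness_mm = v$line_thickness_mm,
        line_spacing_mm = v$line_spacing_mm
      )
    }
    if (!is.null(p$acoustic)) {
      a <- p$acoustic
      out$acoustic <- list(
        interval_s = a$pulse_interval_s,
        pulse_duration_ms = a$pulse_duration_ms,
        frequency_hz = a$frequency_hz
      )
    }
    out
  }
  doc <- list(
    frame_interval_s = schedule$frame_interval_s,
    background_rgb = as.integer(schedule$background_rgb),
    periods = lapply(schedule$periods, rep_period)
  )
  txt <- yaml::as.yaml(doc)
  if (is.null(path)) {
    return(invisible(txt))
  }
  writeLines(txt, path)
  invisible(path)
}

#' @rdname schedule_to_yaml
#' @param text YAML string (alternative to `path`).
#' @export
schedule_from_yaml <- function(path = NULL, text = NULL) {
  doc <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  periods <- lapply(doc$periods, function(p) {
    visual <- NULL
    acoustic <- NULL
    if (!is.null(p$visual)) {
      v <- p$visual
      visual <- visual_stimulus(
        class = v$class, direction = v$direction,
        color_rgb = v$rgb, speed_mm_per_s = v$speed_mm_per_s,
        line_thickness_mm = v$line_thickness_mm,
        line_spacing_mm = v$line_spacing_mm
      )
    }
    if (!is.null(p$acoustic)) {
      a <- p$acoustic
      acoustic <- acoustic_stimulus(
        pulse_interval_s = a$interval_s,
        pulse_duration_ms = a$pulse_duration_ms,
        frequency_hz = a$frequency_hz
      )
    }
    schedule_period(p$index, p$n_frames, visual = visual, acoustic = acoustic)
  })
  new_schedule(periods, doc$frame_interval_s, doc$background_rgb)
}
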