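#' Well geometry
#'
#' Geometry of a single well of the 384-well (4 x 96) imaging format and
#' of the larva rendered into it.
#'
#' @param inner_diameter_mm Inner well diameter (default 7.15 mm).
#' @param pixels_per_mm Image resolution used when rendering/tracking.
#' @param larva_length_mm Larva body length (default 4 mm at 5 dpf).
#' @param larva_width_mm Larva body width (default 1 mm).
#' @param margin_mm Containment margin: simulated centroids stay within
#'   `inner_diameter_mm / 2 - margin_mm` of the well center (a real
#'   larva's centroid cannot lie on the wall; default 0.5 mm, half the
#'   body width).
#' @return An object of class `well_geometry`.
#' @export
well_geometry <- function(inner_diameter_mm = 7.15, pixels_per_mm = 6,
                          larva_length_mm = 4, larva_width_mm = 1,
                          margin_mm = 0.5) {
  stopifnot(
    inner_diameter_mm > 0, pixels_per_mm > 0,
    larva_length_mm > 0, larva_width_mm > 0,
    margin_mm >= 0, margin_mm < inner_diameter_mm / 2
  )
  if (larva_length_mm > inner_diameter_mm) {
    stop("rendered larva does not fit in the well", call. = FALSE)
  }
  structure(
    list(
      inner_diameter_mm = inner_diameter_mm,
      pixels_per_mm = pixels_per_mm,
      larva_length_mm = larva_length_mm,
      larva_width_mm = larva_width_mm,
      margin_mm = margin_mm
    ),
    class = "well_geometry"
  )
}

# Stable per-well seed: a small multiplicative-congruential hash of
# (master seed, plate, well index). Exact in double arithmetic
# (48271 * 2^31 < 2^53) and independent of iteration order.
well_seed <- function(master, plate, well_index) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  h <- (h * 48271 + as.numeric(plate) * 1009 + as.numeric(well_index)) %% m
  h <- (h * 48271 + 12345) %% m
  as.integer(h)
}

#' Simulate one larva's track
#'
#' Draws per-frame movement from the phenotype's period-dependent
#' probability ([move_probability()]); on movement the larva takes a step
#' with independent horizontal and vertical components (magnitudes uniform
#' in `step_mm`), the vertical sign biased by the active optomotor
#' stimulus ([omr_bias()]). Positions are reflected at the containment
#' circle (radius = well radius minus `geometry$margin_mm`). Frames
#' without movement repeat the previous position exactly.
#'
#' @param phen A [phenotype()].
#' @param schedule An `assay_schedule`.
#' @param geometry A [well_geometry()].
#' @param seed Integer seed; identical inputs give bit-identical tracks.
#' @param step_mm Length-2 numeric: per-axis step magnitude range in mm.
#' @param well Optional well id stored on the track.
#' @return A `larva_track`: data.frame with columns `frame` (0-based),
#'   `moved` (logical), `x_mm`, `y_mm` (well-centered coordinates, y
#'   increasing upward), with the generating phenotype attached as
#'   attribute `phenotype`.
#' @examples
#' tr <- simulate_track(phenotype("DMSO"), default_schedule(), seed = 1)
#' mean(tr$moved) # close to 0.2
#' @export
simulate_track <- function(phen, schedule = default_schedule(),
                           geometry = well_geometry(), seed = 1L,
                           step_mm = c(0.5, 3.5), well = NA_character_) {
  stopifnot(
    inherits(phen, "phenotype"), inherits(schedule, "assay_schedule"),
    inherits(geometry, "well_geometry"),
    length(step_mm) == 2L, all(step_mm > 0), step_mm[1] <= step_mm[2]
  )
  cache <- sim_cache(phen, schedule, geometry, step_mm)
  sim <- sim_walk(cache, seed)
  n <- length(sim$moved)
  out <- data.frame(
    frame = 0:(n - 1L), moved = sim$moved,
    x_mm = sim$x, y_mm = sim$y
  )
  attr(out, "phenotype") <- phen
  attr(out, "well") <- well
  class(out) <- c("larva_track", "data.frame")
  out
}

# Per-phenotype constants of the walk, computed once and reused across
# wells (the per-frame probability and bias vectors depend only on the
# phenotype and schedule).
sim_cache <- function(phen, schedule, geometry, step_mm = c(0.5, 3.5)) {
  list(
    p = move_probability(phen, schedule),
    b = omr_bias(phen, schedule),
    r = geometry$inner_diameter_mm / 2 - geometry$margin_mm,
    step_mm = step_mm
  )
}

# One seeded walk from a cache; the single source of the RNG call order.
sim_walk <- function(cache, seed) {
  n <- length(cache$p)
  set.seed(seed)
  moved <- runif(n) < cache$p
  u_dir <- runif(n)
  sx <- ifelse(runif(n) < 0.5, -1, 1)
  mag_x <- runif(n, cache$step_mm[1], cache$step_mm[2])
  mag_y <- runif(n, cache$step_mm[1], cache$step_mm[2])
  # initial position: uniform in the containment disc
  th <- runif(1, 0, 2 * pi)
  rad <- cache$r * sqrt(runif(1))
  pos <- walk_core(
    as.integer(moved), cache$b, u_dir, sx, mag_x, mag_y, cache$r,
    rad * cos(th), rad * sin(th)
  )
  list(moved = moved, x = pos[, 1], y = pos[, 2])
}

#' Plate layouts
#'
#' A layout maps wells of the four-plate, 384-well imaging format to
#' treatment labels. `plate_layout()` builds one from a data.frame;
#' `screen_layout()` builds a randomized screen-style layout in which each
#' 96-well plate holds at most one well per drug (duplicate treatments are
#' spread across plates) and the remaining wells carry the controls.
#'
#' @param wells Data.frame with columns `plate` (1-4), `row` ("A"-"H"),
#'   `col` (1-12), `label`.
#' @param controls Character vector of labels to treat as
#'   vehicle/untreated controls.
#' @param screen_rule Enforce the screen-mode rule that no drug occupies
#'   two wells of the same 96-well plate (default). Validation-style
#'   layouts with whole rows per treatment set this to `FALSE`.
#' @return A `plate_layout`: the wells data.frame with a `controls`
#'   attribute and a derived `well` id column ("P1-A01").
#' @export
plate_layout <- function(wells, controls = "DMSO", screen_rule = TRUE) {
  stopifnot(all(c("plate", "row", "col", "label") %in% names(wells)))
  wells$plate <- as.integer(wells$plate)
  wells$col <- as.integer(wells$col)
  stopifnot(
    all(wells$plate >= 1), all(wells$row %in% LETTERS[1:8]),
    all(wells$col >= 1 & wells$col <= 12)
  )
  key <- sprintf("P%d-%s%02d", wells$plate, wells$row, wells$col)
  if (anyDuplicated(key)) stop("duplicate wells in layout", call. = FALSE)
  wells$well <- key
  # screen rule: no duplicate drug treatment within a single 96-well plate
  treated <- if (screen_rule) wells[!(wells$label %in% controls), ] else wells[0, ]
  if (nrow(treated)) {
    dup <- stats::aggregate(
      list(n = treated$label),
      by = list(plate = treated$plate, label = treated$label), FUN = length
    )
    if (any(dup$n > 1)) {
      stop("layout places a drug twice on one 96-well plate: ",
        paste(unique(dup$label[dup$n > 1]), collapse = ", "),
        call. = FALSE
      )
    }
  }
  attr(wells, "controls") <- controls
  class(wells) <- c("plate_layout", "data.frame")
  wells
}

#' @rdname plate_layout
#' @param drugs Character vector of drug labels (at most 80 for a full
#'   96-well plate with 16 control wells).
#' @param n_plates Number of 96-well plates (default 4).
#' @param control_labels Labels cycled through the non-drug wells
#'   (default: half untreated, half DMSO).
#' @param seed Seed for the randomized well assignment.
#' @export
screen_layout <- function(drugs, n_plates = 4,
                          control_labels = c("untreated", "DMSO"),
                          controls = c("untreated", "DMSO"), seed = 1L) {
  stopifnot(length(drugs) <= 96 - length(control_labels))
  set.seed(seed)
  all_wells <- expand.grid(
    col = 1:12, row = LETTERS[1:8], plate = seq_len(n_plates),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  per_plate <- lapply(seq_len(n_plates), function(pl) {
    n_ctrl <- 96 - length(drugs)
    labels <- c(drugs, rep_len(control_labels, n_ctrl))
    sample(labels)
  })
  all_wells$label <- unlist(per_plate)
  plate_layout(all_wells[, c("plate", "row", "col", "label")], controls = controls)
}

#' Read/write plate layouts as CSV
#' @param path CSV path with columns plate,row,col,label.
#' @param controls Control labels (see [plate_layout()]).
#' @return A `plate_layout` / the path, invisibly.
#' @export
read_layout_csv <- function(path, controls = "DMSO") {
  plate_layout(
    utils::read.csv(path, stringsAsFactors = FALSE),
    controls = controls
  )
}

#' @rdname read_layout_csv
#' @param layout A `plate_layout`.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(
    layout[, c("plate", "row", "col", "label")], path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Simulate a whole screen
#'
#' One track per layout well, with per-well seeds derived deterministically
#' from `(seed, plate, well index)` by a stable hash, so results are
#' reproducible bit-for-bit and independent of iteration order.
#'
#' @param layout A [plate_layout()].
#' @param phenotypes Named list of [phenotype()]s covering every layout
#'   label.
#' @param schedule,geometry,step_mm As in [simulate_track()].
#' @param seed Master seed.
#' @return A list of `larva_track` objects, one per well, each carrying
#'   `well`, `plate` and `label` attributes.
#' @export
simulate_screen <- function(layout, phenotypes,
                            schedule = default_schedule(),
                            geometry = well_geometry(), seed = 1L,
                            step_mm = c(0.5, 3.5)) {
  stopifnot(inherits(layout, "plate_layout"))
  missing <- setdiff(unique(layout$label), names(phenotypes))
  if (length(missing)) {
    stop("no phenotype for label(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  idx_in_plate <- (match(layout$row, LETTERS) - 1L) * 12L + layout$col
  lapply(seq_len(nrow(layout)), function(i) {
    tr <- simulate_track(
      phenotypes[[layout$label[i]]], schedule, geometry,
      seed = well_seed(seed, layout$plate[i], idx_in_plate[i]),
      step_mm = step_mm, well = layout$well[i]
    )
    attr(tr, "plate") <- layout$plate[i]
    attr(tr, "label") <- layout$label[i]
    tr
  })
}

#' Screen cohort bookkeeping
#'
#' Arithmetic of a screen design: treated larvae = drugs x larvae per
#' drug; the total adds the untreated and vehicle-control larvae. The
#' published screen used 190 drugs x 48 larvae plus 960 untreated and 864
#' DMSO larvae across 36 imaging sessions.
#'
#' @param n_drugs,n_per_drug,n_untreated,n_dmso Design counts.
#' @return Named list with `treated`, `total`, and the inputs.
#' @examples
#' screen_cohort()$treated # 9120
#' screen_cohort()$total # 10944
#' @export
screen_cohort <- function(n_drugs = 190, n_per_drug = 48,
                          n_untreated = 960, n_dmso = 864) {
  list(
    n_drugs = n_drugs, n_per_drug = n_per_drug,
    n_untreated = n_untreated, n_dmso = n_dmso,
    treated = n_drugs * n_per_drug,
    total = n_untreated + n_dmso + n_drugs * n_per_drug
  )
}

#' Write tracks as TSV
#'
#' One row per well-frame: plate, well, frame, moved, x_mm, y_mm.
#'
#' @param tracks List of `larva_track`s (or a single track).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_tracks_tsv <- function(tracks, path) {
  if (inherits(tracks, "larva_track")) tracks <- list(tracks)
  tab <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(
      plate = attr(tr, "plate") %||% NA_integer_,
      well = attr(tr, "well"),
      frame = tr$frame, moved = tr$moved,
      x_mm = tr$x_mm, y_mm = tr$y_mm
    )
  }))
  utils::write.table(tab, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
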