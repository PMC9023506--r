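#' Parametric larval phenotype
#'
#' The simulator's behavior model is a linear-probability model on
#' per-frame movement, chosen so that every activity-family outcome
#' measure has a closed-form expectation. Per frame, movement occurs with
#' probability
#'
#' `p = clip(p_move_base + startle_gain * [slow acoustic period]
#'        + (startle_gain + excitability_gain) * [fast acoustic period]
#'        - habituation_drop * [second half of the fast acoustic period], 0, 1)`
#'
#' On movement, the larva takes a random step whose vertical sign is
#' biased by `omr_gain[class] * (+1 if lines move up, -1 if down)` during
#' visual periods; horizontal steps are symmetric.
#'
#' @param label Treatment name.
#' @param p_move_base Baseline per-frame movement probability in \[0,1\].
#' @param startle_gain Additive probability during 20-s-interval acoustic
#'   periods.
#' @param excitability_gain Additional additive probability during the
#'   1-s-interval acoustic period (on top of `startle_gain`).
#' @param habituation_drop Probability decrease applied during the second
#'   half of the 1-s-interval acoustic period.
#' @param omr_gain Named numeric, entries `red`, `green`, `blue`,
#'   `fast_red` in \[-1,1\]: the probability bias of the vertical step
#'   direction toward line motion (`0` = unbiased walk).
#' @return An object of class `phenotype`.
#' @examples
#' phenotype("DMSO", p_move_base = 0.2)
#' @export
phenotype <- function(label = "untreated",
                      p_move_base = 0.2,
                      startle_gain = 0,
                      excitability_gain = 0,
                      habituation_drop = 0,
                      omr_gain = c(red = 0, green = 0, blue = 0, fast_red = 0)) {
  full <- c(red = 0, green = 0, blue = 0, fast_red = 0)
  if (length(omr_gain) > 0) {
    if (is.null(names(omr_gain)) && length(omr_gain) == 1L) {
      full[] <- omr_gain
    } else {
      bad <- setdiff(names(omr_gain), names(full))
      if (length(bad)) stop("unknown OMR class: ", paste(bad, collapse = ", "), call. = FALSE)
      full[names(omr_gain)] <- omr_gain
    }
  }
  ok <- function(x) length(x) == 1L && is.finite(x)
  if (!ok(p_move_base) || p_move_base < 0 || p_move_base > 1) {
    stop("phenotype error: p_move_base must be a probability in [0,1]", call. = FALSE)
  }
  for (nm in c("startle_gain", "excitability_gain", "habituation_drop")) {
    if (!ok(get(nm))) stop("phenotype error: ", nm, " must be a finite scalar", call. = FALSE)
  }
  if (any(!is.finite(full)) || any(abs(full) > 1)) {
    stop("phenotype error: omr_gain entries must lie in [-1,1]", call. = FALSE)
  }
  structure(
    list(
      label = label,
      p_move_base = p_move_base,
      startle_gain = startle_gain,
      excitability_gain = excitability_gain,
      habituation_drop = habituation_drop,
      omr_gain = full
    ),
    class = "phenotype"
  )
}

#' @export
print.phenotype <- function(x, ...) {
  cat(
    sprintf(
      "Phenotype '%s': base %.3f, startle +%.3f, excitability +%.3f, habituation -%.3f\n",
      x$label, x$p_move_base, x$startle_gain, x$excitability_gain, x$habituation_drop
    ),
    sprintf(
      "  OMR gains: red %.2f, green %.2f, blue %.2f, fast_red %.2f\n",
      x$omr_gain["red"], x$omr_gain["green"], x$omr_gain["blue"], x$omr_gain["fast_red"]
    )
  )
  invisible(x)
}

#' Per-frame movement probability under a phenotype
#'
#' @param phen A [phenotype()].
#' @param schedule An `assay_schedule`.
#' @return Numeric vector of length `n_frames(schedule)`, clipped to
#'   \[0,1\].
#' @export
move_probability <- function(phen, schedule) {
  stopifnot(inherits(phen, "phenotype"), inherits(schedule, "assay_schedule"))
  p <- rep(phen$p_move_base, n_frames(schedule))
  for (per in schedule$periods) {
    ac <- per$acoustic
    if (is.null(ac)) next
    fr <- frames_of_period(schedule, per$index) + 1L
    if (ac$pulse_interval_s <= 1) {
      p[fr] <- p[fr] + phen$startle_gain + phen$excitability_gain
      # habituation: step drop between the first and second half; with an
      # odd frame count the first half keeps the extra frame
      second <- fr[-seq_len(ceiling(length(fr) / 2))]
      p[second] <- p[second] - phen$habituation_drop
    } else {
      p[fr] <- p[fr] + phen$startle_gain
    }
  }
  pmin(pmax(p, 0), 1)
}

#' Per-frame vertical step bias under a phenotype
#'
#' @inheritParams move_probability
#' @return Numeric vector in \[-1,1\]: `omr_gain[class]` signed by the
#'   line direction (+ up, - down); 0 outside visual periods.
#' @export
omr_bias <- function(phen, schedule) {
  stopifnot(inherits(phen, "phenotype"), inherits(schedule, "assay_schedule"))
  b <- numeric(n_frames(schedule))
  for (per in schedule$periods) {
    v <- per$visual
    if (is.null(v)) next
    fr <- frames_of_period(schedule, per$index) + 1L
    b[fr] <- phen$omr_gain[v$class] * if (v$direction == "up") 1 else -1
  }
  b
}

#' Expected behavior vector of a phenotype
#'
#' Closed-form expectations under the linear-probability model, in percent
#' / percentage points:
#' * baseline activities `act_1h`, `act_p15` = `100 * p_move_base`
#' * startle `S = 100 * startle_gain`
#' * excitability `E = 100 * (excitability_gain - habituation_drop / 2)`
#'   (the habituation drop depresses the second half of the fast-pulse
#'   period, whose mean enters E)
#' * habituation `Hab = 100 * habituation_drop`
#'
#' OMR expectations have no closed form (the occupancy of a reflected
#' biased walk); they are evaluated by the registered Monte-Carlo oracle
#' [expected_omr_mc()] when `omr = "mc"`, or reported as `NA` when
#' `omr = "none"` (all-zero gains always give exact zeros).
#'
#' @param phen A [phenotype()].
#' @param schedule Schedule the expectation refers to.
#' @param omr `"mc"`, `"none"`, or `"zero"` (assert all gains are zero and
#'   return exact zeros).
#' @param geometry,n_tracks,seed Passed to [expected_omr_mc()].
#' @return Named numeric vector with the 10 outcome measures (see
#'   [behavior_vector()]).
#' @export
expected_vector <- function(phen, schedule = default_schedule(),
                            omr = c("mc", "none", "zero"),
                            geometry = well_geometry(), n_tracks = 2000,
                            seed = 1L) {
  omr <- match.arg(omr)
  stopifnot(inherits(phen, "phenotype"))
  base <- 100 * phen$p_move_base
  out <- c(
    act_1h = base,
    act_p15 = base,
    hab = 100 * phen$habituation_drop,
    startle = 100 * phen$startle_gain,
    excit = 100 * (phen$excitability_gain - phen$habituation_drop / 2),
    omr_red = NA_real_, omr_green = NA_real_, omr_blue = NA_real_,
    omr_fast_red = NA_real_, omr_rgb = NA_real_
  )
  if (omr == "zero" || (omr == "mc" && all(phen$omr_gain == 0))) {
    if (any(phen$omr_gain != 0)) {
      stop('omr = "zero" requires all-zero omr_gain', call. = FALSE)
    }
    out[6:10] <- 0
  } else if (omr == "mc") {
    mc <- expected_omr_mc(phen, schedule, geometry, n_tracks = n_tracks, seed = seed)
    out[c("omr_red", "omr_green", "omr_blue", "omr_fast_red")] <-
      mc[c("red", "green", "blue", "fast_red")]
    out["omr_rgb"] <- mean(mc, na.rm = TRUE)
  }
  out
}

#' Monte-Carlo oracle for expected OMR responses
#'
#' Simulates `n_tracks` larvae under `phen` and averages the measured
#' per-class OMRs (excluding larvae/periods hit by the movement
#' exclusions). This is the registered oracle behind [expected_vector()]'s
#' OMR components and behind [calibrate_omr_gain()].
#'
#' @inheritParams expected_vector
#' @return Named numeric: mean OMR in percentage points per visual class.
#' @export
expected_omr_mc <- function(phen, schedule = default_schedule(),
                            geometry = well_geometry(),
                            n_tracks = 2000, seed = 1L) {
  vecs <- replicate_vectors(phen, schedule, geometry, n_tracks, seed)
  cols <- c("omr_red", "omr_green", "omr_blue", "omr_fast_red")
  out <- colMeans(vecs[, cols, drop = FALSE], na.rm = TRUE)
  names(out) <- sub("^omr_", "", cols)
  out
}

# Simulate n tracks of one phenotype and return their behavior-vector rows.
replicate_vectors <- function(phen, schedule, geometry, n, seed) {
  ctx <- metrics_context(schedule)
  rows <- matrix(NA_real_, n, length(behavior_measure_names()),
    dimnames = list(NULL, behavior_measure_names())
  )
  for (i in seq_len(n)) {
    tr <- simulate_track(phen, schedule, geometry, seed = well_seed(seed, 0L, i))
    v <- track_vector(tr, ctx)
    if (!is.null(v)) rows[i, ] <- v
  }
  as.data.frame(rows)
}

#' Calibrate an OMR gain for a target optomotor response
#'
#' Inverts the monotone gain-to-response curve of the step-bias model by
#' Monte-Carlo evaluation on a gain grid and monotone interpolation. Used
#' to program screen fixtures with a known expected OMR in percentage
#' points.
#'
#' @param target_pp Desired expected OMR (pp) for a single visual class
#'   applied to all classes.
#' @param phen Base phenotype whose activity parameters are kept.
#' @param schedule,geometry Assay context.
#' @param gains Gain grid to evaluate (must bracket the target).
#' @param n_tracks Monte-Carlo tracks per grid point.
#' @param seed RNG seed for the calibration simulations.
#' @return A single gain value in \[0,1\] (negative targets return the
#'   negated gain).
#' @export
calibrate_omr_gain <- function(target_pp, phen = phenotype(),
                               schedule = default_schedule(),
                               geometry = well_geometry(),
                               gains = seq(0, 1, by = 0.2),
                               n_tracks = 300, seed = 1L) {
  sign_t <- sign(target_pp)
  if (target_pp == 0) {
    return(0)
  }
  resp <- vapply(seq_along(gains), function(i) {
    g <- gains[i]
    ph <- phenotype(
      label = phen$label, p_move_base = phen$p_move_base,
      startle_gain = phen$startle_gain,
      excitability_gain = phen$excitability_gain,
      habituation_drop = phen$habituation_drop,
      omr_gain = g
    )
    mean(expected_omr_mc(ph, schedule, geometry,
      n_tracks = n_tracks,
      seed = well_seed(seed, 99L, i)
    ))
  }, numeric(1))
  if (abs(target_pp) > max(resp)) {
    stop("target OMR of ", target_pp, " pp exceeds the model's range (max ",
      round(max(resp), 1), " pp)",
      call. = FALSE
    )
  }
  # enforce monotonicity against Monte-Carlo jitter before inverting
  resp <- cummax(resp)
  sign_t * stats::approx(resp, gains, xout = abs(target_pp), ties = "ordered")$y
}
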