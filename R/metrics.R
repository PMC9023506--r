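#' Names of the ten behavioral outcome measures
#'
#' In assay notation: 1h, P15, Hab, S, E, R, G, B, FR, RGB.
#'
#' @param display If `TRUE`, return the short assay labels instead of the
#'   column names.
#' @return Character vector of length 10.
#' @export
behavior_measure_names <- function(display = FALSE) {
  cols <- c(
    "act_1h", "act_p15", "hab", "startle", "excit",
    "omr_red", "omr_green", "omr_blue", "omr_fast_red", "omr_rgb"
  )
  if (display) {
    c("1h", "P15", "Hab", "S", "E", "R", "G", "B", "FR", "RGB")
  } else {
    cols
  }
}

# Column names of the five activity-family / five OMR-family measures.
activity_measures <- function() behavior_measure_names()[1:5]
omr_measures <- function() behavior_measure_names()[6:10]

#' Convert a simulated track to per-frame observations
#'
#' Derives the "up" location state the image analysis would log: after
#' each movement the larva is classified as in the upper half of the well
#' (`y_mm > 0`); between movements the state is carried forward; before
#' the first movement it is undefined.
#'
#' @param track A `larva_track` from [simulate_track()].
#' @return Data.frame with columns `well`, `frame`, `moved`, `up`.
#' @export
track_to_observations <- function(track) {
  stopifnot(inherits(track, "larva_track"))
  m <- which(track$moved)
  up <- rep(NA, nrow(track))
  if (length(m)) {
    state <- track$y_mm[m] > 0
    idx <- findInterval(seq_len(nrow(track)), m)
    up[idx > 0] <- state[idx[idx > 0]]
  }
  data.frame(
    well = attr(track, "well") %||% NA_character_,
    frame = track$frame, moved = track$moved, up = up
  )
}

#' Summarize one larva's observations per period
#'
#' Computes, per 10-min period, the percentage of frames with movement
#' (`pct_move`) and the percentage of time the larva's location state is
#' "upper half" (`pct_up`; denominator = frames where the state is
#' defined, i.e. from the first movement onward with carry-forward — set
#' `up_weight = "event"` to average over movement frames only). For the
#' fast-pulse acoustic period the two half-period activities are also
#' reported (odd frame counts give the first half the extra frame).
#'
#' Exclusion rules are applied here: a larva moving less than
#' `min_total_pct` (default 1%) of the whole recording is excluded from
#' all statistics; periods in which it moves less than `min_period_pct`
#' (default 5%) are marked invalid for optomotor measurements.
#'
#' @param obs Observations for one well: data.frame with `frame`
#'   (0-based), `moved`, `up` (logical, NA where undefined). Frames must
#'   be contiguous; tracking output starting at frame 1 (no predecessor
#'   for the first image) is accepted.
#' @param schedule The `assay_schedule` the frames refer to.
#' @param min_total_pct,min_period_pct Exclusion thresholds in percent.
#' @param up_weight `"time"` (carry-forward state, default) or `"event"`
#'   (movement frames only).
#' @return A list with `summaries` (data.frame of 18 period rows) and
#'   `flags` (list `excluded_total`, `omr_period_invalid`).
#' @export
summarize_periods <- function(obs, schedule,
                              min_total_pct = 1, min_period_pct = 5,
                              up_weight = c("time", "event")) {
  up_weight <- match.arg(up_weight)
  stopifnot(all(c("frame", "moved", "up") %in% names(obs)))
  if (nrow(obs) == 0L) stop("no observations", call. = FALSE)
  obs <- obs[order(obs$frame), , drop = FALSE]
  if (any(diff(obs$frame) != 1L)) {
    stop("gaps in the frame series", call. = FALSE)
  }
  ctx <- metrics_context(schedule, min_total_pct, min_period_pct, up_weight)
  summarize_periods_impl(obs$frame, obs$moved, obs$up, ctx)
}

# Precomputed schedule structures shared by the per-larva loop.
metrics_context <- function(schedule, min_total_pct = 1, min_period_pct = 5,
                            up_weight = "time") {
  np <- length(schedule$periods)
  fast <- excitability_period(schedule)
  fast_frames <- frames_of_period(schedule, fast)
  first_half <- fast_frames[seq_len(ceiling(length(fast_frames) / 2))]
  pidx <- period_index_of_frame(schedule, 0:(n_frames(schedule) - 1L))
  list(
    schedule = schedule,
    n_periods = np,
    period_idx = pidx,
    idx_list = split(seq_len(n_frames(schedule)), pidx),
    fast_first_idx = first_half + 1L,
    fast_second_idx = setdiff(fast_frames, first_half) + 1L,
    baseline = baseline_periods(schedule),
    rest = rest_period(schedule),
    startle = startle_period(schedule),
    excit = fast,
    fast_first_half = first_half,
    pairs = omr_period_pairs(schedule),
    min_total_pct = min_total_pct,
    min_period_pct = min_period_pct,
    up_weight = up_weight
  )
}

summarize_periods_impl <- function(frame, moved, up, ctx) {
  np <- ctx$n_periods
  pid <- ctx$period_idx[frame + 1L]
  pct_move <- pct_up <- first_half <- second_half <- rep(NA_real_, np)
  n_fr <- n_up <- integer(np)
  use_up <- if (ctx$up_weight == "event") ifelse(moved, up, NA) else up
  for (k in seq_len(np)) {
    sel <- pid == k
    n_fr[k] <- sum(sel)
    if (n_fr[k] == 0L) next
    pct_move[k] <- 100 * mean(moved[sel])
    uk <- use_up[sel]
    n_up[k] <- sum(!is.na(uk))
    if (n_up[k] > 0L) pct_up[k] <- 100 * mean(uk, na.rm = TRUE)
  }
  in_first <- frame %in% ctx$fast_first_half
  sel_fast <- pid == ctx$excit
  if (any(sel_fast & in_first)) {
    first_half[ctx$excit] <- 100 * mean(moved[sel_fast & in_first])
  }
  if (any(sel_fast & !in_first)) {
    second_half[ctx$excit] <- 100 * mean(moved[sel_fast & !in_first])
  }
  summaries <- data.frame(
    period = seq_len(np), n_frames = n_fr,
    pct_move = pct_move, pct_up = pct_up,
    n_frames_defined_up = n_up,
    first_half_pct_move = first_half,
    second_half_pct_move = second_half
  )
  overall <- 100 * mean(moved)
  flags <- list(
    excluded_total = overall < ctx$min_total_pct,
    overall_pct_move = overall,
    omr_period_invalid = which(!is.na(pct_move) & pct_move < ctx$min_period_pct)
  )
  list(summaries = summaries, flags = flags)
}

#' Optomotor response from an up/down period pair
#'
#' Larval locations are compared between the two periods in which the
#' same lines move up vs. down: `pct_up(up period) - pct_up(down
#' period)`, in percentage points. Undefined (NA) when either period is
#' invalid under the 5% movement rule or has no defined location state.
#'
#' @param up_period,down_period Single rows of the `summaries` table of
#'   [summarize_periods()].
#' @param flags The `flags` element of [summarize_periods()].
#' @return OMR in percentage points, or `NA`.
#' @export
omr <- function(up_period, down_period, flags) {
  stopifnot(nrow(up_period) == 1L, nrow(down_period) == 1L)
  if (up_period$period == down_period$period) {
    stop("up and down periods must differ", call. = FALSE)
  }
  bad <- c(up_period$period, down_period$period) %in% flags$omr_period_invalid
  if (any(bad)) {
    return(NA_real_)
  }
  up_period$pct_up - down_period$pct_up
}

#' The ten behavioral outcome measures for one larva
#'
#' * `act_1h`: mean activity over the leading stimulus-free periods (1-6)
#' * `act_p15`: activity in the rest period (15)
#' * `hab`: first-half minus second-half activity of the fast-pulse
#'   period (17)
#' * `startle`: activity(16) - activity(15)
#' * `excit`: activity(17) - activity(16)
#' * `omr_red/green/blue/fast_red`: [omr()] over the scheduled down/up
#'   pairs (7,8), (9,10), (11,12), (13,14)
#' * `omr_rgb`: combined OMR; by default the mean of the defined per-class
#'   OMRs, or a pooled location comparison across all visual periods
#'   (`omr_combined = "pooled"`, weighting each period by its number of
#'   defined location frames).
#'
#' All values are percent / percentage points.
#'
#' @param period_summary Result of [summarize_periods()] (list with
#'   `summaries` and `flags`).
#' @param schedule The `assay_schedule`.
#' @param omr_combined `"mean"` or `"pooled"`.
#' @return Named numeric vector of the 10 measures.
#' @export
behavior_vector <- function(period_summary, schedule = default_schedule(),
                            omr_combined = c("mean", "pooled")) {
  omr_combined <- match.arg(omr_combined)
  s <- period_summary$summaries
  flags <- period_summary$flags
  if (isTRUE(flags$excluded_total)) {
    stop("larva is excluded (moved < threshold overall); no behavior vector",
      call. = FALSE
    )
  }
  ctx <- metrics_context(schedule)
  behavior_vector_impl(s, flags, ctx, omr_combined)
}

behavior_vector_impl <- function(s, flags, ctx, omr_combined = "mean") {
  pm <- s$pct_move
  out <- c(
    act_1h = mean(pm[ctx$baseline]),
    act_p15 = pm[ctx$rest],
    hab = s$first_half_pct_move[ctx$excit] - s$second_half_pct_move[ctx$excit],
    startle = pm[ctx$startle] - pm[ctx$rest],
    excit = pm[ctx$excit] - pm[ctx$startle],
    omr_red = NA_real_, omr_green = NA_real_, omr_blue = NA_real_,
    omr_fast_red = NA_real_, omr_rgb = NA_real_
  )
  per_class <- rep(NA_real_, length(ctx$pairs))
  names(per_class) <- names(ctx$pairs)
  for (cl in names(ctx$pairs)) {
    pr <- ctx$pairs[[cl]]
    if (any(pr %in% flags$omr_period_invalid)) next
    if (s$n_frames_defined_up[pr["up"]] == 0L ||
      s$n_frames_defined_up[pr["down"]] == 0L) {
      next
    }
    per_class[cl] <- s$pct_up[pr["up"]] - s$pct_up[pr["down"]]
  }
  key <- paste0("omr_", names(per_class))
  out[key[key %in% names(out)]] <- per_class[key %in% names(out)]
  if (omr_combined == "mean") {
    if (any(!is.na(per_class))) out["omr_rgb"] <- mean(per_class, na.rm = TRUE)
  } else {
    ups <- downs <- c(num = 0, den = 0)
    for (cl in names(ctx$pairs)) {
      pr <- ctx$pairs[[cl]]
      if (any(pr %in% flags$omr_period_invalid)) next
      for (side in c("up", "down")) {
        k <- pr[side]
        w <- s$n_frames_defined_up[k]
        if (w == 0L) next
        add <- c(num = w * s$pct_up[k], den = w)
        if (side == "up") ups <- ups + add else downs <- downs + add
      }
    }
    if (ups["den"] > 0 && downs["den"] > 0) {
      out["omr_rgb"] <- unname(ups["num"] / ups["den"] - downs["num"] / downs["den"])
    }
  }
  out
}

# Fast path for simulation screens: a full-length walk (list with moved
# and y) -> measure vector, NULL when the larva is excluded. Avoids
# data.frame construction but reuses behavior_vector_impl, so the vector
# assembly has a single source of truth.
sim_vector <- function(sim, ctx) {
  n <- length(sim$moved)
  overall <- 100 * sum(sim$moved) / n
  if (overall < ctx$min_total_pct) {
    return(NULL)
  }
  m <- which(sim$moved)
  up <- rep(NA, n)
  state <- sim$y[m] > 0
  posi <- findInterval(seq_len(n), m)
  up[posi > 0] <- state[posi[posi > 0]]
  if (ctx$up_weight == "event") up[!sim$moved] <- NA

  np <- ctx$n_periods
  pct_move <- pct_up <- rep(NA_real_, np)
  n_up <- integer(np)
  for (k in seq_len(np)) {
    ix <- ctx$idx_list[[k]]
    pct_move[k] <- 100 * sum(sim$moved[ix]) / length(ix)
    uk <- up[ix]
    def <- !is.na(uk)
    n_up[k] <- sum(def)
    if (n_up[k] > 0L) pct_up[k] <- 100 * sum(uk[def]) / n_up[k]
  }
  first_half <- second_half <- rep(NA_real_, np)
  first_half[ctx$excit] <-
    100 * sum(sim$moved[ctx$fast_first_idx]) / length(ctx$fast_first_idx)
  second_half[ctx$excit] <-
    100 * sum(sim$moved[ctx$fast_second_idx]) / length(ctx$fast_second_idx)
  s <- list(
    pct_move = pct_move, pct_up = pct_up, n_frames_defined_up = n_up,
    first_half_pct_move = first_half, second_half_pct_move = second_half
  )
  flags <- list(
    excluded_total = FALSE,
    omr_period_invalid = which(pct_move < ctx$min_period_pct)
  )
  behavior_vector_impl(s, flags, ctx)
}

# track (data.frame form) -> vector; full-length tracks take the fast
# path, anything else goes through the generic per-frame machinery.
track_vector <- function(track, ctx, omr_combined = "mean") {
  if (nrow(track) == length(ctx$period_idx) && track$frame[1] == 0L &&
    omr_combined == "mean" && ctx$up_weight == "time") {
    return(sim_vector(list(moved = track$moved, y = track$y_mm), ctx))
  }
  obs <- track_to_observations(track)
  ps <- summarize_periods_impl(obs$frame, obs$moved, obs$up, ctx)
  if (ps$flags$excluded_total) {
    return(NULL)
  }
  behavior_vector_impl(ps$summaries, ps$flags, ctx, omr_combined)
}

#' Per-larva behavior table for a screen
#'
#' Applies [summarize_periods()] and [behavior_vector()] to every track
#' and assembles the per-larva "summary sheet": one row per well with
#' plate, well, treatment label, the 10 measures, and the exclusion flag.
#' Excluded larvae keep their row (flagged, measures NA) so the exclusion
#' bookkeeping stays visible; downstream statistics drop them.
#'
#' @param tracks List of `larva_track`s (e.g. from [simulate_screen()]).
#' @param schedule The `assay_schedule`.
#' @param min_total_pct,min_period_pct,up_weight,omr_combined See
#'   [summarize_periods()] and [behavior_vector()].
#' @return Data.frame with columns `plate`, `well`, `label`, `excluded`,
#'   and the 10 measures.
#' @export
screen_vectors <- function(tracks, schedule = default_schedule(),
                           min_total_pct = 1, min_period_pct = 5,
                           up_weight = "time", omr_combined = "mean") {
  ctx <- metrics_context(schedule, min_total_pct, min_period_pct, up_weight)
  nm <- behavior_measure_names()
  rows <- lapply(tracks, function(tr) {
    obs <- track_to_observations(tr)
    ps <- summarize_periods_impl(obs$frame, obs$moved, obs$up, ctx)
    v <- if (ps$flags$excluded_total) {
      stats::setNames(rep(NA_real_, length(nm)), nm)
    } else {
      behavior_vector_impl(ps$summaries, ps$flags, ctx, omr_combined)
    }
    cbind(
      data.frame(
        plate = attr(tr, "plate") %||% NA_integer_,
        well = attr(tr, "well") %||% NA_character_,
        label = attr(tr, "label") %||% attr(tr, "phenotype")$label,
        excluded = ps$flags$excluded_total
      ),
      as.data.frame(as.list(v))
    )
  })
  do.call(rbind, rows)
}

#' Read/write per-larva vector tables as TSV
#' @param vectors Data.frame from [screen_vectors()].
#' @param path TSV path.
#' @return The path / the data.frame.
#' @export
write_vectors_tsv <- function(vectors, path) {
  utils::write.table(vectors, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vectors_tsv
#' @export
read_vectors_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
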