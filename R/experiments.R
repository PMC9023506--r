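#' Programmed-effect recovery experiment
#'
#' Simulates seeded replicates of a validation-style two-group experiment
#' — a vehicle control versus a treatment with programmed effects (see
#' [effect_phenotypes()]) — computes the per-replicate behavioral deltas
#' and Welch p-values, and flags them at the requested Bonferroni tier.
#' Used to verify that the full pipeline (simulation, metrics,
#' statistics) recovers known ground truth.
#'
#' @param phens Named list with `DMSO` and `treated` phenotypes, e.g.
#'   from [effect_phenotypes()].
#' @param n_per_group Larvae per group per replicate.
#' @param n_replicates Number of seeded replicates.
#' @param schedule,geometry Assay context.
#' @param seed Master seed; replicate r, group g, larva i gets a derived
#'   well seed.
#' @param m Bonferroni comparison count for flagging (default 11, the
#'   validation-experiment tier).
#' @param alpha Family-wise alpha for flagging.
#' @return List with `deltas` (replicates x 10 matrix, treatment minus
#'   control in pp), `p` (same shape), `flagged` (logical, p below
#'   `alpha/m`), and `threshold`.
#' @export
recovery_experiment <- function(phens, n_per_group = 160, n_replicates = 100,
                                schedule = default_schedule(),
                                geometry = well_geometry(), seed = 1L,
                                m = 11, alpha = 0.05) {
  ctx <- metrics_context(schedule)
  nm <- behavior_measure_names()
  deltas <- p <- matrix(NA_real_, n_replicates, length(nm),
    dimnames = list(NULL, nm)
  )
  thr <- bonferroni(alpha, m)
  caches <- lapply(phens[c("DMSO", "treated")], sim_cache,
    schedule = schedule, geometry = geometry
  )
  sim_group <- function(cache, rep, g) {
    rows <- matrix(NA_real_, n_per_group, length(nm))
    for (i in seq_len(n_per_group)) {
      v <- sim_vector(sim_walk(cache, well_seed(seed, rep * 10L + g, i)), ctx)
      if (!is.null(v)) rows[i, ] <- v
    }
    rows
  }
  for (r in seq_len(n_replicates)) {
    ctrl <- sim_group(caches$DMSO, r, 1L)
    trt <- sim_group(caches$treated, r, 2L)
    deltas[r, ] <- colMeans(trt, na.rm = TRUE) - colMeans(ctrl, na.rm = TRUE)
    for (b in seq_along(nm)) {
      x <- trt[, b]
      y <- ctrl[, b]
      # degenerate-sample warnings follow the documented p = 1 convention
      p[r, b] <- suppressWarnings(welch_test(x[!is.na(x)], y[!is.na(y)])$p)
    }
  }
  list(deltas = deltas, p = p, flagged = p < thr, threshold = thr)
}

#' Null-screen calibration experiment
#'
#' Simulates whole screens in which every treatment group has the same
#' phenotype as the vehicle control (no programmed effects), applies the
#' screening statistics, and counts per-comparison rejections at the
#' screen-wide Bonferroni threshold. Under a calibrated pipeline the
#' rejection rate matches the threshold up to Monte-Carlo error.
#'
#' @param n_screens Number of simulated screens.
#' @param n_groups Treatment groups per screen (the published screen has
#'   190).
#' @param n_per_group Larvae per treatment group.
#' @param n_control Larvae in the vehicle-control group.
#' @param phen The shared null phenotype.
#' @param schedule,geometry Assay context (reduced schedules keep the
#'   experiment cheap).
#' @param seed Master seed.
#' @param alpha,m Threshold definition (default 0.05/190).
#' @return List with `n_tests`, `n_reject`, `rate`, `threshold`.
#' @export
null_screen_calibration <- function(n_screens = 200, n_groups = 190,
                                    n_per_group = 12, n_control = 216,
                                    phen = phenotype("DMSO", p_move_base = 0.2),
                                    schedule = default_schedule(frame_interval_s = 60),
                                    geometry = well_geometry(), seed = 1L,
                                    alpha = 0.05, m = 190) {
  ctx <- metrics_context(schedule)
  nm <- behavior_measure_names()
  thr <- bonferroni(alpha, m)
  n_tests <- 0L
  n_reject <- 0L
  cache <- sim_cache(phen, schedule, geometry)
  sim_group <- function(n, screen, g) {
    rows <- matrix(NA_real_, n, length(nm))
    for (i in seq_len(n)) {
      v <- sim_vector(sim_walk(cache, well_seed(seed, screen * 251L + g, i)), ctx)
      if (!is.null(v)) rows[i, ] <- v
    }
    rows
  }
  for (s in seq_len(n_screens)) {
    ctrl <- sim_group(n_control, s, 0L)
    for (g in seq_len(n_groups)) {
      trt <- sim_group(n_per_group, s, g)
      for (b in seq_along(nm)) {
        x <- trt[, b]
        y <- ctrl[, b]
        x <- x[!is.na(x)]
        y <- y[!is.na(y)]
        if (length(x) < 2L || length(y) < 2L) next
        n_tests <- n_tests + 1L
        if (suppressWarnings(welch_test(x, y)$p) < thr) n_reject <- n_reject + 1L
      }
    }
  }
  list(
    n_tests = n_tests, n_reject = n_reject,
    rate = n_reject / n_tests, threshold = thr
  )
}
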