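test_that("track observations carry the location state forward", {
  s <- small_schedule()
  tr <- simulate_track(phenotype(p_move_base = 0.3, omr_gain = 0.4), s, seed = 21)
  obs <- track_to_observations(tr)
  # naive per-frame oracle
  up <- NA
  for (i in seq_len(nrow(tr))) {
    if (tr$moved[i]) up <- tr$y_mm[i] > 0
    expect_identical(obs$up[i], up)
  }
  first_move <- which(tr$moved)[1]
  if (!is.na(first_move) && first_move > 1) {
    expect_true(all(is.na(obs$up[seq_len(first_move - 1L)])))
  }
})

test_that("period summaries count movement and location correctly", {
  s <- small_schedule()
  # always moving: 100% everywhere, never excluded
  obs <- data.frame(
    frame = 0:179, moved = TRUE,
    up = rep(c(TRUE, FALSE), 90)
  )
  ps <- summarize_periods(obs, s)
  expect_equal(ps$summaries$pct_move, rep(100, 18))
  expect_equal(ps$summaries$pct_up, rep(50, 18))
  expect_false(ps$flags$excluded_total)
  expect_length(ps$flags$omr_period_invalid, 0)

  # moving 0.5% of the time overall: excluded
  obs2 <- data.frame(frame = 0:179, moved = FALSE, up = NA)
  obs2$moved[c(5, 100)] <- TRUE # wait: 2/180 > 1% -> use 0 moves in all but one
  obs2$moved[] <- FALSE
  obs2$moved[5] <- TRUE # 1/180 = 0.56%
  obs2$up[5:180] <- TRUE
  ps2 <- summarize_periods(obs2, s)
  expect_true(ps2$flags$excluded_total)
  expect_error(behavior_vector(ps2, s), "excluded")
})

test_that("summaries equal a brute-force frame-counting oracle on toy series", {
  set.seed(101)
  s <- small_schedule()
  for (rep in 1:25) {
    tr <- simulate_track(random_phenotype(), s, seed = 300 + rep)
    obs <- track_to_observations(tr)
    ps <- summarize_periods(obs, s)
    want <- oracle_vector(obs, s)
    if (is.null(want)) {
      expect_true(ps$flags$excluded_total)
    } else {
      got <- behavior_vector(ps, s)
      expect_equal(got, want)
    }
  }
})

test_that("tracking-style observations missing frame 0 are accepted", {
  s <- small_schedule()
  tr <- simulate_track(phenotype(p_move_base = 0.5), s, seed = 77)
  obs <- track_to_observations(tr)
  obs1 <- obs[obs$frame >= 1, ]
  ps <- summarize_periods(obs1, s)
  expect_equal(ps$summaries$n_frames[1], 9) # 10-frame period minus frame 0
  expect_equal(sum(ps$summaries$n_frames), 179)
  # gaps are an error
  expect_error(summarize_periods(obs[-10, ], s), "gaps")
})

test_that("the optomotor response compares up vs down periods", {
  s <- small_schedule()
  sm <- data.frame(
    period = 1:18, n_frames = 10,
    pct_move = 50, pct_up = 50,
    n_frames_defined_up = 10,
    first_half_pct_move = NA, second_half_pct_move = NA
  )
  up <- sm[8, ]
  up$pct_up <- 70
  down <- sm[7, ]
  down$pct_up <- 30
  flags <- list(excluded_total = FALSE, omr_period_invalid = integer(0))
  expect_equal(omr(up, down, flags), 40)
  expect_equal(omr(sm[8, ], sm[7, ], flags), 0)
  expect_equal(omr(down, up, flags), -40) # antisymmetry
  # a slow period invalidates the pair
  flags5 <- list(excluded_total = FALSE, omr_period_invalid = 7L)
  expect_true(is.na(omr(up, down, flags5)))
  expect_error(omr(up, up, flags), "differ")
})

test_that("larvae moving under 5% in a period lose that OMR but keep others", {
  s <- small_schedule()
  obs <- data.frame(frame = 0:179, moved = TRUE, up = TRUE)
  # period 7 (frames 60-69): no movement at all -> 0% < 5%
  obs$moved[61:70] <- FALSE
  ps <- summarize_periods(obs, s)
  expect_equal(ps$flags$omr_period_invalid, 7L)
  v <- behavior_vector(ps, s)
  expect_true(is.na(v[["omr_red"]]))
  expect_false(anyNA(v[c("omr_green", "omr_blue", "omr_fast_red", "omr_rgb")]))
})

test_that("behavior vector follows the printed definitions", {
  s <- small_schedule()
  sm <- data.frame(
    period = 1:18, n_frames = 10,
    pct_move = c(20, 22, 18, 20, 21, 19, rep(30, 8), 10, 18, 40, 25),
    pct_up = 50, n_frames_defined_up = 10,
    first_half_pct_move = NA_real_, second_half_pct_move = NA_real_
  )
  sm$first_half_pct_move[17] <- 45
  sm$second_half_pct_move[17] <- 35
  sm$pct_up[7:14] <- c(30, 70, 45, 55, 50, 50, 80, 20)
  ps <- list(
    summaries = sm,
    flags = list(excluded_total = FALSE, omr_period_invalid = integer(0))
  )
  v <- behavior_vector(ps, s)
  expect_equal(v[["act_1h"]], 20)
  expect_equal(v[["act_p15"]], 10)
  expect_equal(v[["startle"]], 8)
  expect_equal(v[["excit"]], 22)
  expect_equal(v[["hab"]], 10)
  expect_equal(v[["omr_red"]], 40)
  expect_equal(v[["omr_green"]], 10)
  expect_equal(v[["omr_blue"]], 0)
  expect_equal(v[["omr_fast_red"]], -60)
  expect_equal(v[["omr_rgb"]], mean(c(40, 10, 0, -60)))

  # all periods identical -> differences vanish
  sm2 <- sm
  sm2$pct_move <- 30
  sm2$pct_up <- 50
  sm2$first_half_pct_move[17] <- 30
  sm2$second_half_pct_move[17] <- 30
  v2 <- behavior_vector(list(summaries = sm2, flags = ps$flags), s)
  expect_equal(unname(v2[c("hab", "startle", "excit")]), c(0, 0, 0))
  expect_equal(unname(v2[omr_measures()]), rep(0, 5))
})

test_that("period-17 halves average back to the period activity", {
  s <- small_schedule()
  set.seed(8)
  tr <- simulate_track(
    phenotype(
      p_move_base = 0.3, startle_gain = 0.2,
      excitability_gain = 0.2, habituation_drop = 0.25
    ),
    s,
    seed = 15
  )
  ps <- summarize_periods(track_to_observations(tr), s)
  sm <- ps$summaries
  n17 <- sm$n_frames[17]
  n1 <- ceiling(n17 / 2)
  expect_equal(
    (n1 * sm$first_half_pct_move[17] + (n17 - n1) * sm$second_half_pct_move[17]) / n17,
    sm$pct_move[17]
  )
})

test_that("lowering the exclusion threshold never excludes an included larva", {
  s <- small_schedule()
  for (i in 1:10) {
    tr <- simulate_track(phenotype(p_move_base = 0.02), s, seed = 600 + i)
    obs <- track_to_observations(tr)
    at1 <- summarize_periods(obs, s, min_total_pct = 1)$flags$excluded_total
    at05 <- summarize_periods(obs, s, min_total_pct = 0.5)$flags$excluded_total
    if (!at1) expect_false(at05)
  }
})

test_that("event-weighted %up differs from time-weighted only via carry-forward", {
  s <- small_schedule()
  obs <- data.frame(frame = 0:179, moved = FALSE, up = NA)
  obs$moved[c(1, 2)] <- TRUE
  obs$up[1] <- TRUE # movement to the upper half at frame 0
  obs$up[2:180] <- FALSE # then a movement down, state carried to the end
  pt <- summarize_periods(obs, s, min_total_pct = 0)
  pe <- summarize_periods(obs, s, min_total_pct = 0, up_weight = "event")
  expect_equal(pt$summaries$pct_up[1], 10) # 1 of 10 defined frames up
  expect_equal(pe$summaries$pct_up[1], 50) # 1 of 2 movement events up
  expect_equal(pt$summaries$pct_up[5], 0) # carried-forward "down"
  expect_true(is.na(pe$summaries$pct_up[5])) # no events in period 5
})

test_that("the pooled combined-OMR variant weights periods by defined frames", {
  s <- small_schedule()
  tr <- simulate_track(phenotype(p_move_base = 0.4, omr_gain = 0.5), s, seed = 33)
  ps <- summarize_periods(track_to_observations(tr), s)
  v <- behavior_vector(ps, s, omr_combined = "pooled")
  sm <- ps$summaries
  ups <- c(8, 10, 12, 14)
  downs <- c(7, 9, 11, 13)
  pool <- function(idx) {
    stats::weighted.mean(sm$pct_up[idx], sm$n_frames_defined_up[idx])
  }
  expect_equal(v[["omr_rgb"]], pool(ups) - pool(downs))
})

test_that("screen vectors keep excluded larvae flagged with NA measures", {
  s <- small_schedule()
  lay <- plate_layout(
    data.frame(
      plate = 1L, row = "A", col = 1:3,
      label = c("DMSO", "dead", "DMSO")
    ),
    controls = "DMSO"
  )
  phens <- list(DMSO = phenotype(p_move_base = 0.3), dead = phenotype(p_move_base = 0))
  vecs <- screen_vectors(simulate_screen(lay, phens, s, seed = 3), s)
  expect_equal(nrow(vecs), 3)
  expect_equal(sum(vecs$excluded), 1)
  expect_true(all(is.na(vecs[vecs$excluded, behavior_measure_names()])))
  expect_false(anyNA(vecs[!vecs$excluded, c("act_1h", "startle")]))
})

test_that("vector tables round-trip through TSV", {
  s <- small_schedule()
  lay <- plate_layout(
    data.frame(plate = 1L, row = "A", col = 1:2, label = "DMSO"),
    controls = "DMSO"
  )
  vecs <- screen_vectors(
    simulate_screen(lay, list(DMSO = phenotype(p_move_base = 0.4)), s, seed = 4), s
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vectors_tsv(vecs, path)
  back <- read_vectors_tsv(path)
  expect_equal(back$act_1h, vecs$act_1h)
  expect_equal(back$well, vecs$well)
})
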