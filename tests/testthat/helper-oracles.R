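# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (plain loops, no shared code with the package
# internals) so they can serve as ground truth.

# A reduced-scale schedule: 10 frames per period, 180 frames total.
small_schedule <- function() default_schedule(frame_interval_s = 60)

# Brute-force period summaries + behavior vector from raw frames.
# Assumes the default 18-period structure (pairs 7/8, 9/10, 11/12,
# 13/14; rest 15; acoustic 16-18).
oracle_vector <- function(obs, schedule, min_total_pct = 1, min_period_pct = 5) {
  np <- length(schedule$periods)
  ends <- cumsum(vapply(schedule$periods, function(p) p$n_frames, integer(1)))
  tot <- mv <- upn <- upc <- rep(0, np)
  for (r in seq_len(nrow(obs))) {
    f <- obs$frame[r]
    p <- which(f < ends)[1]
    tot[p] <- tot[p] + 1
    if (obs$moved[r]) mv[p] <- mv[p] + 1
    if (!is.na(obs$up[r])) {
      upn[p] <- upn[p] + 1
      if (obs$up[r]) upc[p] <- upc[p] + 1
    }
  }
  pct_move <- ifelse(tot > 0, 100 * mv / tot, NA)
  pct_up <- ifelse(upn > 0, 100 * upc / upn, NA)
  if (100 * sum(mv) / sum(tot) < min_total_pct) {
    return(NULL) # excluded
  }
  invalid <- which(!is.na(pct_move) & pct_move < min_period_pct)
  # period-17 halves (first half gets the extra frame)
  f17 <- (ends[16]):(ends[17] - 1)
  half1 <- f17[seq_len(ceiling(length(f17) / 2))]
  c1 <- n1 <- c2 <- n2 <- 0
  for (r in seq_len(nrow(obs))) {
    f <- obs$frame[r]
    if (f %in% f17) {
      if (f %in% half1) {
        n1 <- n1 + 1
        if (obs$moved[r]) c1 <- c1 + 1
      } else {
        n2 <- n2 + 1
        if (obs$moved[r]) c2 <- c2 + 1
      }
    }
  }
  omr1 <- function(up_p, down_p) {
    if (up_p %in% invalid || down_p %in% invalid) {
      return(NA_real_)
    }
    if (upn[up_p] == 0 || upn[down_p] == 0) {
      return(NA_real_)
    }
    pct_up[up_p] - pct_up[down_p]
  }
  omrs <- c(omr1(8, 7), omr1(10, 9), omr1(12, 11), omr1(14, 13))
  c(
    act_1h = mean(pct_move[1:6]),
    act_p15 = pct_move[15],
    hab = 100 * c1 / n1 - 100 * c2 / n2,
    startle = pct_move[16] - pct_move[15],
    excit = pct_move[17] - pct_move[16],
    omr_red = omrs[1], omr_green = omrs[2], omr_blue = omrs[3],
    omr_fast_red = omrs[4],
    omr_rgb = if (all(is.na(omrs))) NA_real_ else mean(omrs, na.rm = TRUE)
  )
}

# Welch's t-test from the textbook formula.
oracle_welch <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Weighted mean squared difference by explicit loop.
oracle_wdist <- function(x, y, w) {
  num <- den <- 0
  for (i in seq_along(x)) {
    if (!is.na(x[i]) && !is.na(y[i])) {
      num <- num + w[i] * (x[i] - y[i])^2
      den <- den + w[i]
    }
  }
  num / den
}

# Random phenotype for oracle-equivalence sweeps: occasionally nearly
# immobile (hits the 1%/5% exclusion paths).
random_phenotype <- function() {
  base <- sample(c(0.005, 0.03, runif(1, 0.05, 0.6)), 1,
    prob = c(0.05, 0.15, 0.8)
  )
  phenotype(
    label = "rand",
    p_move_base = base,
    startle_gain = runif(1, 0, 0.3),
    excitability_gain = runif(1, 0, 0.3),
    habituation_drop = runif(1, 0, min(0.3, base)),
    omr_gain = runif(4, -0.8, 0.8)
  )
}
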