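#' Per-treatment group statistics
#'
#' Mean, SD, SEM and n per behavior per treatment label, computed over
#' included larvae. OMR components can be undefined for individual larvae
#' (period-level movement exclusions), so n may differ across behaviors
#' within a group; exclusion is per-measure, never propagated to the
#' activity behaviors.
#'
#' @param vectors Per-larva table from [screen_vectors()] (columns
#'   `label`, `excluded`, and the 10 measures).
#' @return Long data.frame: `label`, `behavior`, `n`, `mean`, `sd`, `sem`.
#' @export
aggregate_behavior <- function(vectors) {
  stopifnot("label" %in% names(vectors))
  if ("excluded" %in% names(vectors)) vectors <- vectors[!vectors$excluded, ]
  measures <- intersect(behavior_measure_names(), names(vectors))
  if (length(measures) == 0L) stop("no behavior columns found", call. = FALSE)
  labs <- unique(vectors$label)
  out <- expand.grid(
    behavior = measures, label = labs,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("label", "behavior")]
  stat <- function(lab, beh, f) {
    x <- vectors[vectors$label == lab, beh]
    x <- x[!is.na(x)]
    f(x)
  }
  out$n <- mapply(stat, out$label, out$behavior, MoreArgs = list(f = length))
  out$mean <- mapply(
    stat, out$label, out$behavior,
    MoreArgs = list(f = function(x) if (length(x)) mean(x) else NA_real_)
  )
  out$sd <- mapply(
    stat, out$label, out$behavior,
    MoreArgs = list(f = function(x) if (length(x) > 1) stats::sd(x) else NA_real_)
  )
  out$sem <- out$sd / sqrt(out$n)
  rownames(out) <- NULL
  out
}

#' Welch's unequal-variances t-test
#'
#' Two-sided Welch test via [stats::t.test()] with screening-friendly
#' degenerate-case conventions: samples with fewer than two finite values,
#' or two zero-variance samples with equal means, return `p = 1` with a
#' warning instead of failing (synthetic edge cases must not crash a
#' screen); two zero-variance samples with different means return `p = 0`.
#'
#' @param x,y Numeric samples (NAs dropped).
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' welch_test(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
#' @export
welch_test <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    warning("welch_test: sample with n < 2; returning p = 1", call. = FALSE)
    return(list(t = NA_real_, df = NA_real_, p = 1))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("welch_test: zero variance in both samples with equal means; returning p = 1",
        call. = FALSE
      )
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    warning("welch_test: zero variance in both samples with different means; returning p = 0",
      call. = FALSE
    )
    return(list(
      t = sign(mean(x) - mean(y)) * Inf,
      df = length(x) + length(y) - 2, p = 0
    ))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = unname(ht$p.value)
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (0 < alpha < 1).
#' @param m Number of comparisons.
#' @return `alpha / m`. The screen of 190 drugs uses 0.05/190 = 2.6e-4;
#'   the 11-drug validation 0.05/11 = 4.5e-3; the 3-dose concentration
#'   series 0.05/3 = 0.017.
#' @examples
#' bonferroni(0.05, 190) # 2.6e-4
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(length(alpha) == 1L, length(m) == 1L)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(m) || m < 1 || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  alpha / m
}

#' Behavioral profiles vs. the vehicle control
#'
#' For each treatment label, the per-behavior difference of group means
#' from the control group (percentage points) and the two-sided Welch
#' p-value of that comparison on the per-larva values. Per-larva values
#' are the statistical unit throughout.
#'
#' @param vectors Per-larva table from [screen_vectors()].
#' @param control Control label (default `"DMSO"`).
#' @param labels Treatment labels to profile (default: all non-control
#'   labels present).
#' @return A `behavioral_profiles` data.frame, one row per label x
#'   behavior: `label`, `behavior`, `delta_pp`, `p`, `n_treat`,
#'   `n_control`.
#' @export
behavioral_profiles <- function(vectors, control = "DMSO", labels = NULL) {
  stopifnot(control %in% vectors$label)
  if ("excluded" %in% names(vectors)) vectors <- vectors[!vectors$excluded, ]
  measures <- intersect(behavior_measure_names(), names(vectors))
  if (is.null(labels)) labels <- setdiff(unique(vectors$label), control)
  ctrl <- vectors[vectors$label == control, , drop = FALSE]
  rows <- list()
  for (lab in labels) {
    trt <- vectors[vectors$label == lab, , drop = FALSE]
    for (beh in measures) {
      x <- trt[[beh]][!is.na(trt[[beh]])]
      y <- ctrl[[beh]][!is.na(ctrl[[beh]])]
      delta <- if (length(x) >= 1L && length(y) >= 1L) mean(x) - mean(y) else NA_real_
      p <- if (length(x) >= 2L && length(y) >= 2L) welch_test(x, y)$p else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, behavior = beh, delta_pp = delta, p = p,
        n_treat = length(x), n_control = length(y)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "control") <- control
  class(out) <- c("behavioral_profiles", "data.frame")
  out
}

#' Profiles in wide (label x behavior) matrix form
#' @param profiles A `behavioral_profiles` data.frame.
#' @param value Column to spread (default `"delta_pp"`).
#' @return Numeric matrix, labels as rownames, the 10 behaviors as
#'   columns.
#' @export
profiles_matrix <- function(profiles, value = "delta_pp") {
  labs <- unique(profiles$label)
  behs <- intersect(behavior_measure_names(), unique(profiles$behavior))
  m <- matrix(NA_real_, length(labs), length(behs),
    dimnames = list(labs, behs)
  )
  m[cbind(
    match(profiles$label, labs),
    match(profiles$behavior, behs)
  )] <- profiles[[value]]
  m
}

#' Tiered Bonferroni significance flags for a screen
#'
#' Flags each label x behavior p-value against `alpha / m` for alpha =
#' 0.05 (`*`), 0.01 (`**`) and 0.001 (`***`); a drug is "significant"
#' when any behavior passes the 0.05/m tier. Comparisons use unrounded
#' thresholds.
#'
#' @param profiles A `behavioral_profiles` data.frame.
#' @param m Number of comparisons for the Bonferroni correction (190 for
#'   the full screen, 11 for the validation set, 3 for a dose series).
#' @param alphas The three tier alphas.
#' @return The profiles data.frame with a `tier` column (`ns`, `*`, `**`,
#'   `***`) plus attribute `significant_labels`.
#' @export
screen_significance <- function(profiles, m, alphas = c(0.05, 0.01, 0.001)) {
  stopifnot(all(diff(alphas) < 0))
  thr <- vapply(alphas, bonferroni, numeric(1), m = m)
  tier <- rep("ns", nrow(profiles))
  for (k in seq_along(thr)) {
    tier[!is.na(profiles$p) & profiles$p < thr[k]] <-
      paste(rep("*", k), collapse = "")
  }
  profiles$tier <- tier
  sig <- unique(profiles$label[profiles$tier != "ns"])
  attr(profiles, "thresholds") <- stats::setNames(thr, paste0("alpha_", alphas))
  attr(profiles, "significant_labels") <- sig
  profiles
}

#' Diverging profile colors
#'
#' Maps percentage-point differences to the assay's diverging color
#' scale, clipped at +/-25 pp: green for decreases, red for increases,
#' passing through white (screen style) or black (cluster style) at zero.
#'
#' @param delta_pp Numeric vector of differences.
#' @param style `"screen"` (white midpoint) or `"cluster"` (black
#'   midpoint).
#' @param clip_pp Clipping magnitude (default 25).
#' @return Character vector of hex colors; NA deltas give `"#808080"`.
#' @export
profile_colors <- function(delta_pp, style = c("screen", "cluster"),
                           clip_pp = 25) {
  style <- match.arg(style)
  mid <- if (style == "screen") "#FFFFFF" else "#000000"
  ramp <- grDevices::colorRamp(c("#00FF00", mid, "#FF0000"))
  z <- pmin(pmax(delta_pp / clip_pp, -1), 1)
  out <- rep("#808080", length(z))
  ok <- !is.na(z)
  if (any(ok)) {
    rgbm <- ramp((z[ok] + 1) / 2)
    out[ok] <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3], maxColorValue = 255)
  }
  out
}

#' Color-coded profile table
#'
#' The screen's overview artifact: a label x behavior table of
#' percentage-point differences on the diverging green/white(black)/red
#' scale with significance-tier annotations.
#'
#' @param profiles A `behavioral_profiles` data.frame, ideally after
#'   [screen_significance()].
#' @param style,clip_pp See [profile_colors()].
#' @param file Optional PNG path to save to.
#' @return A ggplot object, invisibly if `file` is given.
#' @export
export_profile_table <- function(profiles, style = c("screen", "cluster"),
                                 clip_pp = 25, file = NULL) {
  style <- match.arg(style)
  df <- as.data.frame(profiles)
  df$behavior <- factor(df$behavior, levels = behavior_measure_names(),
    labels = behavior_measure_names(display = TRUE)
  )
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  df$fill <- profile_colors(df$delta_pp, style, clip_pp)
  df$note <- if ("tier" %in% names(df)) sub("^ns$", "", df$tier) else ""
  p <- ggplot2::ggplot(df, ggplot2::aes(x = behavior, y = label)) +
    ggplot2::geom_tile(ggplot2::aes(fill = fill), color = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = note),
      size = 3,
      color = if (style == "screen") "black" else "white"
    ) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf(
        "Behavioral profiles vs. %s (clip ±%g pp)",
        attr(profiles, "control") %||% "control", clip_pp
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p,
      width = 6, height = 1 + 0.3 * length(levels(df$label)), dpi = 150
    )
    return(invisible(p))
  }
  p
}

#' Write behavioral profiles as TSV
#' @param profiles A `behavioral_profiles` data.frame.
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  utils::write.table(as.data.frame(profiles), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
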