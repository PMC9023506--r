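#' Packaged reference profile families
#'
#' Two fixture families of behavioral profiles with the qualitative sign
#' structure of the calcineurin-axis compound classes: a "CsA-like"
#' family (hyperactive early and in the rest period, more excitable,
#' reduced optomotor responses) and an "INDY-like" family with the
#' opposite signs. Magnitudes are fixture parameters on the scale of the
#' validated drug effects (10-20 pp), not measured ground truth; each
#' family member adds independent Gaussian noise of `noise_sd` pp.
#'
#' @param n_per_family Members per family.
#' @param noise_sd Per-component noise SD in pp (0 gives identical
#'   members).
#' @param seed RNG seed.
#' @return A [feature_matrix()] of `2 * n_per_family` rows with a
#'   `family` attribute (named character vector).
#' @examples
#' sign(reference_profiles(noise_sd = 0)["CsA-like-1", ])
#' @export
reference_profiles <- function(n_per_family = 6, noise_sd = 3, seed = 1L) {
  base_csa <- c(
    act_1h = 15, act_p15 = 12, hab = 0, startle = 0, excit = 15,
    omr_red = -12, omr_green = -10, omr_blue = -12,
    omr_fast_red = -18, omr_rgb = -13
  )
  set.seed(seed)
  build <- function(center, fam) {
    t(vapply(seq_len(n_per_family), function(i) {
      center + stats::rnorm(length(center), 0, noise_sd)
    }, numeric(length(center))))
  }
  m <- rbind(build(base_csa, "CsA"), build(-base_csa, "INDY"))
  rownames(m) <- c(
    paste0("CsA-like-", seq_len(n_per_family)),
    paste0("INDY-like-", seq_len(n_per_family))
  )
  fam <- stats::setNames(
    rep(c("CsA", "INDY"), each = n_per_family), rownames(m)
  )
  out <- feature_matrix(m)
  attr(out, "family") <- fam
  out
}

#' Phenotype map for a programmed-effect demonstration screen
#'
#' A control phenotype plus one treatment phenotype with programmed
#' effects: `d_activity` pp added to baseline activity, `d_excit` pp to
#' excitability, and OMR gains calibrated (Monte-Carlo inversion, see
#' [calibrate_omr_gain()]) so the expected treatment-minus-control OMR is
#' `d_omr_pp`.
#'
#' @param d_activity,d_excit,d_omr_pp Programmed effects in percentage
#'   points.
#' @param control_omr_pp The control group's expected OMR (real vehicle
#'   larvae do follow the moving lines).
#' @param base Control baseline movement probability.
#' @param schedule,geometry Assay context for the OMR calibration.
#' @param calib_tracks Monte-Carlo tracks per calibration grid point.
#' @param seed Calibration seed.
#' @return Named list of two [phenotype()]s: `DMSO` and `treated`.
#' @export
effect_phenotypes <- function(d_activity = 20, d_excit = 15, d_omr_pp = -20,
                              control_omr_pp = 30, base = 0.2,
                              schedule = default_schedule(),
                              geometry = well_geometry(),
                              calib_tracks = 300, seed = 1L) {
  g_ctrl <- calibrate_omr_gain(control_omr_pp,
    phen = phenotype(p_move_base = base),
    schedule = schedule, geometry = geometry,
    n_tracks = calib_tracks, seed = seed
  )
  g_trt <- calibrate_omr_gain(control_omr_pp + d_omr_pp,
    phen = phenotype(p_move_base = base + d_activity / 100),
    schedule = schedule, geometry = geometry,
    n_tracks = calib_tracks, seed = seed + 1L
  )
  list(
    DMSO = phenotype("DMSO", p_move_base = base, omr_gain = g_ctrl),
    treated = phenotype("treated",
      p_move_base = base + d_activity / 100,
      excitability_gain = d_excit / 100,
      omr_gain = g_trt
    )
  )
}
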