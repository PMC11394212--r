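#' Calibration configuration
#'
#' Controls automated threshold placement on the donor's unstimulated
#' sample. Defaults: the CD63 positivity target is 1% (the
#' one-percent-in-unstimulated convention), the CD32 red-percentage
#' target is 70%, candidate axis thresholds are drawn from quantile
#' grids, and a candidate is feasible when the upper-left (UL) quadrant
#' holds a plausible basophil fraction and is sufficiently CD32-pure.
#'
#' @param cd63_target_pct CD63+ target in the unstimulated basophils
#'   (default 1).
#' @param cd32_target_pct CD32 red-percentage target (default 70).
#' @param cd32_purity_min minimum UL CD32+ fraction (%) during the axis
#'   search (default 80: genuine basophil clouds reach well above 90%
#'   even with an allergic baseline CD32 downshift, while CD32-bright
#'   granulocyte FcERIa-tail artifacts stay below ~75%).
#' @param baso_freq_bounds plausible basophil fraction of gated events,
#'   in percent (default `c(0.05, 3)`).
#' @param ssc_quantile_grid,fcer1a_quantile_grid candidate threshold
#'   quantiles (probabilities).
#' @param cd32_provisional_quantile quantile of whole-sample CD32 used
#'   as the provisional CD32+ cut during the axis search (default 0.40,
#'   low enough that a 70%-pure basophil cloud passes).
#' @return a `calibration_config`.
#' @export
calibration_config <- function(cd63_target_pct = 1.0, cd32_target_pct = 70.0,
                               cd32_purity_min = 80.0,
                               baso_freq_bounds = c(0.05, 3.0),
                               ssc_quantile_grid = seq(0.30, 0.80, by = 0.05),
                               fcer1a_quantile_grid = c(0.950, 0.960, 0.970, 0.975,
                                                        0.980, 0.985, 0.990, 0.9925,
                                                        0.995, 0.9975),
                               cd32_provisional_quantile = 0.40) {
  if (cd63_target_pct <= 0 || cd63_target_pct >= 100)
    stop_binbat("binbat_config_error", "cd63_target_pct must be in (0, 100)")
  if (cd32_target_pct <= 0 || cd32_target_pct >= 100)
    stop_binbat("binbat_config_error", "cd32_target_pct must be in (0, 100)")
  if (baso_freq_bounds[1] >= baso_freq_bounds[2])
    stop_binbat("binbat_config_error", "baso_freq_bounds must be ordered (low, high)")
  structure(list(
    cd63_target_pct = cd63_target_pct, cd32_target_pct = cd32_target_pct,
    cd32_purity_min = cd32_purity_min, baso_freq_bounds = baso_freq_bounds,
    ssc_quantile_grid = ssc_quantile_grid,
    fcer1a_quantile_grid = fcer1a_quantile_grid,
    cd32_provisional_quantile = cd32_provisional_quantile
  ), class = "calibration_config")
}

#' Automated SSC / FcERIa axis threshold placement
#'
#' Grid search over candidate threshold pairs drawn from the configured
#' quantile grids of the pregated, transformed unstimulated sample. The
#' basophil (upper-left) quadrant is `SSC < thr_ssc` and
#' `FcERIa >= thr_fcer1a`. A candidate is feasible when (a) the UL
#' event fraction lies within `baso_freq_bounds` and (b) the UL CD32+
#' fraction — at a provisional CD32 cut set to the sample's 40th
#' percentile — is at least `cd32_purity_min`. Among feasible
#' candidates, the one with the highest UL CD32+ purity wins; purities
#' within 5 percentage points of the best are treated as tied (such
#' differences are sampling noise at basophil event counts, and chasing
#' them needlessly shrinks the recovered cloud), with ties broken by
#' larger UL event count, then lower FcERIa threshold, then lower SSC
#' threshold. Deterministic.
#'
#' @param unstim pregated, transformed unstimulated `event_table`.
#' @param map a [channel_map].
#' @param cfg a [calibration_config()].
#' @return list `thr_ssc`, `thr_fcer1a`, plus `ul_fraction_pct`,
#'   `ul_cd32_purity_pct`, `n_ul` diagnostics.
#' @export
find_axis_thresholds <- function(unstim, map, cfg = calibration_config()) {
  ssc <- marker_values(unstim, "SSC", map)
  fce <- marker_values(unstim, "FCER1A", map)
  cd32 <- marker_values(unstim, "CD32", map)
  n <- n_events(unstim)
  if (n == 0L) stop_binbat("binbat_empty_sample", "no events for calibration")
  cd32_prov <- nearest_rank_quantile(cd32, cfg$cd32_provisional_quantile)
  cand_ssc <- unique(nearest_rank_quantile(ssc, cfg$ssc_quantile_grid))
  cand_fce <- unique(nearest_rank_quantile(fce, cfg$fcer1a_quantile_grid))
  feasible <- list()
  for (ts in cand_ssc) {
    in_left <- ssc < ts
    for (tf in cand_fce) {
      in_ul <- in_left & fce >= tf
      n_ul <- sum(in_ul)
      frac_pct <- 100 * n_ul / n
      if (frac_pct < cfg$baso_freq_bounds[1] || frac_pct > cfg$baso_freq_bounds[2]) next
      purity <- 100 * sum(cd32[in_ul] > cd32_prov) / n_ul
      if (purity < cfg$cd32_purity_min) next
      feasible[[length(feasible) + 1]] <- list(thr_ssc = ts, thr_fcer1a = tf,
                                               n_ul = n_ul, purity = purity)
    }
  }
  if (!length(feasible))
    stop_binbat("binbat_calibration_failure",
                "no feasible SSC/FcERIa threshold pair (basophil quadrant not identifiable)")
  pur <- vapply(feasible, `[[`, numeric(1), "purity")
  top <- feasible[pur >= max(pur) - 5]
  ord <- order(-vapply(top, `[[`, numeric(1), "n_ul"),
               vapply(top, `[[`, numeric(1), "thr_fcer1a"),
               vapply(top, `[[`, numeric(1), "thr_ssc"))
  best <- top[[ord[1]]]
  list(thr_ssc = best$thr_ssc, thr_fcer1a = best$thr_fcer1a,
       ul_fraction_pct = 100 * best$n_ul / n,
       ul_cd32_purity_pct = best$purity, n_ul = best$n_ul)
}

#' Calibrate a z-marker threshold to a target positive fraction
#'
#' The threshold is the nearest-rank `(100 - target_pos_pct)` percentile
#' of the z values of the basophil events. With the package's
#' strictly-above positivity rule, the realized positive fraction is the
#' largest achievable value not exceeding the target on the empirical
#' distribution (granularity `100 / n` percentage points).
#'
#' @param z numeric vector of basophil z values (transformed scale), or
#'   an `event_table` together with `z_marker`/`map`.
#' @param target_pos_pct target positive percentage (e.g. 1 for CD63,
#'   70 for CD32).
#' @param z_marker,map used when `z` is an `event_table`.
#' @return the threshold (numeric scalar); attribute
#'   `"realized_pos_pct"` holds the realized positive percentage.
#' @export
calibrate_z_threshold <- function(z, target_pos_pct, z_marker = NULL, map = NULL) {
  if (inherits(z, "event_table")) z <- marker_values(z, z_marker, map)
  n <- length(z)
  if (n < 10)
    stop_binbat("binbat_insufficient_events",
                sprintf("z-threshold calibration needs >= 10 events, got %d", n))
  if (n < 50)
    warn_binbat("binbat_low_events",
                sprintf("z-threshold calibrated on only %d events (< 50)", n))
  thr <- nearest_rank_quantile(z, (100 - target_pos_pct) / 100)
  realized <- 100 * sum(z > thr) / n
  if (length(unique(z)) == 1L)
    warn_binbat("binbat_degenerate_z",
                "degenerate z distribution (all values identical): 0% positive at any target")
  attr(thr, "realized_pos_pct") <- realized
  thr
}

#' Threshold set calibrated on an unstimulated sample
#'
#' @param thr_ssc,thr_fcer1a,thr_cd63,thr_cd32 calibrated cut points on
#'   the transformed scale.
#' @param calibrated_on sample identifier of the UNSTIM sample used.
#' @param target_quadrant basophil quadrant (default `"UL"`).
#' @return an immutable `threshold_set` (applied verbatim to all other
#'   samples of the donor).
#' @export
threshold_set <- function(thr_ssc, thr_fcer1a, thr_cd63, thr_cd32,
                          calibrated_on, target_quadrant = "UL") {
  vals <- c(thr_ssc, thr_fcer1a, thr_cd63, thr_cd32)
  if (any(!is.finite(vals)))
    stop_binbat("binbat_config_error", "all thresholds must be finite")
  structure(list(
    thr_ssc = as.numeric(thr_ssc), thr_fcer1a = as.numeric(thr_fcer1a),
    thr_cd63 = as.numeric(thr_cd63), thr_cd32 = as.numeric(thr_cd32),
    calibrated_on = calibrated_on, target_quadrant = target_quadrant
  ), class = "threshold_set")
}

#' Apply a frozen threshold set to one sample
#'
#' Selects the basophil (UL) quadrant with the calibrated SSC/FcERIa
#' thresholds and computes CD63+ and CD32+ percentages among those
#' events with the calibrated z cuts. No re-fitting happens here; the
#' same `threshold_set` is applied verbatim to every sample of the
#' donor.
#'
#' @param sample pregated, transformed `event_table`.
#' @param map a [channel_map].
#' @param ts a [threshold_set()].
#' @return list `n_gated`, `n_basophils`, `cd63_pos_pct`,
#'   `cd32_pos_pct` (percentages are `NA` when the quadrant is empty).
#' @export
apply_thresholds <- function(sample, map, ts) {
  ssc <- marker_values(sample, "SSC", map)
  fce <- marker_values(sample, "FCER1A", map)
  cd63 <- marker_values(sample, "CD63", map)
  cd32 <- marker_values(sample, "CD32", map)
  in_ul <- ssc < ts$thr_ssc & fce >= ts$thr_fcer1a
  n_b <- sum(in_ul)
  list(
    n_gated = n_events(sample),
    n_basophils = as.integer(n_b),
    cd63_pos_pct = if (n_b) 100 * sum(cd63[in_ul] > ts$thr_cd63) / n_b else NA_real_,
    cd32_pos_pct = if (n_b) 100 * sum(cd32[in_ul] > ts$thr_cd32) / n_b else NA_real_)
}
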