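#' Full analysis configuration
#'
#' Bundles everything one run needs: channel map, transform spec,
#' pregate and calibration settings, decision cutoffs, QC limits, bin
#' settings and seed. Serializable to/from YAML or JSON; a run's config
#' is embedded in its result JSON for provenance.
#'
#' @param map a [channel_map].
#' @param transform a `transform_spec` (default [default_transform_spec()]
#'   over `map`).
#' @param pregate a [pregate_config()].
#' @param calibration a [calibration_config()].
#' @param responder_cutoff_pct positive-control CD63+% at or above which
#'   the donor is a responder (default 10; not a literature constant —
#'   config-exposed and echoed in every call).
#' @param activation_cutoff_pct allergen CD63+% at or above which a BAT
#'   is called positive (default 5), together with
#' @param activation_fold the required fold-change over the
#'   unstimulated baseline (default 2).
#' @param qc_min_gated,qc_min_baso_warn,qc_min_baso_block QC limits
#'   (defaults 5000, 50, 10).
#' @param bin_width,min_cells_per_bin PRI bin settings (defaults 0.2
#'   transformed units, 10 cells).
#' @param seed integer seed for the (seeded) pregate subsampling.
#' @return a `bat_config`.
#' @export
bat_config <- function(map = default_channel_map(),
                       transform = default_transform_spec(map),
                       pregate = pregate_config(),
                       calibration = calibration_config(),
                       responder_cutoff_pct = 10,
                       activation_cutoff_pct = 5,
                       activation_fold = 2,
                       qc_min_gated = 5000,
                       qc_min_baso_warn = 50,
                       qc_min_baso_block = 10,
                       bin_width = 0.2,
                       min_cells_per_bin = 10L,
                       seed = 1L) {
  structure(list(
    map = map, transform = transform, pregate = pregate, calibration = calibration,
    responder_cutoff_pct = responder_cutoff_pct,
    activation_cutoff_pct = activation_cutoff_pct,
    activation_fold = activation_fold,
    qc_min_gated = qc_min_gated, qc_min_baso_warn = qc_min_baso_warn,
    qc_min_baso_block = qc_min_baso_block,
    bin_width = bin_width, min_cells_per_bin = as.integer(min_cells_per_bin),
    seed = as.integer(seed)
  ), class = "bat_config")
}

qc_flag <- function(code, severity, message) {
  code <- match.arg(code, c("LOW_EVENTS", "LOW_BASOPHILS", "THRESHOLD_OUT_OF_RANGE",
                            "CALIBRATION_FAILED", "EMPTY_QUADRANT", "DEGENERATE_Z"))
  severity <- match.arg(severity, c("WARNING", "BLOCKING"))
  list(code = code, severity = severity, message = message)
}

has_blocking <- function(flags) {
  any(vapply(flags, function(f) identical(f$severity, "BLOCKING"), logical(1)))
}

#' Evaluate quality-control flags for one sample result
#'
#' Pure rule set (all limits config-exposed): LOW_EVENTS when fewer
#' gated events than `qc_min_gated` (warning); LOW_BASOPHILS below
#' `qc_min_baso_warn` (warning) or `qc_min_baso_block` (blocking);
#' EMPTY_QUADRANT when the basophil quadrant is empty (blocking);
#' THRESHOLD_OUT_OF_RANGE when a calibrated threshold falls outside the
#' channel's observed 0.1–99.9% quantile span (warning); DEGENERATE_Z
#' when the basophil CD63 distribution is a point mass (warning).
#' Blocking flags suppress activation calls for the sample.
#'
#' @param sr sample result list (from [apply_thresholds()]).
#' @param sample the pregated, transformed `event_table` behind `sr`.
#' @param ts the applied [threshold_set()].
#' @param cfg a [bat_config()].
#' @param map channel map (default from `cfg`).
#' @return list of QC flags (possibly empty).
#' @export
evaluate_qc <- function(sr, sample, ts, cfg, map = cfg$map) {
  flags <- list()
  if (sr$n_gated < cfg$qc_min_gated)
    flags <- c(flags, list(qc_flag("LOW_EVENTS", "WARNING",
      sprintf("only %d gated events (< %d)", sr$n_gated, cfg$qc_min_gated))))
  if (sr$n_basophils == 0) {
    flags <- c(flags, list(qc_flag("EMPTY_QUADRANT", "BLOCKING",
      "basophil quadrant contains no events")))
  } else if (sr$n_basophils < cfg$qc_min_baso_block) {
    flags <- c(flags, list(qc_flag("LOW_BASOPHILS", "BLOCKING",
      sprintf("only %d basophil events (< %d)", sr$n_basophils, cfg$qc_min_baso_block))))
  } else if (sr$n_basophils < cfg$qc_min_baso_warn) {
    flags <- c(flags, list(qc_flag("LOW_BASOPHILS", "WARNING",
      sprintf("only %d basophil events (< %d)", sr$n_basophils, cfg$qc_min_baso_warn))))
  }
  # axis thresholds are judged against the whole sample; the z-marker
  # thresholds against the basophil quadrant they are applied to
  in_ul <- marker_values(sample, "SSC", map) < ts$thr_ssc &
    marker_values(sample, "FCER1A", map) >= ts$thr_fcer1a
  span_check <- list(SSC = ts$thr_ssc, FCER1A = ts$thr_fcer1a,
                     CD63 = ts$thr_cd63, CD32 = ts$thr_cd32)
  for (m in names(span_check)) {
    v <- marker_values(sample, m, map)
    if (m %in% c("CD63", "CD32") && any(in_ul)) v <- v[in_ul]
    span <- nearest_rank_quantile(v, c(0.001, 0.999))
    thr <- span_check[[m]]
    if (thr < span[1] || thr > span[2]) {
      flags <- c(flags, list(qc_flag("THRESHOLD_OUT_OF_RANGE", "WARNING",
        sprintf("%s threshold %.4g outside observed 0.1-99.9%% span [%.4g, %.4g]",
                m, thr, span[1], span[2]))))
      break
    }
  }
  if (sr$n_basophils > 0) {
    z <- marker_values(sample, "CD63", map)[in_ul]
    if (length(unique(z)) == 1L)
      flags <- c(flags, list(qc_flag("DEGENERATE_Z", "WARNING",
        "basophil CD63 distribution is degenerate (single value)")))
  }
  flags
}

#' Run the full automated bin-BAT pipeline on one experiment
#'
#' Fully automated steps, in order: pregate every file (singlets,
#' debris, thrombocytes), transform, calibrate all thresholds on the
#' donor's single unstimulated sample (SSC/FcERIa axis search with CD32
#' purity; CD63 at the 1% convention; CD32 at the 70% red-percentage
#' rule), apply the frozen threshold set verbatim to every sample,
#' compute per-sample basophil counts and CD63+/CD32+ percentages,
#' attach QC flags, derive the donor's responder status from the
#' positive control and per-allergen activation calls. Deterministic:
#' identical inputs and config yield byte-identical result JSON.
#'
#' @param samples list of per-sample lists with elements `events` (raw
#'   `event_table`) and `meta` ([sample_meta()]); exactly one UNSTIM
#'   sample plus at least one other.
#' @param cfg a [bat_config()].
#' @return an `experiment_result`: `donor_id`, `thresholds`,
#'   `calibration` diagnostics, per-sample `samples` (each with `meta`,
#'   `n_gated`, `n_basophils`, `cd63_pos_pct`, `cd32_pos_pct`,
#'   `qc_flags`), `responder_status`, `allergen_calls`, `call_rules`,
#'   `config` echo.
#' @export
analyze_experiment <- function(samples, cfg = bat_config()) {
  conds <- vapply(samples, function(s) s$meta$condition, character(1))
  if (sum(conds == "UNSTIM") != 1L)
    stop_binbat("binbat_config_error", "experiment needs exactly one UNSTIM sample")
  if (length(samples) < 2L)
    stop_binbat("binbat_config_error", "experiment needs at least one non-UNSTIM sample")
  donor_id <- samples[[which(conds == "UNSTIM")]]$meta$donor_id

  prepped <- lapply(samples, function(s) {
    validate_channel_map(s$events, cfg$map, require_all = TRUE)
    g <- pregate(s$events, cfg$map, cfg$pregate)
    tt <- apply_transform(g, cfg$transform)
    attr(tt, "retention") <- attr(g, "retention")
    list(events = tt, meta = s$meta)
  })
  unstim <- prepped[[which(conds == "UNSTIM")]]

  calib <- tryCatch({
    ax <- find_axis_thresholds(unstim$events, cfg$map, cfg$calibration)
    ssc <- marker_values(unstim$events, "SSC", cfg$map)
    fce <- marker_values(unstim$events, "FCER1A", cfg$map)
    in_ul <- ssc < ax$thr_ssc & fce >= ax$thr_fcer1a
    baso <- subset_events(unstim$events, in_ul)
    thr63 <- withCallingHandlers(
      calibrate_z_threshold(baso, cfg$calibration$cd63_target_pct, "CD63", cfg$map),
      binbat_warning = function(w) invokeRestart("muffleWarning"))
    thr32 <- withCallingHandlers(
      calibrate_z_threshold(baso, cfg$calibration$cd32_target_pct, "CD32", cfg$map),
      binbat_warning = function(w) invokeRestart("muffleWarning"))
    list(
      ts = threshold_set(ax$thr_ssc, ax$thr_fcer1a, as.numeric(thr63), as.numeric(thr32),
                         calibrated_on = unstim$meta$sample_id),
      diagnostics = c(ax, list(
        cd63_realized_pct = attr(thr63, "realized_pos_pct"),
        cd32_realized_pct = attr(thr32, "realized_pos_pct"))))
  }, binbat_error = function(e) e)

  if (inherits(calib, "error")) {
    n_samp <- length(prepped)
    srs <- lapply(prepped, function(p) list(
      meta = p$meta, n_gated = n_events(p$events), n_basophils = NA_integer_,
      cd63_pos_pct = NA_real_, cd32_pos_pct = NA_real_,
      qc_flags = list(qc_flag("CALIBRATION_FAILED", "BLOCKING", conditionMessage(calib)))))
    return(new_experiment_result(donor_id, NULL, NULL, srs, "UNDETERMINED",
                                 undetermined_calls(prepped), cfg))
  }

  ts <- calib$ts
  srs <- lapply(prepped, function(p) {
    sr <- apply_thresholds(p$events, cfg$map, ts)
    sr$meta <- p$meta
    sr$retention <- attr(p$events, "retention")
    sr$qc_flags <- evaluate_qc(sr, p$events, ts, cfg)
    sr
  })

  unstim_sr <- srs[[which(conds == "UNSTIM")]]
  pos_idx <- which(conds == "POS_CTRL")
  responder_status <- "UNDETERMINED"
  if (length(pos_idx) >= 1L) {
    pos_sr <- srs[[pos_idx[1]]]
    if (!has_blocking(pos_sr$qc_flags) && !is.na(pos_sr$cd63_pos_pct))
      responder_status <- if (pos_sr$cd63_pos_pct >= cfg$responder_cutoff_pct)
        "RESPONDER" else "NON_RESPONDER"
  }

  allergen_calls <- list()
  for (i in which(conds == "ALLERGEN")) {
    sr <- srs[[i]]
    name <- sr$meta$allergen_name
    call <- if (responder_status != "RESPONDER" ||
                has_blocking(sr$qc_flags) || has_blocking(unstim_sr$qc_flags) ||
                is.na(sr$cd63_pos_pct) || is.na(unstim_sr$cd63_pos_pct)) {
      "UNDETERMINED"
    } else if (sr$cd63_pos_pct >= cfg$activation_cutoff_pct &&
               sr$cd63_pos_pct >= cfg$activation_fold * unstim_sr$cd63_pos_pct) {
      "POSITIVE"
    } else "NEGATIVE"
    allergen_calls[[name]] <- call
  }

  new_experiment_result(donor_id, ts, calib$diagnostics, srs, responder_status,
                        allergen_calls, cfg)
}

undetermined_calls <- function(prepped) {
  out <- list()
  for (p in prepped)
    if (p$meta$condition == "ALLERGEN") out[[p$meta$allergen_name]] <- "UNDETERMINED"
  out
}

new_experiment_result <- function(donor_id, ts, diagnostics, srs, responder_status,
                                  allergen_calls, cfg) {
  structure(list(
    donor_id = donor_id,
    thresholds = ts,
    calibration = diagnostics,
    samples = srs,
    responder_status = responder_status,
    allergen_calls = allergen_calls,
    call_rules = list(
      responder = sprintf("POS_CTRL CD63+%% >= %g", cfg$responder_cutoff_pct),
      allergen = sprintf("CD63+%% >= %g AND >= %g x UNSTIM CD63+%%",
                         cfg$activation_cutoff_pct, cfg$activation_fold)),
    config = config_to_list(cfg)
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> donor %s: %s\n", x$donor_id, x$responder_status))
  for (sr in x$samples)
    cat(sprintf("  %-28s n_gated=%6s n_baso=%5s CD63+%%=%s CD32+%%=%s %s\n",
                sr$meta$sample_id, sr$n_gated, sr$n_basophils,
                ifelse(is.na(sr$cd63_pos_pct), "NA", sprintf("%.2f", sr$cd63_pos_pct)),
                ifelse(is.na(sr$cd32_pos_pct), "NA", sprintf("%.2f", sr$cd32_pos_pct)),
                paste(vapply(sr$qc_flags, function(f) f$code, character(1)), collapse = ",")))
  for (a in names(x$allergen_calls))
    cat(sprintf("  allergen %s: %s\n", a, x$allergen_calls[[a]]))
  invisible(x)
}
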