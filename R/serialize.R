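# Result serialization. JSON writing is deterministic (fixed digits,
# fixed key order) so identical inputs yield byte-identical files.

result_to_list <- function(result) {
  list(
    donor_id = result$donor_id,
    thresholds = if (is.null(result$thresholds)) NULL else unclass(result$thresholds),
    calibration = result$calibration,
    samples = lapply(result$samples, function(sr) list(
      meta = unclass(sr$meta),
      n_gated = sr$n_gated,
      n_basophils = sr$n_basophils,
      cd63_pos_pct = sr$cd63_pos_pct,
      cd32_pos_pct = sr$cd32_pos_pct,
      retention = sr$retention %||% NULL,
      qc_flags = sr$qc_flags)),
    responder_status = result$responder_status,
    allergen_calls = result$allergen_calls,
    call_rules = result$call_rules,
    config = result$config)
}

result_to_json <- function(result) {
  jsonlite::toJSON(result_to_list(result), auto_unbox = TRUE, digits = I(10),
                   null = "null", na = "null", pretty = TRUE)
}

result_from_list <- function(lst) {
  ts <- if (!is.null(lst$thresholds))
    do.call(threshold_set, lst$thresholds[c("thr_ssc", "thr_fcer1a", "thr_cd63",
                                            "thr_cd32", "calibrated_on", "target_quadrant")])
  samples <- lapply(lst$samples, function(s) {
    meta <- sample_meta(s$meta$donor_id, s$meta$condition,
                        allergen_name = s$meta$allergen_name,
                        instrument = s$meta$instrument,
                        sample_id = s$meta$sample_id)
    list(meta = meta,
         n_gated = as.integer(s$n_gated),
         n_basophils = if (is.null(s$n_basophils)) NA_integer_ else as.integer(s$n_basophils),
         cd63_pos_pct = if (is.null(s$cd63_pos_pct)) NA_real_ else as.numeric(s$cd63_pos_pct),
         cd32_pos_pct = if (is.null(s$cd32_pos_pct)) NA_real_ else as.numeric(s$cd32_pos_pct),
         retention = s$retention,
         qc_flags = lapply(s$qc_flags, function(f) qc_flag(f$code, f$severity, f$message)))
  })
  structure(list(
    donor_id = lst$donor_id,
    thresholds = ts,
    calibration = lst$calibration,
    samples = samples,
    responder_status = lst$responder_status,
    allergen_calls = lst$allergen_calls,
    call_rules = lst$call_rules,
    config = lst$config
  ), class = "experiment_result")
}
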