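#' Load cytometry events from an FCS 3.0/3.1 file
#'
#' Reads list-mode FCS data into an [event_table]. All channels are kept;
#' `transformed` flags start out `FALSE`; the FCS TEXT keywords are
#' preserved in `$meta$fcs_keywords`. Spillover compensation is never
#' applied — inputs are assumed compensated upstream.
#'
#' @param path path to an FCS 3.0/3.1 file.
#' @param map optional [channel_map]; if given, every mapped marker must
#'   resolve to a channel present in the file.
#' @return an `event_table`.
#' @export
load_fcs <- function(path, map = NULL) {
  if (!file.exists(path)) stop_binbat("binbat_io_error", sprintf("file not found: %s", path))
  parsed <- read_fcs_raw(path)
  t <- event_table(parsed$values, colnames(parsed$values), transformed = FALSE,
                   meta = list(fcs_keywords = parsed$keywords, source = path))
  if (!is.null(map)) validate_channel_map(t, map)
  t
}

#' Load cytometry events from a CSV event table
#'
#' Expects a header row of unique channel names and a numeric body (one
#' row per event). An empty body yields a zero-event table (downstream
#' operations reject it where it matters).
#'
#' @param path path to a CSV file.
#' @param map optional [channel_map], validated against the header.
#' @return an `event_table`.
#' @export
load_csv <- function(path, map = NULL) {
  if (!file.exists(path)) stop_binbat("binbat_io_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  if (anyDuplicated(names(df)))
    stop_binbat("binbat_parse_error", sprintf(
      "duplicate channel name(s) in header of %s", path))
  if (nrow(df) == 0L) {
    mat <- matrix(numeric(0), nrow = 0, ncol = ncol(df), dimnames = list(NULL, names(df)))
    t <- event_table(mat, names(df), transformed = FALSE, meta = list(source = path))
    if (!is.null(map)) validate_channel_map(t, map)
    return(t)
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop_binbat("binbat_parse_error", sprintf(
        "non-numeric value in column '%s', data row %d of %s", names(df)[j], bad, path))
    }
  }
  t <- event_table(as.matrix(df), names(df), transformed = FALSE,
                   meta = list(source = path))
  if (!is.null(map)) validate_channel_map(t, map)
  t
}

#' Write an event table to CSV
#'
#' @param t an `event_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_events <- function(t, path) {
  utils::write.csv(as.data.frame(t$values, check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}

#' Write experiment results to disk
#'
#' Emits one machine-readable JSON document and one per-sample CSV table
#' per experiment (basophil counts, CD63+%, CD32+%, thresholds, QC
#' flags), plus a line in an append-only experiment index CSV. Files
#' round-trip via [read_results()].
#'
#' @param result an `experiment_result` from [analyze_experiment()].
#' @param out_dir output directory (created if missing).
#' @return named list of written paths, invisibly.
#' @export
write_results <- function(result, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop_binbat("binbat_io_error", sprintf("cannot write to directory: %s", out_dir))
  stem <- file.path(out_dir, paste0("experiment_", result$donor_id))
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, ".csv")
  writeLines(result_to_json(result), json_path)
  utils::write.csv(result_to_table(result), csv_path, row.names = FALSE)
  index_path <- file.path(out_dir, "experiment_index.csv")
  idx_row <- data.frame(
    donor_id = result$donor_id,
    n_samples = length(result$samples),
    responder_status = result$responder_status,
    json_file = basename(json_path),
    stringsAsFactors = FALSE)
  utils::write.table(idx_row, index_path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(index_path), append = file.exists(index_path))
  invisible(list(json = json_path, csv = csv_path, index = index_path))
}

#' Re-read a written experiment result
#'
#' @param json_path path to an `experiment_*.json` written by [write_results()].
#' @return an `experiment_result`.
#' @export
read_results <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  result_from_list(obj)
}

# Per-sample tabular summary (one row per sample).
result_to_table <- function(result) {
  rows <- lapply(result$samples, function(sr) {
    data.frame(
      donor_id = sr$meta$donor_id,
      sample_id = sr$meta$sample_id,
      condition = sr$meta$condition,
      allergen = sr$meta$allergen_name %||% "",
      n_gated = sr$n_gated,
      n_basophils = sr$n_basophils,
      cd63_pos_pct = sr$cd63_pos_pct,
      cd32_pos_pct = sr$cd32_pos_pct,
      thr_ssc = result$thresholds$thr_ssc,
      thr_fcer1a = result$thresholds$thr_fcer1a,
      thr_cd63 = result$thresholds$thr_cd63,
      thr_cd32 = result$thresholds$thr_cd32,
      qc_flags = paste(vapply(sr$qc_flags, function(f) f$code, character(1)), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
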