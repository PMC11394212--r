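# Config serialization: bat_config <-> plain lists <-> YAML/JSON files.

config_to_list <- function(cfg) {
  list(
    map = as.list(unclass(cfg$map)),
    transform = list(methods = as.list(cfg$transform$methods),
                     cofactors = as.list(cfg$transform$cofactors)),
    pregate = unclass(cfg$pregate),
    calibration = unclass(cfg$calibration),
    responder_cutoff_pct = cfg$responder_cutoff_pct,
    activation_cutoff_pct = cfg$activation_cutoff_pct,
    activation_fold = cfg$activation_fold,
    qc_min_gated = cfg$qc_min_gated,
    qc_min_baso_warn = cfg$qc_min_baso_warn,
    qc_min_baso_block = cfg$qc_min_baso_block,
    bin_width = cfg$bin_width,
    min_cells_per_bin = cfg$min_cells_per_bin,
    seed = cfg$seed)
}

config_from_list <- function(lst) {
  map <- channel_map(map = lst$map)
  tr <- if (!is.null(lst$transform)) {
    cof <- unlist(lst$transform$cofactors)
    transform_spec(unlist(lst$transform$methods), cof[!is.na(cof)])
  } else default_transform_spec(map)
  pg <- do.call(pregate_config, lapply(lst$pregate %||% list(), identity))
  cb <- do.call(calibration_config,
                lapply((lst$calibration %||% list()), unlist))
  bat_config(
    map = map, transform = tr, pregate = pg, calibration = cb,
    responder_cutoff_pct = lst$responder_cutoff_pct %||% 10,
    activation_cutoff_pct = lst$activation_cutoff_pct %||% 5,
    activation_fold = lst$activation_fold %||% 2,
    qc_min_gated = lst$qc_min_gated %||% 5000,
    qc_min_baso_warn = lst$qc_min_baso_warn %||% 50,
    qc_min_baso_block = lst$qc_min_baso_block %||% 10,
    bin_width = lst$bin_width %||% 0.2,
    min_cells_per_bin = lst$min_cells_per_bin %||% 10L,
    seed = lst$seed %||% 1L)
}

#' Load a run configuration from a YAML or JSON file
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file. Must at
#'   least provide `map` (logical marker -> channel name); all other
#'   sections fall back to package defaults.
#' @return a `bat_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_binbat("binbat_io_error", sprintf("config not found: %s", path))
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tryCatch(config_from_list(lst), error = function(e)
    stop_binbat("binbat_config_error", sprintf("invalid config %s: %s", path, conditionMessage(e))))
}

#' Write a run configuration to YAML
#'
#' @param cfg a [bat_config()].
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(config_to_list(cfg), digits.d = 12)), collapse = "\n")
  # small deterministic polynomial rolling hash (no digest dependency)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 4294967291
  sprintf("%08x", h)
}
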