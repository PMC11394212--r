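#' Event tables, channel maps and sample metadata
#'
#' An `event_table` is the package's universal currency: an events x
#' channels numeric matrix of non-negative raw (or transformed)
#' intensities, with unique channel names and a per-channel `transformed`
#' flag. A `channel_map` assigns the logical markers the analysis needs
#' (FSC_A, FSC_H, SSC, FCER1A, CD63, CD32, optionally CD123, HLA_DR,
#' CCR3, CRTH2) to physical channel names.
#'
#' @name event_table
NULL

REQUIRED_MARKERS <- c("FSC_A", "FSC_H", "SSC", "FCER1A", "CD63", "CD32")
OPTIONAL_MARKERS <- c("CD123", "HLA_DR", "CCR3", "CRTH2")

#' Construct an event table
#'
#' @param values numeric matrix (events x channels), all finite.
#' @param channel_names character vector of unique channel names; defaults
#'   to `colnames(values)`.
#' @param transformed logical vector (length 1 or one per channel): has the
#'   channel already been mapped to the analysis scale?
#' @param meta optional named list of side information (e.g. FCS keywords).
#' @return an object of class `event_table`.
#' @export
event_table <- function(values, channel_names = colnames(values),
                        transformed = FALSE, meta = list()) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(channel_names)) stop_binbat("binbat_parse_error", "channel names required")
  channel_names <- as.character(channel_names)
  if (ncol(values) != length(channel_names))
    stop_binbat("binbat_parse_error", "number of columns must equal number of channel names")
  if (anyDuplicated(channel_names))
    stop_binbat("binbat_parse_error", sprintf(
      "duplicate channel name(s): %s",
      paste(unique(channel_names[duplicated(channel_names)]), collapse = ", ")))
  if (nrow(values) > 0 && any(!is.finite(values)))
    stop_binbat("binbat_parse_error", "event values must all be finite")
  if (length(transformed) == 1L) transformed <- rep(transformed, length(channel_names))
  if (length(transformed) != length(channel_names))
    stop_binbat("binbat_parse_error", "transformed flags must match channels")
  colnames(values) <- channel_names
  structure(list(
    values = values,
    channel_names = channel_names,
    transformed = stats::setNames(as.logical(transformed), channel_names),
    meta = meta
  ), class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events x %d channels\n", n_events(x), length(x$channel_names)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat("  transformed:", paste(x$channel_names[x$transformed], collapse = ", ") , "\n")
  invisible(x)
}

#' Number of events in an event table
#' @param t an `event_table`.
#' @return integer event count.
#' @export
n_events <- function(t) nrow(t$values)

#' Construct a channel map
#'
#' @param ... or `map`: named channel assignments, e.g.
#'   `channel_map(FSC_A = "FSC-A", SSC = "SSC-A", ...)`.
#' @param map optional named character vector / list used instead of `...`.
#' @return an object of class `channel_map` (named character vector).
#' @export
channel_map <- function(..., map = NULL) {
  m <- if (is.null(map)) c(...) else unlist(map)
  m <- stats::setNames(as.character(m), names(m))
  unknown <- setdiff(names(m), c(REQUIRED_MARKERS, OPTIONAL_MARKERS))
  if (length(unknown))
    stop_binbat("binbat_channel_error", sprintf("unknown logical marker(s): %s", paste(unknown, collapse = ", ")))
  structure(m, class = "channel_map")
}

#' Resolve a logical marker to its event-table column
#'
#' @param t an `event_table`.
#' @param marker logical marker name (e.g. `"FCER1A"`).
#' @param map a `channel_map`.
#' @return numeric vector of that channel's values.
#' @export
marker_values <- function(t, marker, map) {
  ch <- resolve_channel(t, marker, map)
  t$values[, ch]
}

resolve_channel <- function(t, marker, map) {
  if (!marker %in% names(map))
    stop_binbat("binbat_channel_error", sprintf("marker %s not present in channel map", marker))
  ch <- unname(map[[marker]])
  if (!ch %in% t$channel_names)
    stop_binbat("binbat_channel_error", sprintf(
      "marker %s maps to channel '%s' which is absent from the event table", marker, ch))
  ch
}

# Check that a map's channels all exist and (optionally) that all
# required markers are present. Called on load and before the workflow.
validate_channel_map <- function(t, map, require_all = FALSE) {
  if (require_all) {
    missing <- setdiff(REQUIRED_MARKERS, names(map))
    if (length(missing))
      stop_binbat("binbat_channel_error", sprintf(
        "required marker(s) missing from channel map: %s", paste(missing, collapse = ", ")))
  }
  for (m in names(map)) resolve_channel(t, m, map)
  invisible(TRUE)
}

#' Sample metadata
#'
#' @param donor_id donor identifier string.
#' @param condition one of `"UNSTIM"`, `"POS_CTRL"`, `"ALLERGEN"`.
#' @param allergen_name required iff `condition == "ALLERGEN"`.
#' @param instrument optional instrument string.
#' @param sample_id optional sample identifier (defaults to donor/condition).
#' @return an object of class `sample_meta`.
#' @export
sample_meta <- function(donor_id, condition, allergen_name = NULL,
                        instrument = NULL, sample_id = NULL) {
  condition <- match.arg(condition, c("UNSTIM", "POS_CTRL", "ALLERGEN"))
  if (condition == "ALLERGEN" && is.null(allergen_name))
    stop_binbat("binbat_config_error", "allergen_name required for ALLERGEN condition")
  if (condition != "ALLERGEN" && !is.null(allergen_name))
    stop_binbat("binbat_config_error", "allergen_name only allowed for ALLERGEN condition")
  structure(list(
    donor_id = as.character(donor_id),
    condition = condition,
    allergen_name = allergen_name,
    instrument = instrument,
    sample_id = sample_id %||% paste(donor_id, condition, allergen_name %||% "", sep = "_")
  ), class = "sample_meta")
}

#' Row-subset an event table
#'
#' Keeps channel names, transform flags and metadata.
#'
#' @param t an `event_table`.
#' @param keep logical or integer row index.
#' @return the filtered `event_table`.
#' @export
subset_events <- function(t, keep) {
  event_table(t$values[keep, , drop = FALSE], t$channel_names, t$transformed, t$meta)
}
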