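#' Transform specifications
#'
#' Fluorescence (and mass) intensities are mapped to a quasi-logarithmic
#' scale before binning and threshold placement: `asinh(x / cofactor)`.
#' Scatter channels used for singlet gating (FSC-A vs FSC-H) stay linear.
#'
#' @param methods named character vector, channel name -> `"ASINH"` or
#'   `"IDENTITY"`.
#' @param cofactors named numeric vector of positive cofactors for the
#'   ASINH channels (ignored for IDENTITY).
#' @return an object of class `transform_spec`.
#' @export
transform_spec <- function(methods, cofactors = NULL) {
  methods <- toupper(methods)
  if (!all(methods %in% c("ASINH", "IDENTITY")))
    stop_binbat("binbat_config_error", "transform method must be ASINH or IDENTITY")
  asinh_ch <- names(methods)[methods == "ASINH"]
  cf <- stats::setNames(rep(NA_real_, length(methods)), names(methods))
  if (!is.null(cofactors)) cf[names(cofactors)] <- cofactors
  if (any(!is.finite(cf[asinh_ch]) | cf[asinh_ch] <= 0))
    stop_binbat("binbat_config_error", "every ASINH channel needs a cofactor > 0")
  structure(list(methods = methods, cofactors = cf), class = "transform_spec")
}

#' Default transform spec for a channel map
#'
#' Fluorescence markers get `asinh(x / 150)` (the community convention
#' for conventional flow; use cofactor 5 for mass-cytometry data). SSC
#' is also arcsinh-transformed by default because it serves as the
#' x-axis of the basophil bin plot and shares the grid's bin width;
#' FSC-A/FSC-H stay linear for singlet gating. All overridable.
#'
#' @param map a [channel_map].
#' @param fluor_cofactor cofactor for fluorescence markers (default 150).
#' @param ssc_cofactor cofactor for SSC (default 150); set `NA` to keep
#'   SSC linear.
#' @return a `transform_spec` over the mapped channels.
#' @export
default_transform_spec <- function(map, fluor_cofactor = 150, ssc_cofactor = 150) {
  fluor <- intersect(names(map), c("FCER1A", "CD63", "CD32", OPTIONAL_MARKERS))
  methods <- c(); cof <- c()
  for (m in names(map)) {
    ch <- unname(map[[m]])
    if (m %in% fluor) { methods[ch] <- "ASINH"; cof[ch] <- fluor_cofactor }
    else if (m == "SSC" && !is.na(ssc_cofactor)) { methods[ch] <- "ASINH"; cof[ch] <- ssc_cofactor }
    else methods[ch] <- "IDENTITY"
  }
  transform_spec(methods, cof)
}

#' Apply a transform to an event table
#'
#' ASINH channels become `asinh(x / cofactor)`; IDENTITY channels are
#' unchanged but marked transformed. Re-transforming an already
#' transformed channel is an error (the operation is idempotent-guarded).
#'
#' @param t an `event_table`.
#' @param spec a `transform_spec` covering channels of `t`.
#' @return the transformed `event_table`.
#' @export
apply_transform <- function(t, spec) {
  chans <- intersect(names(spec$methods), t$channel_names)
  if (any(t$transformed[chans]))
    stop_binbat("binbat_state_error", sprintf(
      "channel(s) already transformed: %s", paste(chans[t$transformed[chans]], collapse = ", ")))
  vals <- t$values
  for (ch in chans) {
    if (spec$methods[[ch]] == "ASINH") vals[, ch] <- asinh(vals[, ch] / spec$cofactors[[ch]])
  }
  tr <- t$transformed
  tr[chans] <- TRUE
  event_table(vals, t$channel_names, tr, t$meta)
}
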