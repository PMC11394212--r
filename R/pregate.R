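#' Pregating configuration
#'
#' Controls singlet gating and debris/thrombocyte removal. Scatter
#' floors default to fractions of the sample's median FSC-A so that one
#' convention covers both synthetic and real acquisitions; absolute
#' cutoffs (linear FSC-A units) may be given instead.
#'
#' @param singlet_band_k residual band half-width in robust MADs
#'   (default 4).
#' @param fsc_debris_min absolute debris cutoff, or `NULL` to use
#'   `debris_frac_of_median * median(FSC_A)`.
#' @param fsc_thrombocyte_min absolute thrombocyte cutoff, or `NULL` to
#'   use `thrombo_frac_of_median * median(FSC_A)`.
#' @param debris_frac_of_median,thrombo_frac_of_median relative floors
#'   (defaults 0.30 and 0.45).
#' @param eosinophil_exclusion reserved switch for scatter-based
#'   eosinophil out-gating used in manual analysis; default `FALSE` in
#'   the automated workflow.
#' @param subsample_size events used for the robust singlet line fit
#'   (default 201).
#' @param seed seed for the fit subsample (default 1).
#' @return a `pregate_config`.
#' @export
pregate_config <- function(singlet_band_k = 4, fsc_debris_min = NULL,
                           fsc_thrombocyte_min = NULL,
                           debris_frac_of_median = 0.30,
                           thrombo_frac_of_median = 0.45,
                           eosinophil_exclusion = FALSE,
                           subsample_size = 201L, seed = 1L) {
  if (singlet_band_k <= 0) stop_binbat("binbat_config_error", "singlet_band_k must be > 0")
  if (!is.null(fsc_debris_min) && !is.null(fsc_thrombocyte_min) &&
      fsc_debris_min > fsc_thrombocyte_min)
    stop_binbat("binbat_config_error", "fsc_debris_min must be <= fsc_thrombocyte_min")
  structure(list(
    singlet_band_k = singlet_band_k,
    fsc_debris_min = fsc_debris_min,
    fsc_thrombocyte_min = fsc_thrombocyte_min,
    debris_frac_of_median = debris_frac_of_median,
    thrombo_frac_of_median = thrombo_frac_of_median,
    eosinophil_exclusion = eosinophil_exclusion,
    subsample_size = as.integer(subsample_size),
    seed = as.integer(seed)
  ), class = "pregate_config")
}

# Theil-Sen slope over a fixed-size subsample drawn after a canonical
# sort, so the retained event set is invariant to input row order.
theil_sen <- function(x, y, m = 201L, seed = 1L) {
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  if (n > m) {
    old <- .Random.seed_exists()
    set.seed(seed)
    idx <- sort(sample.int(n, m))
    .restore_seed(old)
    x <- x[idx]; y <- y[idx]
  }
  k <- length(x)
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  slope <- stats::median(dy[keep] / dx[keep])
  intercept <- stats::median(y - slope * x)
  c(slope = slope, intercept = intercept)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Singlet gate: remove doublets by FSC-A vs FSC-H linearity
#'
#' Fits a robust line FSC-H ~ FSC-A (Theil–Sen over a seeded fixed-size
#' subsample drawn after a canonical sort) and keeps events whose
#' residual magnitude is at most `singlet_band_k` times the MAD of the
#' residuals. Doublets (roughly doubled FSC-A at unchanged FSC-H) fall
#' far below the line and are removed.
#'
#' @param t an `event_table` with FSC_A and FSC_H mapped.
#' @param map a [channel_map].
#' @param cfg a [pregate_config()].
#' @return filtered `event_table`; attribute `"retention"` holds the
#'   retained fraction.
#' @export
gate_singlets <- function(t, map, cfg = pregate_config()) {
  if (n_events(t) < 50)
    stop_binbat("binbat_insufficient_events",
                sprintf("singlet gating needs >= 50 events, got %d", n_events(t)))
  a <- marker_values(t, "FSC_A", map)
  h <- marker_values(t, "FSC_H", map)
  fit <- theil_sen(a, h, m = cfg$subsample_size, seed = cfg$seed)
  resid <- h - (fit["intercept"] + fit["slope"] * a)
  s <- stats::mad(resid)
  keep <- if (s == 0) rep(TRUE, length(resid)) else abs(resid) <= cfg$singlet_band_k * s
  out <- subset_events(t, keep)
  attr(out, "retention") <- mean(keep)
  out
}

#' Remove debris and thrombocytes by forward-scatter floors
#'
#' Events with FSC-A below the debris floor are removed; events with
#' FSC-A below the thrombocyte floor AND SSC below the SSC median of
#' the floor-passing events are removed (small-and-low rule).
#' Deterministic, pure filter.
#'
#' @param t an `event_table` with FSC_A (and SSC) mapped.
#' @param map a [channel_map].
#' @param cfg a [pregate_config()].
#' @return filtered `event_table`; attribute `"retention"` as in
#'   [gate_singlets()].
#' @export
exclude_debris_thrombocytes <- function(t, map, cfg = pregate_config()) {
  a <- marker_values(t, "FSC_A", map)
  med_a <- stats::median(a)
  debris_min <- cfg$fsc_debris_min %||% (cfg$debris_frac_of_median * med_a)
  thrombo_min <- cfg$fsc_thrombocyte_min %||% (cfg$thrombo_frac_of_median * med_a)
  keep <- a >= debris_min
  if ("SSC" %in% names(map)) {
    ssc <- marker_values(t, "SSC", map)
    ssc_med <- stats::median(ssc[keep])
    keep <- keep & !(a < thrombo_min & ssc < ssc_med)
  }
  if (!any(keep))
    stop_binbat("binbat_empty_sample", "all events removed by debris/thrombocyte exclusion")
  out <- subset_events(t, keep)
  attr(out, "retention") <- mean(keep)
  out
}

#' Full pregate: singlets then debris/thrombocyte exclusion
#'
#' @inheritParams gate_singlets
#' @return filtered `event_table` with `"retention"` attribute (overall
#'   retained fraction).
#' @export
pregate <- function(t, map, cfg = pregate_config()) {
  n0 <- n_events(t)
  t1 <- gate_singlets(t, map, cfg)
  t2 <- exclude_debris_thrombocytes(t1, map, cfg)
  attr(t2, "retention") <- n_events(t2) / n0
  t2
}
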