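#' Bin grid for pattern-recognition (PRI) bin plots
#'
#' Partitions the transformed x/y marker plane into square bins of width
#' `bin_width` anchored at `origin`, with half-open intervals
#' `[low, high)`. Quadrant thresholds are snapped to the nearest grid
#' line so bin and quadrant boundaries coincide.
#'
#' @param x_marker,y_marker logical marker names (e.g. `"SSC"`,
#'   `"FCER1A"`).
#' @param bin_width bin side length in transformed units (default 0.2).
#' @param x_threshold,y_threshold quadrant thresholds in transformed
#'   units (snapped to grid lines).
#' @param origin grid anchor, default `c(0, 0)`.
#' @return a `bin_grid`.
#' @export
bin_grid <- function(x_marker, y_marker, bin_width = 0.2,
                     x_threshold = 0, y_threshold = 0, origin = c(0, 0)) {
  if (bin_width <= 0) stop_binbat("binbat_config_error", "bin_width must be > 0")
  snap <- function(thr, o) o + round((thr - o) / bin_width) * bin_width
  structure(list(
    x_marker = x_marker, y_marker = y_marker, bin_width = bin_width,
    x_threshold = snap(x_threshold, origin[1]),
    y_threshold = snap(y_threshold, origin[2]),
    origin = origin
  ), class = "bin_grid")
}

#' Assign events to bins
#'
#' Bin index per axis is `floor((value - origin) / bin_width)`; the
#' half-open convention means an event exactly on a bin's lower edge
#' belongs to that bin. Every event is assigned exactly once.
#'
#' @param t a transformed `event_table`.
#' @param g a [bin_grid()].
#' @param map a [channel_map].
#' @return data.frame with integer columns `ix`, `iy` (one row per event).
#' @export
assign_bins <- function(t, g, map) {
  for (m in c(g$x_marker, g$y_marker)) {
    ch <- resolve_channel(t, m, map)
    if (!t$transformed[[ch]])
      stop_binbat("binbat_state_error", sprintf("marker %s is not transformed", m))
  }
  x <- marker_values(t, g$x_marker, map)
  y <- marker_values(t, g$y_marker, map)
  data.frame(
    ix = as.integer(floor((x - g$origin[1]) / g$bin_width + 1e-9)),
    iy = as.integer(floor((y - g$origin[2]) / g$bin_width + 1e-9)))
}

#' Per-bin statistics with a third (z) marker
#'
#' For every occupied bin: event count, density (fraction of all gated
#' events), frequency of z-positive cells (strictly above `z_threshold`,
#' in percent), mean z signal intensity of all bin events (MSI) and of
#' only the z-positive events (MSI+, `NA` when the bin has none). Bins
#' with fewer than `min_cells_per_bin` events keep their counts but are
#' flagged `below_cutoff` and excluded from color scaling.
#'
#' @param t a transformed `event_table` (gated events).
#' @param g a [bin_grid()].
#' @param map a [channel_map].
#' @param z_marker logical marker used as z.
#' @param z_threshold positivity threshold on the transformed z scale.
#' @param min_cells_per_bin minimum events for a bin to be colored
#'   (default 10).
#' @return a `bin_stats` data.frame: `ix, iy, n_events, density,
#'   freq_zpos, msi_all, msi_pos, below_cutoff`.
#' @export
bin_statistics <- function(t, g, map, z_marker, z_threshold, min_cells_per_bin = 10L) {
  if (n_events(t) == 0L) stop_binbat("binbat_empty_sample", "no gated events to bin")
  if (min_cells_per_bin < 1L) stop_binbat("binbat_config_error", "min_cells_per_bin must be >= 1")
  zch <- resolve_channel(t, z_marker, map)
  if (!t$transformed[[zch]])
    stop_binbat("binbat_state_error", sprintf("marker %s is not transformed", z_marker))
  idx <- assign_bins(t, g, map)
  z <- t$values[, zch]
  key <- paste(idx$ix, idx$iy, sep = ":")
  split_z <- split(z, key)
  coords <- do.call(rbind, strsplit(names(split_z), ":", fixed = TRUE))
  n <- vapply(split_z, length, integer(1))
  pos_n <- vapply(split_z, function(v) sum(v > z_threshold), integer(1))
  msi_all <- vapply(split_z, mean, numeric(1))
  msi_pos <- vapply(split_z, function(v) {
    p <- v[v > z_threshold]
    if (length(p)) mean(p) else NA_real_
  }, numeric(1))
  out <- data.frame(
    ix = as.integer(coords[, 1]),
    iy = as.integer(coords[, 2]),
    n_events = n,
    density = n / n_events(t),
    freq_zpos = 100 * pos_n / n,
    msi_all = msi_all,
    msi_pos = msi_pos,
    below_cutoff = n < min_cells_per_bin,
    row.names = NULL)
  out <- out[order(out$ix, out$iy), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grid") <- g
  attr(out, "z_marker") <- z_marker
  attr(out, "z_threshold") <- z_threshold
  class(out) <- c("bin_stats", "data.frame")
  out
}

#' Quadrant statistics
#'
#' Quadrant membership from the grid's x/y thresholds: `x < x_threshold`
#' is "left", `y >= y_threshold` is "upper". Reports the percentage of
#' all gated events per quadrant (the black numbers of a bin plot) and,
#' within the target quadrant, the percentage of z-positive events (the
#' red percentage).
#'
#' @inheritParams bin_statistics
#' @param target_quadrant one of `"UL"`, `"UR"`, `"LL"`, `"LR"`
#'   (default `"UL"`, the basophil quadrant of SSC/FcERIa plots).
#' @return a `quadrant_stats` list: `q_freq` (named percentages),
#'   `target_quadrant`, `zpos_pct_target` (`NA` with a warning when the
#'   target quadrant is empty), `zpos_count`, `n_target`.
#' @export
quadrant_statistics <- function(t, g, map, z_marker, z_threshold, target_quadrant = "UL") {
  if (n_events(t) == 0L) stop_binbat("binbat_empty_sample", "no gated events")
  target_quadrant <- match.arg(target_quadrant, c("UL", "UR", "LL", "LR"))
  x <- marker_values(t, g$x_marker, map)
  y <- marker_values(t, g$y_marker, map)
  z <- marker_values(t, z_marker, map)
  left <- x < g$x_threshold
  upper <- y >= g$y_threshold
  quad <- ifelse(upper, ifelse(left, "UL", "UR"), ifelse(left, "LL", "LR"))
  n <- length(x)
  q_freq <- vapply(c(UL = "UL", UR = "UR", LL = "LL", LR = "LR"),
                   function(q) 100 * sum(quad == q) / n, numeric(1))
  in_target <- quad == target_quadrant
  n_target <- sum(in_target)
  if (n_target == 0L) {
    warn_binbat("binbat_empty_quadrant",
                sprintf("target quadrant %s contains no events", target_quadrant))
    zpos_pct <- NA_real_; zpos_count <- 0L
  } else {
    zpos_count <- sum(z[in_target] > z_threshold)
    zpos_pct <- 100 * zpos_count / n_target
  }
  structure(list(
    q_freq = q_freq, target_quadrant = target_quadrant,
    zpos_pct_target = zpos_pct, zpos_count = as.integer(zpos_count),
    n_target = as.integer(n_target)
  ), class = "quadrant_stats")
}

#' Per-sample min–max color scaling of a bin statistic
#'
#' Normalizes the chosen statistic over the non-flagged bins to `[0, 1]`
#' (blue = sample minimum, red = sample maximum; scaling is per sample,
#' not global). Bins below the cell cutoff get `NA` (rendered grey);
#' when all usable bins share one value the convention is 0.5
#' everywhere.
#'
#' @param stats a `bin_stats` table.
#' @param statistic one of `"DENSITY"`, `"FREQ"`, `"MSI"`, `"MSI_POS"`.
#' @return numeric vector of normalized color values (one per bin row);
#'   attributes `"range"` holds the min/max used.
#' @export
bin_color_scale <- function(stats, statistic = c("DENSITY", "FREQ", "MSI", "MSI_POS")) {
  statistic <- match.arg(statistic)
  col <- switch(statistic, DENSITY = stats$density, FREQ = stats$freq_zpos,
                MSI = stats$msi_all, MSI_POS = stats$msi_pos)
  usable <- !stats$below_cutoff & !is.na(col)
  if (!any(usable)) stop_binbat("binbat_empty_sample", "all bins below cell cutoff")
  lo <- min(col[usable]); hi <- max(col[usable])
  out <- rep(NA_real_, length(col))
  out[usable] <- if (hi > lo) (col[usable] - lo) / (hi - lo) else 0.5
  attr(out, "range") <- c(min = lo, max = hi)
  out
}
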