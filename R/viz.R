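#' Plot style for bin plots
#'
#' @param below_cutoff_color fill for bins under the cell cutoff.
#' @param quadrant_label_color color of the per-quadrant frequency
#'   labels (black by convention).
#' @param target_zpos_label_color color of the z-positive percentage in
#'   the target (basophil) quadrant (red by convention).
#' @param warning_glyphs named glyphs per QC severity.
#' @return a `plot_style`.
#' @export
plot_style <- function(below_cutoff_color = "#bbbbbb",
                       quadrant_label_color = "black",
                       target_zpos_label_color = "red",
                       warning_glyphs = c(WARNING = "!", BLOCKING = "!!")) {
  structure(list(below_cutoff_color = below_cutoff_color,
                 quadrant_label_color = quadrant_label_color,
                 target_zpos_label_color = target_zpos_label_color,
                 warning_glyphs = warning_glyphs), class = "plot_style")
}

# blue (minimum) -> red (maximum) ramp on [0, 1]
ramp_blue_red <- function(v) {
  r <- round(40 + v * (215 - 40))
  g <- round(60 + (1 - abs(2 * v - 1)) * 100)
  b <- round(215 - v * (215 - 40))
  sprintf("#%02x%02x%02x", r, g, b)
}

fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)

svg_open <- function(w, h) c(
  '<?xml version="1.0" encoding="UTF-8"?>',
  sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">', w, h, w, h))

svg_rect <- function(x, y, w, h, fill, stroke = "none") sprintf(
  '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s"/>',
  fmt(x), fmt(y), fmt(w), fmt(h), fill, stroke)

svg_line <- function(x1, y1, x2, y2, stroke, dash = NULL) sprintf(
  '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"%s/>',
  fmt(x1), fmt(y1), fmt(x2), fmt(y2), stroke,
  if (is.null(dash)) "" else sprintf(' stroke-dasharray="%s"', dash))

svg_text <- function(x, y, s, fill = "black", size = 12, anchor = "start") sprintf(
  '<text x="%s" y="%s" fill="%s" font-size="%d" font-family="sans-serif" text-anchor="%s">%s</text>',
  fmt(x), fmt(y), fill, size, anchor, s)

#' Render a PRI bin plot as SVG
#'
#' Heat-colored bins (per-sample blue-to-red min/max scaling from
#' [bin_color_scale()]), grey below-cutoff bins, threshold cross-hairs,
#' four black quadrant percentages, the red z-positive percentage in the
#' target quadrant, a min/max color legend and QC warning glyphs.
#' Output is plain SVG text and byte-deterministic for fixed inputs.
#'
#' @param stats a `bin_stats` table from [bin_statistics()].
#' @param quad a `quadrant_stats` from [quadrant_statistics()].
#' @param style a [plot_style()].
#' @param out output `.svg` path.
#' @param statistic which bin statistic to color (see
#'   [bin_color_scale()]).
#' @param qc_flags list of QC flags to display as glyphs.
#' @param title plot title.
#' @return `out`, invisibly.
#' @export
render_bin_plot <- function(stats, quad, style = plot_style(), out,
                            statistic = "FREQ", qc_flags = list(), title = "") {
  g <- attr(stats, "grid")
  colors <- bin_color_scale(stats, statistic)  # errors if all below cutoff
  rng <- attr(colors, "range")
  W <- 480L; H <- 480L; m <- 50L  # margin
  pw <- W - 2L * m; ph <- H - 2L * m
  ix0 <- min(stats$ix); ix1 <- max(stats$ix) + 1L
  iy0 <- min(stats$iy); iy1 <- max(stats$iy) + 1L
  sx <- pw / (ix1 - ix0); sy <- ph / (iy1 - iy0)
  px <- function(ix) m + (ix - ix0) * sx
  py <- function(iy) H - m - (iy - iy0 + 1) * sy  # y up
  lines <- svg_open(W, H)
  lines <- c(lines, svg_rect(0, 0, W, H, "white"))
  for (i in seq_len(nrow(stats))) {
    fill <- if (is.na(colors[i])) style$below_cutoff_color else ramp_blue_red(colors[i])
    lines <- c(lines, svg_rect(px(stats$ix[i]), py(stats$iy[i]), sx, sy, fill))
  }
  # threshold cross-hairs (thresholds are on grid lines, transformed units)
  tx <- m + (g$x_threshold / g$bin_width - ix0) * sx
  ty <- H - m - (g$y_threshold / g$bin_width - iy0) * sy
  lines <- c(lines,
             svg_line(tx, m, tx, H - m, "black"),
             svg_line(m, ty, W - m, ty, "black"))
  # quadrant frequencies, black, in the corners (2 decimals, as computed)
  ql <- style$quadrant_label_color
  lines <- c(lines,
             svg_text(m + 4, m + 16, fmt(quad$q_freq[["UL"]]), ql),
             svg_text(W - m - 4, m + 16, fmt(quad$q_freq[["UR"]]), ql, anchor = "end"),
             svg_text(m + 4, H - m - 6, fmt(quad$q_freq[["LL"]]), ql),
             svg_text(W - m - 4, H - m - 6, fmt(quad$q_freq[["LR"]]), ql, anchor = "end"))
  # red z-positive percentage in the target quadrant
  zlab <- if (is.na(quad$zpos_pct_target)) "n/a" else paste0(fmt(quad$zpos_pct_target), "%")
  tq <- quad$target_quadrant
  zx <- if (tq %in% c("UL", "LL")) m + 4 else W - m - 4
  zy <- if (tq %in% c("UL", "UR")) m + 32 else H - m - 22
  lines <- c(lines, svg_text(zx, zy, zlab, style$target_zpos_label_color,
                             anchor = if (tq %in% c("UL", "LL")) "start" else "end"))
  # per-sample min/max legend
  lines <- c(lines,
             svg_rect(m, H - m + 14, 60, 10, ramp_blue_red(0)),
             svg_rect(m + 60, H - m + 14, 60, 10, ramp_blue_red(1)),
             svg_text(m + 126, H - m + 23,
                      sprintf("%s: min %s / max %s", statistic, fmt(rng[["min"]], 4), fmt(rng[["max"]], 4)),
                      size = 10))
  # QC glyphs
  if (length(qc_flags)) {
    sev <- vapply(qc_flags, function(f) f$severity, character(1))
    glyphs <- paste(style$warning_glyphs[sev], collapse = " ")
    codes <- paste(vapply(qc_flags, function(f) f$code, character(1)), collapse = ", ")
    lines <- c(lines, svg_text(W - m - 4, 18, sprintf("%s %s", glyphs, codes),
                               "orange", size = 11, anchor = "end"))
  }
  if (nzchar(title)) lines <- c(lines, svg_text(m, 18, title, size = 13))
  lines <- c(lines,
             svg_text(W / 2, H - 8, attr(stats, "grid")$x_marker, size = 11, anchor = "middle"),
             svg_text(12, H / 2, attr(stats, "grid")$y_marker, size = 11, anchor = "middle"),
             "</svg>")
  writeLines(lines, out)
  invisible(out)
}

#' Symmetric tail trimming with nearest-rank bounds
#'
#' Keeps values within the nearest-rank `[trim_pct/2, 100 - trim_pct/2]`
#' percentile bounds (inclusive); with `trim_pct = 3` this removes the
#' most extreme ~1.5% on each side.
#'
#' @param x numeric vector.
#' @param trim_pct total percentage to trim (default 3).
#' @return the trimmed vector.
#' @export
trim_tails <- function(x, trim_pct = 3) {
  b <- nearest_rank_quantile(x, c(trim_pct / 200, 1 - trim_pct / 200))
  x[x >= b[1] & x <= b[2]]
}

#' Render violin summaries as SVG
#'
#' One violin per group with symmetric tail trimming (default 3%
#' removed in total), the median as a solid line and the 25%/75%
#' percentiles as dashed lines. Groups are drawn in the order given;
#' output is byte-deterministic.
#'
#' @param values_by_group named list of numeric vectors (>= 10 values
#'   each).
#' @param trim_pct total trim percentage (default 3).
#' @param out output `.svg` path.
#' @param title plot title.
#' @return `out`, invisibly.
#' @export
render_violin <- function(values_by_group, trim_pct = 3, out, title = "") {
  if (!length(values_by_group)) stop_binbat("binbat_empty_sample", "no groups to plot")
  for (gname in names(values_by_group))
    if (length(values_by_group[[gname]]) < 10)
      stop_binbat("binbat_insufficient_events",
                  sprintf("group %s has fewer than 10 values", gname))
  trimmed <- lapply(values_by_group, trim_tails, trim_pct = trim_pct)
  W <- 120L * length(trimmed) + 80L; H <- 420L; m <- 45L
  ylo <- min(unlist(trimmed)); yhi <- max(unlist(trimmed))
  if (yhi == ylo) { yhi <- ylo + 1; ylo <- ylo - 1 }
  py <- function(v) H - m - (v - ylo) / (yhi - ylo) * (H - 2 * m)
  lines <- c(svg_open(W, H), svg_rect(0, 0, W, H, "white"))
  for (k in seq_along(trimmed)) {
    v <- trimmed[[k]]
    cx <- 80 + (k - 1) * 120 + 20
    d <- stats::density(v, n = 64)
    half <- 45 * d$y / max(d$y)
    right <- sprintf("%s,%s", fmt(cx + half), fmt(py(d$x)))
    left <- sprintf("%s,%s", fmt(cx - rev(half)), fmt(py(rev(d$x))))
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="#9ecae1" stroke="#3182bd"/>',
      paste(c(right, left), collapse = " ")))
    q <- nearest_rank_quantile(v, c(0.25, 0.5, 0.75))
    lines <- c(lines,
               svg_line(cx - 40, py(q[2]), cx + 40, py(q[2]), "black"),
               svg_line(cx - 40, py(q[1]), cx + 40, py(q[1]), "black", dash = "4,3"),
               svg_line(cx - 40, py(q[3]), cx + 40, py(q[3]), "black", dash = "4,3"),
               svg_text(cx, H - m + 18, names(trimmed)[k], size = 11, anchor = "middle"))
  }
  lines <- c(lines,
             svg_text(10, py(ylo) + 4, fmt(ylo), size = 9),
             svg_text(10, py(yhi) + 4, fmt(yhi), size = 9))
  if (nzchar(title)) lines <- c(lines, svg_text(m, 20, title, size = 13))
  lines <- c(lines, "</svg>")
  writeLines(lines, out)
  invisible(out)
}
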