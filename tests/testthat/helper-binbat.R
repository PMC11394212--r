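# Shared fixtures and independent oracles for the test suite.

test_map <- function() default_channel_map()

# Pregate + transform one generated sample while carrying the truth
# labels through the row filter (via an extra index channel).
prep_with_truth <- function(sample, cfg = bat_config()) {
  ev <- sample$events
  m2 <- cbind(ev$values, ".row" = seq_len(nrow(ev$values)))
  t2 <- event_table(m2, colnames(m2))
  g <- pregate(t2, cfg$map, cfg$pregate)
  tt <- apply_transform(g, cfg$transform)
  idx <- as.integer(g$values[, ".row"])
  list(events = tt, truth = sample$truth[idx, , drop = FALSE])
}

# Naive per-event oracle for bin statistics: a plain accumulation loop,
# no vectorized grouping, used to cross-check bin_statistics exactly.
naive_bin_stats <- function(x, y, z, bin_width, origin, z_threshold, min_cells) {
  n <- length(x)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    ix <- as.integer(floor((x[i] - origin[1]) / bin_width + 1e-9))
    iy <- as.integer(floor((y[i] - origin[2]) / bin_width + 1e-9))
    key <- paste(ix, iy, sep = ":")
    cur <- if (!is.null(acc[[key]])) acc[[key]] else list(ix = ix, iy = iy, z = numeric(0))
    cur$z <- c(cur$z, z[i])
    acc[[key]] <- cur
  }
  rows <- lapply(ls(acc), function(k) {
    b <- acc[[k]]
    pos <- b$z[b$z > z_threshold]
    data.frame(ix = b$ix, iy = b$iy, n_events = length(b$z),
               density = length(b$z) / n,
               freq_zpos = 100 * length(pos) / length(b$z),
               msi_all = sum(b$z) / length(b$z),
               msi_pos = if (length(pos)) sum(pos) / length(pos) else NA_real_,
               below_cutoff = length(b$z) < min_cells)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ix, out$iy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive quadrant oracle (per-event if/else tally).
naive_quadrant_stats <- function(x, y, z, thr_x, thr_y, z_threshold, target) {
  counts <- c(UL = 0, UR = 0, LL = 0, LR = 0)
  n_target <- 0; n_pos <- 0
  for (i in seq_along(x)) {
    q <- if (y[i] >= thr_y) { if (x[i] < thr_x) "UL" else "UR"
         } else { if (x[i] < thr_x) "LL" else "LR" }
    counts[q] <- counts[q] + 1
    if (q == target) {
      n_target <- n_target + 1
      if (z[i] > z_threshold) n_pos <- n_pos + 1
    }
  }
  list(q_freq = 100 * counts / length(x),
       zpos_pct_target = if (n_target) 100 * n_pos / n_target else NA_real_)
}

# Independent Wilcoxon signed-rank enumeration: builds the exact null
# distribution of W+ by dynamic programming over ranks (a different
# route than the implementation's design-matrix enumeration).
oracle_wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- 2^length(r)
  # exact null distribution of W+ by convolution over doubled-integer
  # ranks (midranks may be half-integers)
  r2 <- as.integer(round(2 * r))
  counts <- integer(sum(r2) + 1)  # index = W*2 + 1
  counts[1] <- 1L
  for (ri in r2) {
    shifted <- c(integer(ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  w2 <- round(2 * w_obs)
  p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
  p_le <- sum(counts[1:(w2 + 1)]) / total
  min(1, 2 * min(p_ge, p_le))
}

# Small deterministic event table on the transformed scale.
toy_table <- function(x, y, z, transformed = TRUE) {
  event_table(cbind("X" = x, "Y" = y, "Z" = z), transformed = transformed)
}
toy_map <- function() channel_map(SSC = "X", FCER1A = "Y", CD63 = "Z")
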