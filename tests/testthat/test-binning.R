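test_that("bin assignment follows the half-open grid convention", {
  g <- bin_grid("SSC", "FCER1A", bin_width = 0.2)
  t <- toy_table(x = c(0, 0.2, 0.199999, 1.0), y = c(0, 0, 0.4, 0.6), z = 1:4)
  idx <- assign_bins(t, g, toy_map())
  expect_equal(idx$ix, c(0L, 1L, 0L, 5L))  # lower edge belongs to the bin
  expect_equal(idx$iy, c(0L, 0L, 2L, 3L))
  expect_error(assign_bins(toy_table(1, 1, 1, transformed = FALSE), g, toy_map()),
               class = "binbat_state_error")
})

test_that("all events land in exactly one bin", {
  set.seed(5)
  t <- toy_table(runif(1000, -2, 6), runif(1000, -2, 6), runif(1000))
  st <- bin_statistics(t, bin_grid("SSC", "FCER1A"), toy_map(), "CD63", 0.5, 10)
  expect_equal(sum(st$n_events), 1000L)
  expect_equal(sum(st$density), 1, tolerance = 1e-9)
})

test_that("bin statistics match hand-computed values", {
  t <- toy_table(x = rep(0.1, 3), y = rep(0.1, 3), z = c(1, 2, 3))
  g <- bin_grid("SSC", "FCER1A", bin_width = 0.2)
  st <- bin_statistics(t, g, toy_map(), "CD63", z_threshold = 2, min_cells_per_bin = 1)
  expect_equal(nrow(st), 1L)
  expect_equal(st$freq_zpos, 100 / 3, tolerance = 1e-9)
  expect_equal(st$msi_all, 2)
  expect_equal(st$msi_pos, 3)  # strictly above 2

  st_lo <- bin_statistics(t, g, toy_map(), "CD63", z_threshold = 0, min_cells_per_bin = 1)
  expect_equal(st_lo$freq_zpos, 100)
  expect_equal(st_lo$msi_pos, st_lo$msi_all)

  st_hi <- bin_statistics(t, g, toy_map(), "CD63", z_threshold = 10, min_cells_per_bin = 1)
  expect_equal(st_hi$freq_zpos, 0)
  expect_true(is.na(st_hi$msi_pos))  # absent, never zero
})

test_that("bin and quadrant statistics equal the naive per-event oracle", {
  set.seed(17)
  for (n in c(37, 500, 1000)) {
    x <- runif(n, -1, 5); y <- runif(n, -1, 5); z <- rnorm(n, 2, 1)
    t <- toy_table(x, y, z)
    g <- bin_grid("SSC", "FCER1A", bin_width = 0.2, x_threshold = 2, y_threshold = 1.6)
    st <- bin_statistics(t, g, toy_map(), "CD63", 2, 5)
    or <- naive_bin_stats(x, y, z, 0.2, c(0, 0), 2, 5)
    expect_identical(st$ix, or$ix)
    expect_identical(st$iy, or$iy)
    expect_identical(st$n_events, or$n_events)
    expect_equal(st$density, or$density, tolerance = 0)
    expect_equal(st$freq_zpos, or$freq_zpos, tolerance = 0)
    expect_equal(st$msi_all, or$msi_all, tolerance = 1e-12)
    expect_equal(st$msi_pos, or$msi_pos, tolerance = 1e-12)
    expect_identical(st$below_cutoff, or$below_cutoff)

    q <- quadrant_statistics(t, g, toy_map(), "CD63", 2, "UL")
    oq <- naive_quadrant_stats(x, y, z, g$x_threshold, g$y_threshold, 2, "UL")
    expect_equal(unname(q$q_freq), unname(oq$q_freq), tolerance = 0)
    expect_equal(q$zpos_pct_target, oq$zpos_pct_target, tolerance = 0)
  }
})

test_that("quadrant statistics handle hand-placed and degenerate layouts", {
  # all events upper-left
  t <- toy_table(rep(-1, 4), rep(3, 4), 1:4)
  g <- bin_grid("SSC", "FCER1A", x_threshold = 0, y_threshold = 0)
  q <- quadrant_statistics(t, g, toy_map(), "CD63", 0, "UL")
  expect_equal(unname(q$q_freq), c(100, 0, 0, 0))

  # 8 events, 2 per quadrant, one z-positive in UL -> red percentage 50
  t8 <- toy_table(x = c(-1, -1, 1, 1, -1, -1, 1, 1),
                  y = c(1, 1, 1, 1, -1, -1, -1, -1),
                  z = c(5, 0, 0, 0, 0, 0, 0, 0))
  q8 <- quadrant_statistics(t8, g, toy_map(), "CD63", 1, "UL")
  expect_equal(unname(q8$q_freq), c(25, 25, 25, 25))
  expect_equal(q8$zpos_pct_target, 50)
  expect_equal(q8$zpos_count, 1L)

  # threshold beyond all x puts everything left
  g_far <- bin_grid("SSC", "FCER1A", x_threshold = 100, y_threshold = 0)
  qf <- quadrant_statistics(t8, g_far, toy_map(), "CD63", 1, "UL")
  expect_equal(qf$q_freq[["UR"]] + qf$q_freq[["LR"]], 0)

  # empty target quadrant warns and reports NA
  t_ll <- toy_table(rep(1, 5), rep(-1, 5), rep(0, 5))
  expect_warning(qe <- quadrant_statistics(t_ll, g, toy_map(), "CD63", 0, "UL"),
                 class = "binbat_empty_quadrant")
  expect_true(is.na(qe$zpos_pct_target))
})

test_that("quadrant frequencies always sum to 100", {
  set.seed(3)
  for (i in 1:5) {
    t <- toy_table(rnorm(200), rnorm(200), rnorm(200))
    g <- bin_grid("SSC", "FCER1A", x_threshold = rnorm(1), y_threshold = rnorm(1))
    q <- quadrant_statistics(t, g, toy_map(), "CD63", 0, "UL")
    expect_equal(sum(q$q_freq), 100, tolerance = 0.01)
  }
})

test_that("raising the z threshold never raises freq_zpos or lowers msi_pos", {
  set.seed(23)
  t <- toy_table(runif(800, 0, 4), runif(800, 0, 4), rnorm(800, 2))
  g <- bin_grid("SSC", "FCER1A")
  prev <- NULL
  for (thr in c(0, 1, 2, 3)) {
    st <- bin_statistics(t, g, toy_map(), "CD63", thr, 1)
    if (!is.null(prev)) {
      expect_true(all(st$freq_zpos <= prev$freq_zpos + 1e-12))
      both <- !is.na(st$msi_pos) & !is.na(prev$msi_pos)
      expect_true(all(st$msi_pos[both] >= prev$msi_pos[both] - 1e-12))
    }
    prev <- st
  }
})

test_that("event-weighted mean of per-bin MSI equals the global mean", {
  set.seed(29)
  z <- rnorm(600, 3, 2)
  t <- toy_table(runif(600), runif(600), z)
  st <- bin_statistics(t, bin_grid("SSC", "FCER1A", 0.1), toy_map(), "CD63", 0, 1)
  expect_equal(sum(st$msi_all * st$n_events) / sum(st$n_events), mean(z),
               tolerance = 1e-9)
})

test_that("color scaling normalizes over usable bins only", {
  st <- data.frame(ix = 1:3, iy = 0, n_events = c(20, 20, 20), density = 1 / 3,
                   freq_zpos = 0, msi_all = c(1, 2, 3), msi_pos = c(1, 2, 3),
                   below_cutoff = FALSE)
  expect_equal(as.vector(bin_color_scale(st, "MSI")), c(0, 0.5, 1))

  st$msi_all <- c(2, 2, 2)
  expect_equal(as.vector(bin_color_scale(st, "MSI")), c(0.5, 0.5, 0.5))

  # below-cutoff bin excluded from the min/max but still present (NA)
  st2 <- data.frame(ix = 1:3, iy = 0, n_events = c(2, 20, 20), density = 1 / 3,
                    freq_zpos = 0, msi_all = c(100, 2, 4), msi_pos = NA,
                    below_cutoff = c(TRUE, FALSE, FALSE))
  cols <- bin_color_scale(st2, "MSI")
  expect_true(is.na(cols[1]))
  expect_equal(attr(cols, "range"), c(min = 2, max = 4))
  expect_equal(cols[2:3], c(0, 1))

  st2$below_cutoff <- TRUE
  expect_error(bin_color_scale(st2, "MSI"), class = "binbat_empty_sample")
})

test_that("grid thresholds snap onto bin boundaries", {
  g <- bin_grid("SSC", "FCER1A", bin_width = 0.2, x_threshold = 0.31, y_threshold = 0.49)
  expect_equal(g$x_threshold, 0.4)
  expect_equal(g$y_threshold, 0.4)
  expect_error(bin_grid("SSC", "FCER1A", bin_width = 0), class = "binbat_config_error")
})
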