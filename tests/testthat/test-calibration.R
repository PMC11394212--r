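test_that("nearest-rank z calibration matches enumeration on 1..100", {
  z <- 1:100
  thr1 <- calibrate_z_threshold(z, 1)
  expect_equal(as.numeric(thr1), 99)
  expect_equal(sum(z > thr1), 1L)
  expect_equal(attr(thr1, "realized_pos_pct"), 1)

  thr70 <- calibrate_z_threshold(z, 70)
  expect_equal(as.numeric(thr70), 30)
  expect_equal(sum(z > thr70), 70L)
  expect_equal(attr(thr70, "realized_pos_pct"), 70)
})

test_that("z calibration guards small and degenerate inputs", {
  expect_error(calibrate_z_threshold(1:9, 1), class = "binbat_insufficient_events")
  expect_warning(calibrate_z_threshold(1:20, 1), class = "binbat_low_events")
  suppressWarnings({
    thr <- calibrate_z_threshold(rep(5, 60), 10)
    expect_equal(attr(thr, "realized_pos_pct"), 0)
  })
  expect_warning(calibrate_z_threshold(rep(5, 60), 10), class = "binbat_degenerate_z")
})

test_that("realized positive fraction is within nearest-rank granularity of target", {
  set.seed(8)
  for (n in c(57, 213, 1000)) {
    z <- rnorm(n)
    for (target in c(1, 5, 70)) {
      thr <- suppressWarnings(calibrate_z_threshold(z, target))
      realized <- 100 * sum(z > thr) / n
      expect_lte(realized, target + 1e-9)
      expect_gte(realized, target - 100 / n - 1e-9)
    }
  }
})

test_that("axis search recovers labeled basophils on a seeded unstim sample", {
  s <- generate_sample(synthetic_profile(), "UNSTIM", 100000, seed = 101)
  p <- prep_with_truth(s)
  ax <- find_axis_thresholds(p$events, test_map())
  ssc <- marker_values(p$events, "SSC", test_map())
  fce <- marker_values(p$events, "FCER1A", test_map())
  in_ul <- ssc < ax$thr_ssc & fce >= ax$thr_fcer1a
  is_baso <- p$truth$population == "basophil"
  recovery <- sum(in_ul & is_baso) / sum(is_baso)
  contamination <- sum(in_ul & !is_baso) / sum(in_ul)
  expect_gte(recovery, 0.9)
  expect_lte(contamination, 0.1)
})

test_that("basophil-free samples make calibration fail loudly", {
  pp <- default_pop_params()
  pp$lymphocyte$frac <- pp$lymphocyte$frac + pp$basophil$frac
  pp$basophil$frac <- 0
  s <- generate_sample(synthetic_profile(pop_params = pp), "UNSTIM", 50000, seed = 7)
  cfg <- bat_config()
  tt <- apply_transform(pregate(s$events, cfg$map, cfg$pregate), cfg$transform)
  expect_error(find_axis_thresholds(tt, cfg$map), class = "binbat_calibration_failure")
})

test_that("exact candidate ties resolve to the lower FcERIa threshold", {
  # the events between the two candidate FcERIa thresholds are all
  # SSC-high, so both candidates select the identical UL set: tied
  # purity and count -> the lower threshold must win
  x <- c(rep(1, 30), rep(5, 20), rep(1, 50))    # SSC
  y <- c(rep(10, 30), rep(4, 20), rep(1, 50))   # FcERIa
  z32 <- c(rep(10, 30), rep(10, 20), rep(0, 50))
  t <- event_table(cbind(X = x, Y = y, Z = rep(0, 100), W = z32), transformed = TRUE)
  map <- channel_map(SSC = "X", FCER1A = "Y", CD63 = "Z", CD32 = "W")
  cfg <- calibration_config(baso_freq_bounds = c(5, 60),
                            ssc_quantile_grid = 0.9,     # -> thr_ssc = 5
                            fcer1a_quantile_grid = c(0.6, 0.8))  # -> 4 and 10
  ax <- find_axis_thresholds(t, map, cfg)
  expect_equal(ax$thr_fcer1a, 4)
  expect_equal(ax$n_ul, 30L)
})

test_that("frozen thresholds reproduce calibration targets on the calibration sample", {
  s <- generate_sample(synthetic_profile(), "UNSTIM", 80000, seed = 13)
  cfg <- bat_config()
  tt <- apply_transform(pregate(s$events, cfg$map, cfg$pregate), cfg$transform)
  ax <- find_axis_thresholds(tt, cfg$map, cfg$calibration)
  ssc <- marker_values(tt, "SSC", cfg$map)
  fce <- marker_values(tt, "FCER1A", cfg$map)
  baso <- subset_events(tt, ssc < ax$thr_ssc & fce >= ax$thr_fcer1a)
  thr63 <- calibrate_z_threshold(baso, 1, "CD63", cfg$map)
  thr32 <- calibrate_z_threshold(baso, 70, "CD32", cfg$map)
  ts <- threshold_set(ax$thr_ssc, ax$thr_fcer1a, as.numeric(thr63), as.numeric(thr32), "u")
  sr <- apply_thresholds(tt, cfg$map, ts)
  expect_equal(sr$n_basophils, ax$n_ul)
  expect_equal(sr$cd63_pos_pct, attr(thr63, "realized_pos_pct"), tolerance = 1e-12)
  expect_equal(sr$cd32_pos_pct, attr(thr32, "realized_pos_pct"), tolerance = 1e-12)
  # identical inputs -> identical thresholds
  ax2 <- find_axis_thresholds(tt, cfg$map, cfg$calibration)
  expect_identical(ax, ax2)
})

test_that("threshold sets are validated", {
  expect_error(threshold_set(1, 2, NaN, 4, "u"), class = "binbat_config_error")
})
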