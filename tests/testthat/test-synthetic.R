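test_that("ground-truth labels are closed and activation implies basophil", {
  s <- generate_sample(synthetic_profile(), "POS_CTRL", 20000, seed = 41)
  expect_equal(nrow(s$truth), 20000L)
  expect_true(all(s$truth$population %in%
    c("basophil", "lymphocyte", "monocyte", "neutrophil", "dc", "debris",
      "thrombocyte", "doublet")))
  expect_true(all(s$truth$population[s$truth$activated] == "basophil"))
  expect_true(all(is.finite(s$events$values)))
  expect_true(all(s$events$values >= 0))
})

test_that("zero activation probability yields no high-component CD63", {
  prof <- synthetic_profile(p_act = list(POS_CTRL = 0))
  s <- generate_sample(prof, "POS_CTRL", 20000, seed = 42)
  expect_equal(sum(s$truth$activated), 0L)
  baso_cd63 <- asinh(s$events$values[s$truth$population == "basophil", "CD63-A"] / 150)
  expect_lt(max(baso_cd63), 3)  # resting component only
})

test_that("basophil counts follow the binomial at the configured fraction", {
  n <- 100000
  s <- generate_sample(synthetic_profile(), "UNSTIM", n, seed = 43)
  n_baso <- sum(s$truth$population == "basophil")
  # binomial band around n*p, allowing ~2% relabeled by doublet merging
  expect_lt(n_baso, n * 0.005 + 3 * sqrt(n * 0.005))
  expect_gt(n_baso, 0.98 * n * 0.005 - 3 * sqrt(n * 0.005))
})

test_that("basophil FcERIa/CD32 correlation matches the latent-factor target", {
  pp <- default_pop_params()
  # concentrate events on basophils so n_baso >= 2000 stays cheap
  pp$basophil$frac <- 0.10
  pp$neutrophil$frac <- pp$neutrophil$frac - 0.095
  s <- generate_sample(synthetic_profile(pop_params = pp), "UNSTIM", 25000, seed = 44)
  ib <- s$truth$population == "basophil"
  expect_gte(sum(ib), 2000)
  fce <- asinh(s$events$values[ib, "FceRIa-A"] / 150)
  cd32 <- asinh(s$events$values[ib, "CD32-A"] / 150)
  expect_lt(abs(cor(fce, cd32) - 0.6), 0.05)
})

test_that("activated basophils are CD32-shifted and CD63/CD32 anticorrelated", {
  s <- generate_sample(synthetic_profile(), "POS_CTRL", 100000, seed = 45)
  ib <- which(s$truth$population == "basophil")
  act <- s$truth$activated[ib]
  cd32 <- asinh(s$events$values[ib, "CD32-A"] / 150)
  cd63 <- asinh(s$events$values[ib, "CD63-A"] / 150)
  expect_lt(mean(cd32[act]), mean(cd32[!act]) - 0.2)  # downshift delta = 0.4
  expect_lt(cor(cd63[act], cd32[act]), -0.2)          # anticorrelation on activated
})

test_that("allergic donors carry the baseline CD32 downshift", {
  sa <- generate_sample(synthetic_profile(allergic = TRUE), "UNSTIM", 100000, seed = 46)
  sn <- generate_sample(synthetic_profile(allergic = FALSE), "UNSTIM", 100000, seed = 46)
  ma <- mean(asinh(sa$events$values[sa$truth$population == "basophil", "CD32-A"] / 150))
  mn <- mean(asinh(sn$events$values[sn$truth$population == "basophil", "CD32-A"] / 150))
  expect_equal(mn - ma, 0.3, tolerance = 0.06)
})

test_that("experiments are deterministic under the master seed", {
  prof <- synthetic_profile()
  e1 <- generate_experiment(prof, n_events = 2000, seed = 47)
  e2 <- generate_experiment(prof, n_events = 2000, seed = 47)
  expect_identical(lapply(e1, function(s) s$events$values),
                   lapply(e2, function(s) s$events$values))
  expect_identical(lapply(e1, `[[`, "truth"), lapply(e2, `[[`, "truth"))
  expect_error(generate_experiment(prof, conditions = c("POS_CTRL")),
               class = "binbat_config_error")
})

test_that("non-responder profiles activate at most marginally in positive control", {
  prof <- synthetic_profile(responder = FALSE)
  s <- generate_sample(prof, "POS_CTRL", 50000, seed = 48)
  ib <- s$truth$population == "basophil"
  expect_lte(mean(s$truth$activated[ib]), 0.05)
})

test_that("cohorts pair one allergic and one non-allergic donor per experiment", {
  coh <- generate_cohort(3, n_events = 2000, seed = 49)
  expect_length(coh, 3)
  for (e in coh) {
    expect_equal(e$non_allergic[[1]]$meta$condition, "UNSTIM")
    expect_match(e$allergic[[1]]$meta$donor_id, "_AL$")
  }
})

test_that("profile validation rejects malformed parameters", {
  pp <- default_pop_params()
  pp$basophil$frac <- 0.5
  expect_error(synthetic_profile(pop_params = pp), class = "binbat_config_error")
  expect_error(synthetic_profile(p_act = list(UNSTIM = 2)), class = "binbat_config_error")
  expect_error(generate_sample(synthetic_profile(), "UNSTIM", 500, 1),
               class = "binbat_config_error")
})
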