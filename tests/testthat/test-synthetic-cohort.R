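# Generator contracts: determinism, no-signal limit, oracle calibration,
# planted canonical correlations, confound leakage after residualization.

test_that("identical config and seed give identical cohorts", {
  cfg <- sim_config(n_subjects = 15, n_gray_unilateral = 8, n_wm_targets = 3,
                    visit_range = c(1, 2), n_timepoints = 40, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$fa, b$fa)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$visits, b$visits)
  c2 <- simulate_cohort(sim_config(n_subjects = 15, n_gray_unilateral = 8,
                                   n_wm_targets = 3, visit_range = c(1, 2),
                                   n_timepoints = 40, seed = 6))
  expect_false(identical(a$features, c2$features))
})

test_that("without signal, noise or latent trait, FA is pure confound structure", {
  cfg <- sim_config(n_subjects = 12, n_gray_unilateral = 8, n_wm_targets = 2,
                    visit_range = c(2, 2), n_timepoints = 40,
                    beta_scale = 0, subject_intercept_sd = 0,
                    visit_noise_sd = 0, latent_trait_dim = 0,
                    motion_gap_effect = 0, seed = 9)
  coh <- simulate_cohort(cfg)
  ce <- cfg$confound_effects
  conf_part <- ce$age * (coh$visits$age - 17) +
    ce$sexM * (coh$visits$sex == "M") +
    ce$scanner * (coh$visits$scanner == "Siemens") +
    ce$ses * (coh$visits$ses - 16.8)
  for (tg in names(coh$fa)) {
    resid <- coh$fa[[tg]] - conf_part
    # identical across visits within subject once confounds are removed
    spread <- tapply(resid, coh$visits$subject, function(v) diff(range(v)))
    expect_lt(max(spread), 1e-12)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(visit_range = c(3, 1)))
  expect_error(sim_config(subject_intercept_sd = -1))
  expect_error(sim_config(n_gray_unilateral = 7))
  expect_error(sim_config(n_gray_unilateral = 6, support_size = 100),
               "support_size")
  expect_error(sim_config(latent_trait_dim = 3,
                          gap_loading_scale = c(0.1, 0.1)),
               "gap_loading_scale")
})

test_that("beta calibration hits the requested oracle accuracy exactly", {
  cfg <- sim_config(n_subjects = 120, n_gray_unilateral = 12,
                    n_wm_targets = 3, visit_range = c(1, 3),
                    n_timepoints = 60, seed = 33)
  cfg <- calibrate_beta_scale(cfg, 0.3, pilot_subjects = 120)
  coh <- simulate_cohort(cfg)
  # same seed and size as the pilot: the realized signal variance matches
  expect_equal(oracle_prediction_r(coh)$r, 0.3, tolerance = 1e-10)
})

test_that("planted canonical correlations follow the closed form", {
  # hand-checkable rank-1 case: rho = s^2 / (s^2 + sigma^2) for equal sides
  s <- sqrt(0.3 / 0.7)
  gx <- matrix(c(s, 0, 0), 3, 1)
  gy <- matrix(c(s, 0, 0, 0), 4, 1)
  rho <- planted_canonical_correlations(gx, gy, 1, 1)
  expect_equal(rho, 0.3, tolerance = 1e-12)

  # simulate_cca_pair: empirical canonical correlation near the planted one
  pair <- simulate_cca_pair(20000, rho = c(0.4, 0.25), p = 6, q = 9, seed = 2)
  cc <- cancor(pair$X, pair$Y)
  expect_lt(max(abs(cc$cor[1:2] - c(0.4, 0.25))), 0.03)
})

test_that("behavior missingness and dimensions match the config", {
  cfg <- sim_config(n_subjects = 30, n_gray_unilateral = 8, n_wm_targets = 3,
                    behavior_dim = 40, behavior_missing_rate = 0.1,
                    visit_range = c(1, 2), n_timepoints = 40, seed = 12)
  coh <- simulate_cohort(cfg)
  expect_identical(ncol(coh$behavior), 40L)
  expect_lt(abs(mean(is.na(coh$behavior)) - 0.1), 0.03)
  expect_identical(ncol(coh$fa), 4L)  # whole brain + 3 regions
})

test_that("FC features stay in [-1, 1] and visits stay within range", {
  coh <- small_cohort()
  expect_true(all(coh$features >= -1 & coh$features <= 1))
  nv <- table(coh$visits$subject)
  expect_true(all(nv >= 1 & nv <= 3))
  expect_identical(nrow(coh$features), nrow(coh$visits))
})

test_that("residualized FA shows no confound leakage at scale", {
  cfg <- sim_config(n_subjects = 700, n_gray_unilateral = 8, n_wm_targets = 2,
                    visit_range = c(2, 3), n_timepoints = 40,
                    beta_scale = 0.3, seed = 44)
  coh <- simulate_cohort(cfg)
  conf <- coh$visits[c("age", "sex", "scanner", "ses")]
  m <- fit_confound_model(coh$fa$whole_brain, conf, coh$visits$subject)
  r <- residualize(m, coh$fa$whole_brain, conf)
  expect_lt(abs(cor(r, coh$visits$age)), 0.02)
  expect_lt(abs(cor(r, as.numeric(coh$visits$sex == "M"))), 0.02)
  expect_lt(abs(cor(r, coh$visits$ses)), 0.02)
  expect_lt(abs(cor(r, as.numeric(coh$visits$scanner == "Siemens"))), 0.02)
})

test_that("cohort round-trips through the delimited-table writer", {
  coh <- small_cohort()
  dir <- tempfile("cohort_")
  write_cohort(coh, dir)
  v <- read_table_auto(file.path(dir, "visits.tsv"))
  expect_equal(nrow(v), nrow(coh$visits))
  f <- read_table_auto(file.path(dir, "fc_features.tsv"))
  expect_equal(ncol(f), ncol(coh$features) + 2)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_setequal(gt$support_sets$whole_brain,
                  coh$ground_truth$support_sets$whole_brain)
  unlink(dir, recursive = TRUE)
})
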