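# Subject-level folds, the prediction harness, scoring and model comparison.

test_that("subject folds are balanced, leakage-free and deterministic", {
  cv <- subject_kfold(sprintf("S%03d", 1:10), K = 5, seed = 3)
  expect_true(all(table(cv$assignment$fold) == 2))
  cv2 <- subject_kfold(sprintf("S%03d", 1:10), K = 5, seed = 3)
  expect_identical(cv$assignment, cv2$assignment)
  expect_error(subject_kfold(1:10, K = 1), "at least 2")
  expect_error(subject_kfold(1:3, K = 5), "at least K")

  # all visits of a subject share the fold
  visits <- toy_visits(10, visits_per_subject = 6)
  f <- fold_of(cv, visits$subject)
  expect_true(all(tapply(f, visits$subject,
                         function(x) length(unique(x))) == 1))
  # 23 subjects over 5 folds: sizes within one of each other
  cv3 <- subject_kfold(sprintf("S%02d", 1:23), K = 5, seed = 1)
  sz <- table(cv3$assignment$fold)
  expect_lte(max(sz) - min(sz), 1)
})

test_that("evaluate_prediction matches hand computation and flags degeneracy", {
  pred <- c(0.1, 0.4, 0.3, 0.8, 0.5)
  obs <- c(0.2, 0.3, 0.5, 0.7, 0.4)
  e <- evaluate_prediction(pred, obs)
  expect_equal(e$mse, mean((pred - obs)^2), tolerance = 1e-12)
  expect_equal(e$r, cor(pred, obs), tolerance = 1e-12)
  expect_equal(e$p, cor.test(pred, obs)$p.value, tolerance = 1e-10)
  expect_equal(evaluate_prediction(obs, obs)[c("mse", "r")], list(mse = 0, r = 1))
  expect_equal(evaluate_prediction(-obs, obs)$r, -1)
  d <- evaluate_prediction(rep(1, 5), obs)
  expect_true(d$degenerate)
  expect_true(is.na(d$r))
})

test_that("noiseless linear targets are recovered by the lasso harness", {
  coh <- small_cohort()
  set.seed(41)
  beta <- rnorm(ncol(coh$features))
  y <- as.numeric(coh$features %*% beta)
  cv <- subject_kfold(coh$visits$subject, K = 5, seed = 2)
  res <- cross_validated_prediction(coh$features, y, coh$visits, cv,
                                    model = model_spec("lasso"),
                                    confounds = NULL, seed = 3)
  expect_gte(res$summary$r, 0.999)
})

test_that("prediction harness is deterministic and leakage-guarded", {
  coh <- small_cohort()
  cv <- subject_kfold(coh$visits$subject, K = 4, seed = 9)
  conf <- coh$visits[c("age", "sex")]
  run <- function() cross_validated_prediction(
    coh$features[, 1:20], coh$fa$whole_brain, coh$visits, cv,
    model = model_spec("gp_ard", n_starts = 1, maxit = 50),
    confounds = conf, seed = 13)
  r1 <- run(); r2 <- run()
  expect_identical(r1$rows, r2$rows)
  expect_identical(coef(r1$models[[1]]), coef(r2$models[[1]]))

  # deleting a test subject must not change training-fold fits
  te_subj <- r1$rows$subject[r1$rows$fold == 1][1]
  keep <- coh$visits$subject != te_subj
  r3 <- cross_validated_prediction(
    coh$features[keep, 1:20], coh$fa$whole_brain[keep], coh$visits[keep, ],
    cv, model = model_spec("gp_ard", n_starts = 1, maxit = 50),
    confounds = conf[keep, ], seed = 13)
  expect_identical(coef(r1$models[[1]]), coef(r3$models[[1]]))

  # a cv split missing the cohort's subjects errors out
  cv_bad <- subject_kfold(paste0("X", 1:10), K = 2, seed = 1)
  expect_error(cross_validated_prediction(
    coh$features[, 1:5], coh$fa$whole_brain, coh$visits, cv_bad), "missing")
})

test_that("every model-zoo regressor runs through the identical harness", {
  coh <- small_cohort()
  cv <- subject_kfold(coh$visits$subject, K = 3, seed = 5)
  set.seed(44)
  y <- as.numeric(coh$features %*%
                    c(rep(1, 10), rep(0, ncol(coh$features) - 10))) +
    rnorm(nrow(coh$features), sd = 0.05)
  rs <- sapply(c("lasso", "elastic_net", "random_forest", "svr", "mlp"),
               function(nm) {
    res <- cross_validated_prediction(coh$features, y, coh$visits, cv,
                                      model = model_spec(nm), seed = 17)
    res$summary$r
  })
  expect_true(all(is.finite(rs)))
  expect_true(all(rs > 0.3))  # strong planted signal: every model finds some
})

test_that("transfer evaluation enforces disjoint subjects and matches CV on
          exchangeable cohorts", {
  coh <- small_cohort(n_subjects = 60, seed = 15)
  subj <- unique(coh$visits$subject)
  half <- coh$visits$subject %in% subj[1:30]
  set.seed(46)
  y <- as.numeric(coh$features %*% rnorm(ncol(coh$features))) +
    rnorm(nrow(coh$features), sd = 0.2)
  tr <- transfer_evaluate(half, !half, coh$features, y, coh$visits,
                          model = model_spec("lasso"), seed = 2)
  cv <- subject_kfold(coh$visits$subject, K = 2, seed = 3)
  res <- cross_validated_prediction(coh$features, y, coh$visits, cv,
                                    model = model_spec("lasso"), seed = 2)
  expect_lt(abs(tr$summary$r - res$summary$r), 0.05)
  expect_error(transfer_evaluate(half, half, coh$features, y, coh$visits),
               "overlap")

  # stratified scoring of homogeneous strata reproduces the pooled r
  st <- evaluate_strata(res, rep(c("A", "B"), length.out = nrow(res$rows)))
  expect_equal(nrow(st), 2L)
  expect_lt(max(abs(st$r - res$summary$r)), 0.1)
})

test_that("friedman ranking matches a brute-force rank table", {
  acc <- rbind(gp = c(0.30, 0.25, 0.28, 0.22),
               lasso = c(0.20, 0.21, 0.18, 0.15),
               rf = c(0.10, 0.23, 0.15, 0.18))
  fr <- friedman_rank(acc)
  manual <- apply(acc, 2, function(col) rank(-col))
  expect_equal(fr$mean_ranks[rownames(acc)], rowMeans(manual))
  expect_equal(unname(fr$mean_ranks["gp"]), 1.0)
  ft <- stats::friedman.test(t(acc))
  expect_equal(fr$statistic, unname(ft$statistic))
  expect_equal(fr$p, ft$p.value)
  # identical models tie
  acc2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(unname(friedman_rank(acc2)$mean_ranks), c(1.5, 1.5))
  expect_error(friedman_rank(acc[, 1, drop = FALSE]), "at least 2")
})
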