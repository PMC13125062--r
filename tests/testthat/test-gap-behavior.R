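# Gap computation, motion/FA correction, the Spearman coupling baseline,
# regularized CCA with permutation inference and loadings.

test_that("raw gaps are exact predicted-minus-observed differences", {
  subj <- c("A", "A", "B", "C")
  obs <- c(0.5, 0.52, 0.48, 0.51)
  g0 <- compute_gap(list(t1 = fake_result(obs, obs, subj)))
  expect_true(all(g0$t1 == 0))
  g1 <- compute_gap(list(t1 = fake_result(obs + 0.01, obs, subj)))
  expect_true(all(abs(g1$t1 - 0.01) < 1e-15))
  # toy 4-visit hand subtraction across two targets
  pred2 <- c(0.4, 0.6, 0.55, 0.5)
  g2 <- compute_gap(list(t1 = fake_result(obs + 0.01, obs, subj),
                         t2 = fake_result(pred2, obs, subj)))
  expect_equal(g2$t2, pred2 - obs)
  # missing row errors with the visit key
  short <- fake_result(pred2[1:3], obs[1:3], subj[1:3])
  expect_error(compute_gap(list(t1 = fake_result(obs, obs, subj), t2 = short)),
               "missing prediction row")
})

test_that("motion correction decorrelates gaps from motion and observed FA", {
  set.seed(71)
  n <- 2000
  subj <- rep(sprintf("S%04d", 1:1000), each = 2)
  motion <- abs(rnorm(n, 0.12, 0.05))
  obs <- rnorm(n, 0.5, 0.03)
  gaps <- data.frame(subject = subj,
                     visit = rep(1:2, 1000),
                     t1 = 2 * motion + 0.5 * obs + rnorm(n, sd = 0.05))
  corr <- correct_gap(gaps, motion, data.frame(t1 = obs))
  expect_lt(abs(cor(corr$t1, motion)), 0.02)
  expect_lt(abs(cor(corr$t1, obs)), 0.02)
  expect_lt(abs(mean(corr$t1)), 1e-10)
})

test_that("correction reduces to centering under null coefficients and is
          idempotent in the single-visit regime", {
  set.seed(72)
  n <- 400
  gaps <- data.frame(subject = sprintf("S%03d", 1:n), visit = 1,
                     t1 = rnorm(n))
  motion <- abs(rnorm(n, 0.1, 0.03))
  obs <- rnorm(n, 0.5, 0.02)
  c1 <- correct_gap(gaps, motion, data.frame(t1 = obs))
  # null truth: correction is approximately mean-centering
  expect_gt(cor(c1$t1, gaps$t1 - mean(gaps$t1)), 0.99)
  # projection property: applying the correction twice changes nothing
  g2 <- c1; c2 <- correct_gap(g2, motion, data.frame(t1 = obs))
  expect_lt(max(abs(c2$t1 - c1$t1)), 1e-8)
  # missing motion drops the visit with a warning
  m2 <- motion; m2[5] <- NA
  expect_warning(c3 <- correct_gap(gaps, m2, data.frame(t1 = obs)), "dropped")
  expect_equal(nrow(c3), n - 1)
})

test_that("spearman SC-FC coupling is rank-invariant and matches by hand", {
  set.seed(73)
  R <- 5
  fc <- matrix(runif(R * R, -0.5, 0.9), R, R); fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  dimnames(fc) <- list(letters[1:R], letters[1:R])
  sc <- exp(2 * fc)  # monotone transform of each row
  cp <- scfc_spearman_coupling(sc, fc)
  expect_true(all(abs(cp - 1) < 1e-12))
  # reversed order gives -1
  sc2 <- exp(-2 * fc)
  expect_true(all(abs(scfc_spearman_coupling(sc2, fc) + 1) < 1e-12))
  # direct hand computation for one region
  sc3 <- matrix(abs(rnorm(R * R)), R, R)
  cp3 <- scfc_spearman_coupling(sc3, fc)
  expect_equal(unname(cp3["a"]),
               cor(rank(sc3[1, -1]), rank(fc[1, -1])), tolerance = 1e-12)
  # all-tied profile flagged
  sc4 <- matrix(1, R, R)
  cp4 <- suppressWarnings(scfc_spearman_coupling(sc4, fc))
  expect_true(all(is.na(cp4)))
})

test_that("self-linked sides give near-perfect first canonical correlation", {
  set.seed(74)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5)
  visits <- toy_visits(n / 2)
  cv <- subject_kfold(visits$subject, K = 4, seed = 1)
  fit <- fit_rcca(X, X + matrix(rnorm(n * 5, sd = 1e-6), n, 5), visits, cv,
                  grid = c(1e-4, 1e-2), n_components = 2, seed = 2)
  expect_gte(fit$test_cor[1], 0.99)
})

test_that("planted canonical structure is recovered near its population value", {
  set.seed(75)
  pair <- simulate_cca_pair(1500, rho = 0.3, p = 8, q = 20, seed = 31)
  visits <- toy_visits(750)
  cv <- subject_kfold(visits$subject, K = 5, seed = 3)
  fit <- fit_rcca(pair$X, pair$Y, visits, cv, grid = reg_grid(count = 6),
                  n_components = 3, seed = 4)
  expect_gt(fit$test_cor[1], 0.2)
  expect_lt(fit$test_cor[1], 0.4)
})

test_that("independent sides give test correlations centered at zero", {
  set.seed(76)
  cors <- replicate(60, {
    n <- 120
    X <- matrix(rnorm(n * 5), n, 5)
    Y <- matrix(rnorm(n * 10), n, 10)
    visits <- toy_visits(n / 2)
    cv <- subject_kfold(visits$subject, K = 3,
                        seed = sample.int(1e6, 1))
    fit_rcca(X, Y, visits, cv, fixed_reg = c(0.1, 0.1),
             n_components = 1, seed = sample.int(1e6, 1))$test_cor[1]
  })
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("noiseless rank-1 loadings give canonical correlation near one", {
  set.seed(77)
  lat <- matrix(rnorm(2000), 2000, 1)
  B <- plant_behavior(lat, matrix(runif(6, 0.5, 1), 6, 1), noise_sd = 0)
  visits <- toy_visits(1000)
  cv <- subject_kfold(visits$subject, K = 4, seed = 5)
  fit <- fit_rcca(cbind(lat + rnorm(2000, sd = 1e-8)), B, visits, cv,
                  fixed_reg = c(1e-4, 1e-4), n_components = 1, seed = 6)
  expect_gte(fit$test_cor[1], 0.99)
  # rank-deficient loadings warn but proceed
  expect_warning(plant_behavior(matrix(rnorm(20), 10, 2),
                                matrix(1, 4, 2) %*% diag(c(1, 0)),
                                noise_sd = 1), "rank-deficient")
})

test_that("subject-level permutation preserves within-subject blocks and
          yields valid p-values", {
  set.seed(78)
  n_s <- 50
  visits <- rbind(toy_visits(n_s, 2), toy_visits(n_s, 2)[1:10, ])
  Y <- matrix(rnorm(nrow(visits) * 4), nrow(visits), 4)
  set.seed(1)
  idx <- sfgap:::permute_subject_blocks(visits$subject)
  # block structure: within-subject covariance preserved exactly
  d <- Y[idx, 3] ; names(d) <- visits$subject
  blocks <- split(seq_len(nrow(visits)), visits$subject)
  orig_blocks <- lapply(blocks, function(ix) Y[sort(unique(idx[ix])), , drop = FALSE])
  # each permuted block must be an exact copy of some original block
  for (b in blocks[lengths(blocks) == 2][1:5]) {
    blk <- Y[idx[b], , drop = FALSE]
    match_found <- any(vapply(blocks[lengths(blocks) == 2], function(ob)
      isTRUE(all.equal(Y[ob, , drop = FALSE], blk)), TRUE))
    expect_true(match_found)
  }

  # permutation p bounded below by 1/(1+n_perm)
  X <- matrix(rnorm(nrow(visits) * 3), nrow(visits), 3)
  cv <- subject_kfold(visits$subject, K = 3, seed = 2)
  pt <- suppressWarnings(
    permutation_test_cca(X, X, visits, cv, fixed_reg = c(0.1, 0.1),
                         n_components = 1, n_perm = 49, refit_grid = FALSE,
                         seed = 3))
  expect_gte(min(pt$p), 1 / 50)
  expect_lte(pt$p[1], 3 / 50)   # self-link: essentially the smallest possible
})

test_that("strongly linked sides are detected by the permutation test", {
  set.seed(79)
  pair <- simulate_cca_pair(400, rho = 0.6, p = 6, q = 10, seed = 8)
  visits <- toy_visits(200)
  cv <- subject_kfold(visits$subject, K = 4, seed = 9)
  pt <- permutation_test_cca(pair$X, pair$Y, visits, cv,
                             fixed_reg = c(0.1, 0.1), n_components = 2,
                             n_perm = 199, refit_grid = FALSE, seed = 10)
  expect_lte(pt$p[1], 0.01)
})

test_that("canonical loadings identify the planted behavior support", {
  set.seed(80)
  n <- 1000
  lat <- matrix(rnorm(n), n, 1)
  X <- cbind(lat * 0.8 + rnorm(n, sd = 0.6),
             matrix(rnorm(n * 4), n, 4))
  load <- matrix(0, 20, 1); load[1:5, 1] <- c(1, -1, 0.8, 0.9, -0.7)
  Y <- plant_behavior(lat, load, noise_sd = 1, seed = 81)
  visits <- toy_visits(n / 2)
  cv <- subject_kfold(visits$subject, K = 4, seed = 11)
  fit <- fit_rcca(X, Y, visits, cv, fixed_reg = c(0.1, 0.1),
                  n_components = 1, seed = 12)
  ld <- canonical_loadings(fit, X, Y, visits)
  top5 <- order(-abs(ld$y$loading))[1:5]
  expect_setequal(top5, 1:5)
  # variable identical to the variate loads at 1
  v <- fit$variates
  Xv <- cbind(v$x_variate[, 1], matrix(rnorm(nrow(v) * 2), nrow(v), 2))
  fit2 <- fit
  ld2 <- canonical_loadings(fit2, Xv, Y[seq_len(nrow(v)), ],
                            v[c("subject", "visit")])
  expect_equal(abs(ld2$x$loading[1]), 1, tolerance = 1e-8)
})

test_that("behavior missingness filter and imputation behave as documented", {
  set.seed(82)
  n <- 100
  subj <- rep(sprintf("S%02d", 1:50), each = 2)
  B <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("keep", "borderline", "drop")))
  B[1:30, 2] <- NA                     # 15/50 subjects fully missing
  B[seq(1, 96, by = 2), 3] <- NA       # missing at one visit, present at other
  B[1:90, 3] <- NA                     # now missing for most subjects
  kept <- prepare_behavior(B, subj, max_missing = 0.5)
  expect_true("keep" %in% colnames(kept))
  expect_false("drop" %in% colnames(kept))
})
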