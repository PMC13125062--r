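# Reliability filtering, accuracy covariate checks, embedding, PERMANOVA.

test_that("reliability filter keeps faithful predictions, drops noise", {
  set.seed(51)
  subj <- rep(1:60, each = 2)
  obs <- rnorm(120)
  keepres <- fake_result(obs + rnorm(120, sd = 0.1), obs, subj, "good")
  rel <- reliability_filter(list(good = keepres))
  expect_identical(rel$retained, "good")
  expect_lt(rel$table$p, 1e-10)

  # pure-noise predictions: type-I retention close to alpha
  hits <- 0
  for (s in 1:200) {
    set.seed(1000 + s)
    obs <- rnorm(120)
    nr <- fake_result(rnorm(120), obs, subj)
    hits <- hits + nrow(reliability_filter(list(t = nr))$table[
      reliability_filter(list(t = nr))$table$retained, ])
  }
  expect_lt(abs(hits / 200 - 0.05), 2 * sqrt(0.05 * 0.95 / 200) + 0.02)
})

test_that("accuracy covariate check matches direct correlation formulas", {
  acc <- data.frame(target = c("a", "b", "c", "whole_brain"),
                    r = c(0.1, 0.2, 0.3, 0.5),
                    volume_cm3 = c(1, 2, 3, 10),
                    mean_observed_fa = c(0.5, 0.45, 0.4, 0.5))
  chk <- accuracy_covariate_check(acc)
  expect_equal(chk$r[chk$covariate == "volume_cm3"],
               cor(c(0.1, 0.2, 0.3), c(1, 2, 3)), tolerance = 1e-12)
  expect_equal(chk$r[chk$covariate == "mean_fa"],
               cor(c(0.1, 0.2, 0.3), c(0.5, 0.45, 0.4)), tolerance = 1e-12)
  # accuracy proportional to volume -> r = 1
  acc$r <- acc$volume_cm3 / 10
  expect_equal(accuracy_covariate_check(acc)$r[1], 1, tolerance = 1e-12)
  expect_error(accuracy_covariate_check(acc[1:2, ]), "at least 3")
})

test_that("embedding is deterministic, keeps duplicates together, separates blobs", {
  set.seed(52)
  M <- matrix(rnorm(10 * 6), 10, 6)
  e1 <- embed_importance(M, seed = 4)
  e2 <- embed_importance(M, seed = 4)
  expect_identical(e1$coords, e2$coords)

  # duplicated rows land nearly on top of each other
  Md <- rbind(M, M[3, ])
  ed <- embed_importance(Md, seed = 4)
  dup_d <- sqrt(sum((ed$coords[11, ] - ed$coords[3, ])^2))
  diam <- max(dist(ed$coords))
  expect_lt(dup_d, 0.1 * diam)

  # two well-separated blobs: linearly separable in >= 18/20 seeds
  sep <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    A <- matrix(rnorm(8 * 5), 8, 5)
    B <- matrix(rnorm(8 * 5, mean = 8), 8, 5)
    co <- embed_importance(rbind(A, B), seed = s, normalize = FALSE)$coords
    lab <- rep(0:1, each = 8)
    fit <- suppressWarnings(glm(lab ~ co[, 1] + co[, 2], family = binomial))
    if (all((fitted(fit) > 0.5) == (lab == 1))) sep <- sep + 1
  }
  expect_gte(sep, 18)

  expect_error(embed_importance(M[1:3, ]), "at least 4")
  expect_warning(embed_importance(M[1:5, ], n_neighbors = 10), "reduced")
})

test_that("permanova permutation p equals exhaustive enumeration on tiny sets", {
  skip_if_not_installed("vegan")
  for (seed in 1:3) {
    set.seed(600 + seed)
    pts <- matrix(rnorm(10), 5, 2)
    lab <- c("a", "a", "b", "b", "b")
    ex <- permanova_test(pts, lab, method = "exhaustive")
    # independent oracle: enumerate label permutations, score F via vegan
    D <- dist(pts)
    Fs <- apply(sfgap:::.all_perms(5), 1, function(idx)
      vegan::adonis2(D ~ g, data = data.frame(g = lab[idx]),
                     permutations = 0)$F[1])
    expect_equal(ex$F, Fs[1], tolerance = 1e-10)  # identity permutation
    expect_equal(ex$p, mean(Fs >= Fs[1] - 1e-12), tolerance = 1e-12)
  }
})

test_that("permanova pseudo-F agrees with vegan and the test calibrates", {
  skip_if_not_installed("vegan")
  set.seed(61)
  pts <- matrix(rnorm(40), 20, 2)
  lab <- rep(c("x", "y"), 10)
  pt <- permanova_test(pts, lab, n_perm = 499, seed = 2)
  vg <- vegan::adonis2(dist(pts) ~ g, data = data.frame(g = lab),
                       permutations = 99)
  expect_equal(pt$F, vg$F[1], tolerance = 1e-10)

  # type-I: labels random wrt coordinates
  rej <- 0
  for (s in 1:200) {
    set.seed(700 + s)
    pts <- matrix(rnorm(24), 12, 2)
    lab <- sample(rep(c("a", "b", "c"), 4))
    if (permanova_test(pts, lab, n_perm = 199, seed = s)$p <= 0.05)
      rej <- rej + 1
  }
  expect_lt(abs(rej / 200 - 0.05), 2 * sqrt(0.05 * 0.95 / 200) + 0.02)

  # identical groups: p lands in the no-separation region
  same <- rbind(matrix(rnorm(10), 5, 2), matrix(rnorm(10), 5, 2))
  pid <- permanova_test(rbind(same, same),
                        rep(c("g1", "g2"), each = 10), n_perm = 199, seed = 3)
  expect_gt(pid$p, 0.2)
})

test_that("tract-shared planted supports cluster; shuffled supports do not", {
  rej_shared <- rej_null <- 0
  n_rep <- 12
  for (s in 1:n_rep) {
    # importance stand-ins: tract families share a support pattern
    set.seed(900 + s)
    p <- 40
    fam <- rep(1:4, each = 5)
    proto <- matrix(rnorm(4 * p, sd = 1), 4, p)
    M_shared <- proto[fam, ] + matrix(rnorm(20 * p, sd = 0.35), 20, p)
    M_null <- matrix(rnorm(20 * p), 20, p)
    lab <- paste0("t", fam)
    co_s <- embed_importance(M_shared, seed = s)$coords
    co_n <- embed_importance(M_null, seed = s)$coords
    if (permanova_test(co_s, lab, n_perm = 199, seed = s)$p < 0.05)
      rej_shared <- rej_shared + 1
    if (permanova_test(co_n, lab, n_perm = 199, seed = s)$p < 0.05)
      rej_null <- rej_null + 1
  }
  expect_gte(rej_shared, round(0.9 * n_rep))
  expect_lte(rej_null, round(0.35 * n_rep))
})
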