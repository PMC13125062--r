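# FC construction, hemispheric averaging and vectorization.

test_that("fc_from_timeseries reproduces hand-computed Pearson correlations", {
  set.seed(11)
  ts <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  fc <- fc_from_timeseries(ts)
  # direct formula evaluation, entry by entry
  for (i in 1:3) for (j in 1:3) {
    x <- ts[, i] - mean(ts[, i]); y <- ts[, j] - mean(ts[, j])
    expect_equal(unclass(fc)[i, j], sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
                 tolerance = 1e-12)
  }
  expect_identical(attr(fc, "diagonal"), "unit")

  dup <- cbind(a = ts[, 1], b = ts[, 1], c = -ts[, 1] + 0)
  fc2 <- fc_from_timeseries(dup)
  expect_equal(unclass(fc2)["a", "b"], 1)
  expect_equal(unclass(fc2)["a", "c"], -1)

  bad <- ts; bad[, 2] <- 5
  expect_error(fc_from_timeseries(bad), "zero-variance.*b")
  expect_error(fc_from_timeseries(ts[1:2, ]), "3 timepoints")
})

test_that("bilateral averaging produces the documented dimensions", {
  # 106 unilateral regions -> 53x53; 86 -> 43x43
  for (cfg in list(c(106, 53), c(86, 43))) {
    at <- synthetic_atlas(cfg[1], 5, seed = 2)
    pr <- atlas_pairing(at)
    ts <- sample_homotopic_timeseries(60, cfg[1], pairing = pr, seed = 4)
    bil <- bilateral_average(fc_from_timeseries(ts), pr)
    expect_identical(dim(bil), as.integer(c(cfg[2], cfg[2])))
    expect_identical(attr(bil, "diagonal"), "homotopic")
  }
})

test_that("bilateral averaging takes the mean of the four cross-pair entries", {
  at <- synthetic_atlas(6, 3, seed = 1)
  pr <- atlas_pairing(at)
  labs <- c(pr$left, pr$right)
  # constant off-diagonal input: averaging must preserve the constant
  cst <- matrix(0.4, 6, 6, dimnames = list(labs, labs)); diag(cst) <- 1
  bil <- bilateral_average(fc_matrix(cst), pr)
  off <- unclass(bil)[row(bil) != col(bil)]
  expect_true(all(abs(off - 0.4) < 1e-12))
  expect_true(all(abs(diag(unclass(bil)) - 0.4) < 1e-12))

  # hand-check one off-diagonal and one homotopic entry on random input
  set.seed(9)
  ts <- sample_homotopic_timeseries(50, 6, pairing = pr, seed = 9)
  fc <- fc_from_timeseries(ts)
  bil <- bilateral_average(fc, pr)
  i <- 1; j <- 2
  four <- c(fc[pr$left[i], pr$left[j]], fc[pr$left[i], pr$right[j]],
            fc[pr$right[i], pr$left[j]], fc[pr$right[i], pr$right[j]])
  expect_equal(unclass(bil)[i, j], mean(four), tolerance = 1e-12)
  expect_equal(unclass(bil)[i, i], unclass(fc)[pr$left[i], pr$right[i]],
               tolerance = 1e-12)
  expect_error(bilateral_average(fc, pr[-1, ]), "unpaired")
})

test_that("vectorization counts, order and round trip are exact", {
  at <- synthetic_atlas(106, 27, seed = 3)
  labs <- bilateral_names(at)
  expect_identical(nrow(fc_feature_index(labs)), 1431L)            # 53*54/2
  expect_identical(nrow(fc_feature_index(sprintf("R%02d", 1:43))), 946L)
  expect_identical(nrow(fc_feature_index(labs, include_diagonal = FALSE)),
                   as.integer(53 * 52 / 2))

  m <- matrix(c(0.2, 0.5, 0.5, -0.1), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  v <- vectorize_fc(fc_matrix(m, diagonal = "homotopic"))
  expect_equal(as.numeric(v), c(0.2, 0.5, -0.1))   # row-major upper triangular
  expect_identical(names(v), c("A|A", "A|B", "B|B"))

  set.seed(5)
  pr <- atlas_pairing(synthetic_atlas(10, 3, seed = 5))
  ts <- sample_homotopic_timeseries(40, 10, pairing = pr, seed = 5)
  bil <- bilateral_average(fc_from_timeseries(ts), pr)
  back <- devectorize_fc(vectorize_fc(bil))
  expect_equal(as.matrix(back), as.matrix(bil), tolerance = 1e-12)

  asym <- matrix(c(1, 0.2, 0.3, 1), 2, 2)
  expect_error(vectorize_fc(asym), "asymmetric")
})

test_that("feature index order is stable across cohorts and atlases", {
  labs <- bilateral_names(synthetic_atlas(20, 5, seed = 1))
  idx1 <- fc_feature_index(labs)
  idx2 <- fc_feature_index(bilateral_names(synthetic_atlas(20, 5, seed = 99)))
  expect_identical(idx1$feature, idx2$feature)
  # row-major: first block fixes region 1 as the left member
  expect_identical(idx1$region_i[seq_along(labs)], rep(labs[1], length(labs)))
})

test_that("homotopic factor structure shows up in the correlations", {
  pr <- atlas_pairing(synthetic_atlas(20, 5, seed = 2))
  hom <- het <- numeric(0)
  for (s in 1:25) {
    ts <- sample_homotopic_timeseries(
      120, 20, pairing = pr,
      factor_spec = list(homotopic_weight = 0.7, global_weight = 0.2),
      seed = s)
    fc <- unclass(bilateral_average(fc_from_timeseries(ts), pr))
    hom <- c(hom, diag(fc))
    het <- c(het, fc[row(fc) != col(fc)])
  }
  expect_gt(mean(hom), mean(het) + 0.1)

  # zero homotopic weight: homotopic and heterotopic means coincide
  hom0 <- het0 <- numeric(0)
  for (s in 1:25) {
    ts <- sample_homotopic_timeseries(
      120, 20, pairing = pr,
      factor_spec = list(homotopic_weight = 0, global_weight = 0.2),
      seed = s)
    fc <- unclass(bilateral_average(fc_from_timeseries(ts), pr))
    hom0 <- c(hom0, diag(fc))
    het0 <- c(het0, fc[row(fc) != col(fc)])
  }
  expect_lt(abs(mean(hom0) - mean(het0)), 0.03)

  # weight 1, no global factor: homologues are identical series
  ts1 <- sample_homotopic_timeseries(
    60, 6, pairing = atlas_pairing(synthetic_atlas(6, 3, seed = 3)),
    factor_spec = list(homotopic_weight = 1, global_weight = 0), seed = 3)
  expect_equal(cor(ts1[, 1], ts1[, 4]), 1, tolerance = 1e-12)

  # determinism
  expect_identical(sample_homotopic_timeseries(50, 10, seed = 8),
                   sample_homotopic_timeseries(50, 10, seed = 8))
})
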