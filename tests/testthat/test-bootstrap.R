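test_that("p-values are multiples of 1/B on the counting scale", {
  d <- toyDataset(nTF = 3, nGene = 5, n1 = 8, n2 = 8, seed = 17)
  res <- bootstrapPValue(d, B = 7, seed = 1)
  expect_true(pValue(res) %in% ((0:7) / 7))
  res1 <- bootstrapPValue(d, B = 1, seed = 3)
  expect_true(pValue(res1) %in% c(0, 1))
})

test_that("retained replicate statistics recompute the p-value exactly", {
  d <- toyDataset(nTF = 3, nGene = 6, n1 = 10, n2 = 10, seed = 19)
  res <- bootstrapPValue(d, B = 40, seed = 5, retainDistribution = TRUE)
  expect_length(bootstrapStats(res), 40)
  expect_identical(pValue(res),
                   sum(bootstrapStats(res) > kMax(res)) / 40)
  # add-one correction
  resC <- bootstrapPValue(d, B = 40, seed = 5, corrected = TRUE,
                          retainDistribution = TRUE)
  expect_identical(pValue(resC),
                   (1 + sum(bootstrapStats(resC) > kMax(resC))) / 41)
  expect_gt(pValue(resC), 0)
})

test_that("fixed seed gives bit-identical p-values across runs and workers", {
  d <- toyDataset(nTF = 3, nGene = 6, n1 = 12, n2 = 12, seed = 23)
  a <- bootstrapPValue(d, B = 30, seed = 9, retainDistribution = TRUE)
  b <- bootstrapPValue(d, B = 30, seed = 9, retainDistribution = TRUE)
  w <- bootstrapPValue(d, B = 30, seed = 9, nWorkers = 2,
                       retainDistribution = TRUE)
  expect_identical(pValue(a), pValue(b))
  expect_identical(bootstrapStats(a), bootstrapStats(b))
  expect_identical(bootstrapStats(a), bootstrapStats(w))
  expect_false(identical(
    bootstrapStats(bootstrapPValue(d, B = 30, seed = 10,
                                   retainDistribution = TRUE)),
    bootstrapStats(a)))
})

test_that("permutation mode resamples labels without replacement", {
  d <- toyDataset(nTF = 3, nGene = 6, n1 = 10, n2 = 10, seed = 29)
  res <- bootstrapPValue(d, B = 25, seed = 2, method = "permutation",
                         retainDistribution = TRUE)
  expect_true(pValue(res) %in% ((0:25) / 25))
  expect_identical(res@method, "permutation")
  # permutation replicates see every original column exactly once, so
  # the pooled TF correlation matrix is unchanged and replicate spread
  # comes only from relabelling; statistics stay in [-1, 1]
  expect_true(all(bootstrapStats(res) >= -1 & bootstrapStats(res) <= 1))
})

test_that("invalid configuration is rejected", {
  d <- toyDataset()
  expect_error(bootstrapPValue(d, B = 0), "B")
  expect_error(bootstrapPValue(d, B = 2.5), "B")
})
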