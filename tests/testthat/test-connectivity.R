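test_that("identical case and control groups give exactly zero x", {
  set.seed(7)
  half <- matrix(rnorm(8 * 6), 8,
                 dimnames = list(c("TF1", "TF2", paste0("g", 1:6)), NULL))
  v <- cbind(half, half)
  colnames(v) <- paste0("s", 1:12)
  d <- MRExperiment(v, rep(c("case", "ctl"), each = 6),
                    isTF = rep(c(TRUE, FALSE), c(2, 6)))
  expect_identical(unname(differentialConnectivity(d)), c(0, 0))
})

test_that("sign-flipped gene yields the perfect-correlation value 1", {
  tf <- c(1, 2, 3, 1, 2, 3)
  # gene1 tracks the TF exactly in both groups (r = 1, 1);
  # gene2 flips sign between groups (r = -1 vs +1)
  v <- rbind(TF1 = tf, TF2 = tf,
             g1 = tf, g2 = c(-tf[1:3], tf[4:6]))
  colnames(v) <- paste0("s", 1:6)
  d <- MRExperiment(v, rep(c("case", "ctl"), each = 3),
                    isTF = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(differentialConnectivity(d)), c(1, 1))
})

test_that("vectorized x matches the per-pair brute-force computation", {
  d <- toyDataset(nTF = 3, nGene = 5, n1 = 10, n2 = 10, seed = 11)
  expect_equal(differentialConnectivity(d), oracleDiffConnectivity(d),
               tolerance = 1e-12)
  expect_true(all(differentialConnectivity(d) >= 0 &
                    differentialConnectivity(d) <= 2))
})

test_that("pooled TF correlations are absolute, symmetric, unit-diagonal", {
  set.seed(3)
  base <- rnorm(20)
  v <- rbind(TF1 = base, TF2 = 2 * base + 5, TF3 = -base,
             TF4 = rnorm(20), g1 = rnorm(20))
  colnames(v) <- paste0("s", 1:20)
  d <- MRExperiment(v, rep(c("case", "ctl"), each = 10),
                    isTF = c(rep(TRUE, 4), FALSE))
  y <- tfCorrelationMatrix(d)
  expect_equal(y["TF1", "TF2"], 1)  # affine increasing transform
  expect_equal(y["TF1", "TF3"], 1)  # sign flip, absolute value
  expect_identical(unname(diag(y)), rep(1, 4))
  expect_identical(y, t(y))
  d4 <- toyDataset(nTF = 4, nGene = 3, seed = 5)
  expect_equal(tfCorrelationMatrix(d4), oracleTFCor(d4),
               tolerance = 1e-12)
})

test_that("zero-variance features warn and contribute zero correlation", {
  d <- toyDataset(nTF = 2, nGene = 3, n1 = 5, n2 = 5, seed = 2)
  v <- SummarizedExperiment::assay(d, "exprs")
  v["g3", ] <- 7  # constant everywhere
  d2 <- MRExperiment(v, rep(c("case", "control"), each = 5),
                     isTF = isTF(d), caseLevel = "case")
  # one warning per affected within-group correlation pass
  expect_warning(expect_warning(x <- differentialConnectivity(d2), "g3"),
                 "g3")
  # g3's two within-group correlations are both treated as 0
  d3 <- d2[rownames(d2) != "g3", ]
  suppressWarnings(x3 <- differentialConnectivity(d3))
  expect_equal(unname(x), unname(x3 * 2 / 3), tolerance = 1e-12)
})

test_that("groups smaller than 3 samples are rejected", {
  d <- toyDataset(n1 = 2, n2 = 10)
  expect_error(differentialConnectivity(d), "at least 3 samples")
  expect_error(masterRegulatorTest(d, B = 5), "at least 3 samples")
})

test_that("gene order leaves x unchanged; TF order permutes everything", {
  d <- toyDataset(nTF = 4, nGene = 6, seed = 9)
  x <- differentialConnectivity(d)
  k <- kPerTF(masterStatistic(d))
  set.seed(1)
  permGenes <- c(tfNames(d), sample(geneNames(d)))
  dg <- d[permGenes, ]
  expect_identical(differentialConnectivity(dg), x)
  permTFs <- c("TF3", "TF1", "TF4", "TF2")
  dt <- d[c(permTFs, geneNames(d)), ]
  expect_identical(differentialConnectivity(dt), x[permTFs])
  expect_identical(tfCorrelationMatrix(dt),
                   tfCorrelationMatrix(d)[permTFs, permTFs])
  expect_identical(kPerTF(masterStatistic(dt)), k[permTFs])
})
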