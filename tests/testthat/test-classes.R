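test_that("MRExperiment construction validates its invariants", {
  v <- matrix(rnorm(12), 3, dimnames = list(c("TF1", "TF2", "g1"),
                                            paste0("s", 1:4)))
  grp <- c("case", "case", "ctl", "ctl")
  d <- MRExperiment(v, grp, isTF = c(TRUE, TRUE, FALSE))
  expect_s4_class(d, "MRExperiment")
  expect_identical(levels(groupLabels(d)), c("case", "ctl"))
  expect_identical(caseLevel(d), "case")
  expect_identical(tfNames(d), c("TF1", "TF2"))
  expect_identical(geneNames(d), "g1")

  # case level selects the first factor level
  d2 <- MRExperiment(v, grp, isTF = c(TRUE, TRUE, FALSE),
                     caseLevel = "ctl")
  expect_identical(levels(groupLabels(d2)), c("ctl", "case"))

  expect_error(MRExperiment(v, c("a", "b", "c", "a"),
                            c(TRUE, TRUE, FALSE)), "two levels")
  expect_error(MRExperiment(v, rep("case", 4), c(TRUE, TRUE, FALSE)),
               "two levels")
  expect_error(MRExperiment(v, grp, c(TRUE, FALSE, FALSE)),
               "at least 2 features")
  expect_error(MRExperiment(v, grp, c(TRUE, TRUE, TRUE)),
               "non-TF gene")
  vd <- v; rownames(vd) <- c("TF1", "TF1", "g1")
  expect_error(MRExperiment(vd, grp, c(TRUE, TRUE, FALSE)), "duplicate")
})

test_that("missing values are rejected unless explicitly allowed", {
  v <- matrix(rnorm(40), 4, dimnames = list(c("TF1", "TF2", "g1", "g2"),
                                            paste0("s", 1:10)))
  v[1, 1] <- NA
  grp <- rep(c("case", "ctl"), each = 5)
  tf <- c(TRUE, TRUE, FALSE, FALSE)
  expect_error(MRExperiment(v, grp, tf), "allowMissing")
  d <- MRExperiment(v, grp, tf, allowMissing = TRUE)
  x <- differentialConnectivity(d)  # pairwise-complete path
  expect_true(all(is.finite(x)))
  # overlap below the threshold is refused
  v2 <- v; v2[1, 1:8] <- NA
  expect_error(MRExperiment(v2, grp, tf, allowMissing = TRUE),
               "non-missing")
})

test_that("ConnectivityProfile enforces its geometry", {
  expect_error(validObject(new("ConnectivityProfile", x = c(1, 3),
                               y = diag(2), tfIds = c("a", "b"))),
               "\\[0, 2\\]")
  y <- matrix(c(1, 0.2, 0.8, 1), 2)  # asymmetric
  expect_error(validObject(new("ConnectivityProfile", x = c(0.5, 0.2),
                               y = y, tfIds = c("a", "b"))), "symmetric")
  ok <- ConnectivityProfile(c(0.5, 0.2), matrix(c(1, .3, .3, 1), 2),
                            c("a", "b"))
  expect_true(validObject(ok))
})

test_that("MasterRegulatorResult rejects inconsistent slots", {
  d <- toyDataset()
  res <- masterStatistic(d)
  bad <- res
  bad@kMax <- bad@kMax - 0.5
  expect_error(validObject(bad), "exactly")
})

test_that("show methods summarise the key quantities", {
  d <- toyDataset(nTF = 3, nGene = 4)
  expect_output(show(d), "TFs: 3")
  expect_output(show(connectivityProfile(d)), "ConnectivityProfile")
  expect_output(show(masterStatistic(d)), "K = ")
  expect_output(show(bootstrapPValue(d, B = 5, seed = 1)), "p-value")
  expect_output(show(hierarchicalDesign()), "M=10")
  expect_output(show(empiricalSize(nMC = 1, B = 5, r1 = 20, r2 = 20)),
                "size")
})
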