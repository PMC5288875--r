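test_that("canonical design arithmetic follows the delta parameterisation", {
  d0 <- hierarchicalDesign(delta = 0)
  expect_identical(d0@gamma1, d0@gamma2)
  expect_identical(d0@gamma1, 0.5)
  expect_identical(d0@r1i, d0@r2i)
  expect_identical(d0@r1i, 0.45 - 0.05 * (0:8))
  expect_identical(d0@m, c(30L, rep(10L, 6), rep(5L, 3)))
  expect_identical(d0@rho, c(0.95, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1))
  expect_identical(sum(d0@m), d0@N)

  d1 <- hierarchicalDesign(delta = 1)
  expect_identical(d1@gamma1, 0.95)
  expect_identical(unname(d1@r2i), rep(0, 9))

  d6 <- hierarchicalDesign(delta = 0.6)
  expect_equal(d6@r2i[1], 0.4 * 0.45)  # r_22 = 0.18
  expect_equal(d6@gamma1, 0.5 + 0.36 * 0.45)
  expect_error(hierarchicalDesign(delta = 1.2), "delta")
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- simulateDataset(hierarchicalDesign(delta = 0.3, r1 = 15, r2 = 12,
                                          seed = 99))
  b <- simulateDataset(hierarchicalDesign(delta = 0.3, r1 = 15, r2 = 12,
                                          seed = 99))
  c <- simulateDataset(hierarchicalDesign(delta = 0.3, r1 = 15, r2 = 12,
                                          seed = 100))
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(c)))
})

test_that("simulated datasets have the documented layout", {
  des <- hierarchicalDesign(delta = 0.5, r1 = 7, r2 = 5, seed = 1)
  d <- simulateDataset(des)
  expect_s4_class(d, "MRExperiment")
  expect_identical(dim(d), c(115L, 12L))
  expect_identical(sum(isTF(d)), 10L)
  expect_identical(tfNames(d), paste0("TF", 1:10))
  expect_identical(caseLevel(d), "case")
  # case columns first
  expect_identical(as.character(groupLabels(d)),
                   rep(c("case", "control"), c(7, 5)))
})

test_that("null configuration gives identical gene laws in both groups", {
  # equal TF1 means: the marginal gene laws then coincide exactly under
  # delta = 0 (with the canonical mu = 50 / vartheta = 5 shift, genes
  # loading on TF1 inherit the group mean difference even at delta = 0)
  base <- hierarchicalDesign(delta = 0, seed = 77)
  des <- SimulationDesign(M = 10, N = 105, r1 = 1500, r2 = 1500,
                          mu = 0, vartheta = 0, rho = base@rho,
                          m = base@m, gamma1 = 0.5, gamma2 = 0.5,
                          r1i = base@r1i, r2i = base@r2i, delta = 0,
                          seed = 77)
  d <- simulateDataset(des)
  v <- SummarizedExperiment::assay(d, "exprs")
  g <- groupLabels(d) == "case"
  ps <- apply(v[!isTF(d), ], 1L, function(row)
    suppressWarnings(ks.test(row[g], row[!g])$p.value))
  expect_gte(mean(ps > 0.01), 0.98)
})

test_that("two-master stacking preserves each block and their independence", {
  da <- hierarchicalDesign(delta = 0.8, r1 = 400, r2 = 400, seed = 5)
  db <- hierarchicalDesign(delta = 0.8, r1 = 400, r2 = 400, seed = 6)
  d2 <- simulateTwoMasters(da, db)
  expect_identical(dim(d2), c(230L, 800L))
  expect_identical(sum(isTF(d2)), 20L)
  # block A alone is exactly simulateDataset(da)
  expect_identical(
    unname(SummarizedExperiment::assay(d2)[1:115, ]),
    unname(SummarizedExperiment::assay(simulateDataset(da))))
  # cross-block TFs are independent: within-group sample correlations
  # near 0 (pooled correlations are inflated by the shared TF1 group
  # mean shift, which both blocks carry)
  v <- SummarizedExperiment::assay(d2)
  case <- groupLabels(d2) == "case"
  cc <- cor(t(v[c("A_TF1", "A_TF2"), case]),
            t(v[c("B_TF1", "B_TF2"), case]))
  expect_lt(max(abs(cc)), 0.1)
  expect_error(simulateTwoMasters(
    da, hierarchicalDesign(r1 = 10, r2 = 400, seed = 6)), "share r1")
  expect_warning(simulateTwoMasters(da, da), "same seed")
})

test_that("the designed hierarchy appears in the sample correlations", {
  d <- simulateDataset(hierarchicalDesign(delta = 0, r1 = 2000, r2 = 2000,
                                          seed = 8))
  y <- tfCorrelationMatrix(d)
  # rho strictly decreasing => TF1's correlation row decreases in i
  expect_true(all(diff(y["TF1", paste0("TF", 2:10)]) < 0))
})
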