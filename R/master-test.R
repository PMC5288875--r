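# max-concordance statistic and its bootstrap calibration.

.newMRResult <- function(k, pValue = NA_real_, nBootstrap = 0L,
                         bootstrapStats = numeric(0),
                         method = NA_character_, seed = NA_integer_) {
  kMax <- max(k)
  new("MasterRegulatorResult", kPerTF = k, kMax = kMax,
      masterSet = names(k)[abs(k - kMax) <= .mrTieTol],
      pValue = pValue, nBootstrap = as.integer(nBootstrap),
      bootstrapStats = bootstrapStats, method = method,
      seed = as.integer(seed))
}

#' Max-concordance master-regulator statistic
#'
#' Computes the concordance statistic `K_j` for every candidate TF j
#' (its pooled-correlation row against the differential-connectivity
#' vector, via [kendallConcordance()]), the max statistic
#' `K = max_j K_j`, and the argmax set of TFs attaining it.  Tied
#' maximisers are reported together: TFs at the same hierarchy level can
#' legitimately share the maximum.  The p-value slot is left `NA`; run
#' [bootstrapPValue()] (or use [masterRegulatorTest()]) for inference.
#'
#' @param object a [ConnectivityProfile-class] or an
#'   [MRExperiment-class] (profiled on the fly).
#' @return a [MasterRegulatorResult-class] without p-value.
#' @examples
#' pr <- ConnectivityProfile(c(2, 1),
#'                           matrix(c(1, .5, .5, 1), 2),
#'                           c("TF1", "TF2"))
#' masterStatistic(pr)
#' @rdname masterStatistic
#' @export
setMethod("masterStatistic", "ConnectivityProfile", function(object) {
  k <- setNames(.kendallAll(object@x, object@y), object@tfIds)
  .newMRResult(k)
})

#' @rdname masterStatistic
#' @export
setMethod("masterStatistic", "MRExperiment", function(object) {
  masterStatistic(connectivityProfile(object))
})

#' Bootstrap p-value for the max-concordance statistic
#'
#' Draws `B` resamples of size `r1 + r2` from the pooled sample columns
#' (ignoring group labels, the null of exchangeability), labels the first
#' `r1` drawn columns as case and the rest as control, recomputes the full
#' statistic `K_b` on each resample -- differential connectivity, pooled
#' TF correlations and the max concordance are all recomputed -- and
#' returns `p = #\{b : K_b > K\} / B` (strict inequality, so `p` is a
#' multiple of `1/B` and can be exactly 0).
#'
#' @param data the [MRExperiment-class] the observed statistic was
#'   computed on.
#' @param observed a [MasterRegulatorResult-class] from
#'   [masterStatistic()]; computed from `data` when `NULL`.
#' @param B integer, number of resamples (>= 1).
#' @param seed integer seed; all replicate index draws derive from it, so
#'   results are bit-identical across runs and worker counts.
#' @param nWorkers parallelism degree for recomputing replicates
#'   (forked workers via [parallel::mclapply()]; the result does not
#'   depend on it).
#' @param method `"bootstrap"` draws columns with replacement (default);
#'   `"permutation"` shuffles the group labels (without replacement), a
#'   sensitivity-analysis variant.
#' @param corrected use the add-one corrected estimate
#'   `(1 + #\{K_b > K\}) / (1 + B)`, which avoids p = 0; off by default.
#' @param retainDistribution keep the `B` replicate statistics in the
#'   result's `bootstrapStats` slot.
#' @return a [MasterRegulatorResult-class] with the p-value populated.
#' @examples
#' d <- simulateDataset(hierarchicalDesign(delta = 1, r1 = 30, r2 = 30,
#'                                         seed = 1))
#' bootstrapPValue(d, B = 50, seed = 7)
#' @export
bootstrapPValue <- function(data, observed = NULL, B = 500L, seed = 1L,
                            nWorkers = 1L,
                            method = c("bootstrap", "permutation"),
                            corrected = FALSE, retainDistribution = FALSE) {
  method <- match.arg(method)
  B <- .assertCount(B, "B")
  nWorkers <- .assertCount(nWorkers, "nWorkers")
  .checkGroupSizes(data)
  if (is.null(observed)) observed <- masterStatistic(data)
  p <- .statInputs(data)
  n <- ncol(data)
  r1 <- length(p$caseIdx)
  # all replicate index vectors are drawn serially up front from one seed:
  # the per-replicate computation is then deterministic, so any worker
  # count gives the same p-value
  idx <- .withSeed(seed, {
    matrix(replicate(B, sample.int(n, n, replace = (method == "bootstrap"))),
           nrow = n)
  })
  caseRows <- seq_len(r1)
  ctlRows <- (r1 + 1L):n
  oneRep <- function(b) {
    rows <- idx[, b]
    .coreK(p$tTF[rows, , drop = FALSE], p$tG[rows, , drop = FALSE],
           caseRows, ctlRows, p$use)
  }
  kb <- if (nWorkers > 1L) {
    unlist(mclapply(seq_len(B), oneRep, mc.cores = nWorkers))
  } else {
    vapply(seq_len(B), oneRep, numeric(1L))
  }
  exceed <- sum(kb > observed@kMax)
  pv <- if (corrected) (1 + exceed) / (1 + B) else exceed / B
  .newMRResult(observed@kPerTF, pValue = pv, nBootstrap = B,
               bootstrapStats = if (retainDistribution) kb else numeric(0),
               method = method, seed = seed)
}

#' One-call master-regulator test
#'
#' Convenience wrapper: computes the connectivity profile, the
#' max-concordance statistic and its bootstrap p-value.
#'
#' @inheritParams bootstrapPValue
#' @return a [MasterRegulatorResult-class] with p-value.
#' @examples
#' d <- simulateDataset(hierarchicalDesign(delta = 1, r1 = 30, r2 = 30,
#'                                         seed = 1))
#' masterRegulatorTest(d, B = 50, seed = 7)
#' @export
masterRegulatorTest <- function(data, B = 500L, seed = 1L, nWorkers = 1L,
                                method = c("bootstrap", "permutation"),
                                corrected = FALSE,
                                retainDistribution = FALSE) {
  bootstrapPValue(data, masterStatistic(data), B = B, seed = seed,
                  nWorkers = nWorkers, method = method,
                  corrected = corrected,
                  retainDistribution = retainDistribution)
}
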