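# Monte-Carlo drivers: empirical size, power curve, identification.

# Shared engine.  Per-repetition seeds (one for data generation, one for
# the bootstrap) are derived from the master seed up front and do NOT
# depend on delta, so runs at different delta share random numbers --
# powerCurve at delta = 0 is then exactly empiricalSize -- and any
# parallelism degree gives identical results.
.mcRejection <- function(delta, nMC, B, r1, r2, alpha, seed, nWorkers,
                         designFun, retainPValues = TRUE) {
  nMC <- .assertCount(nMC, "nMC")
  B <- .assertCount(B, "B")
  seeds <- .withSeed(seed,
                     matrix(sample.int(.mrSeedMax, 2L * nMC), nrow = 2L))
  oneRep <- function(i) {
    dat <- simulateDataset(designFun(delta = delta, r1 = r1, r2 = r2,
                                     seed = seeds[1L, i]))
    bootstrapPValue(dat, B = B, seed = seeds[2L, i])@pValue
  }
  pv <- if (nWorkers > 1L) {
    unlist(mclapply(seq_len(nMC), oneRep, mc.cores = nWorkers))
  } else {
    vapply(seq_len(nMC), oneRep, numeric(1L))
  }
  est <- mean(pv < alpha)
  new("MonteCarloResult", estimate = est,
      stderr = sqrt(est * (1 - est) / nMC), nMC = nMC, B = B,
      alpha = alpha, delta = delta, seed = as.integer(seed),
      pValues = if (retainPValues) pv else numeric(0))
}

#' Empirical size of the bootstrap max-concordance test
#'
#' Simulates `nMC` independent datasets under the null of the canonical
#' hierarchical design (`delta = 0`: a TF hierarchy exists, but no
#' differential regulation between groups, hence no master regulator in
#' the sense of the test), runs the full bootstrap test on each, and
#' reports the fraction of repetitions with p-value below `alpha`.
#'
#' @param nMC Monte-Carlo repetitions.
#' @param B bootstrap replicates per repetition.
#' @param r1,r2 group sample sizes.
#' @param alpha rejection threshold.
#' @param seed master seed; per-repetition substream seeds are derived
#'   from it, so the estimate is bit-reproducible for any `nWorkers`.
#' @param nWorkers forked workers over repetitions.
#' @param designFun design factory called as
#'   `designFun(delta, r1, r2, seed)`; defaults to
#'   [hierarchicalDesign()].
#' @return a [MonteCarloResult-class] with `delta = 0`.
#' @examples
#' empiricalSize(nMC = 3, B = 20, r1 = 30, r2 = 30, seed = 1)
#' @export
empiricalSize <- function(nMC = 200L, B = 200L, r1 = 200L, r2 = 200L,
                          alpha = 0.05, seed = 1L, nWorkers = 1L,
                          designFun = hierarchicalDesign) {
  .mcRejection(0, nMC, B, r1, r2, alpha, seed, nWorkers, designFun)
}

#' Empirical power curve over delta
#'
#' One size-style Monte-Carlo run per value of `delta` under the
#' canonical alternative (`r2i = (1 - delta) r1i`,
#' `gamma1 = gamma2 + delta^2 r12`).  All runs share per-repetition
#' random numbers (common random numbers across delta), so
#' `powerCurve(0, ...)` reproduces [empiricalSize()] exactly under the
#' same seed and sizes, and the curve is smooth in delta up to
#' Monte-Carlo noise.
#'
#' @param deltas numeric vector of differential-connectivity strengths
#'   in \[0, 1\].
#' @inheritParams empiricalSize
#' @return a list of [MonteCarloResult-class], one per delta (see
#'   [mcResultTable()] to tabulate).
#' @examples
#' pc <- powerCurve(c(0, 1), nMC = 3, B = 20, r1 = 30, r2 = 30, seed = 1)
#' mcResultTable(pc)
#' @export
powerCurve <- function(deltas, nMC = 100L, B = 200L, r1 = 200L,
                       r2 = 200L, alpha = 0.05, seed = 1L,
                       nWorkers = 1L, designFun = hierarchicalDesign) {
  if (any(deltas < 0 | deltas > 1))
    .mrStop("all deltas must lie in [0, 1]")
  lapply(deltas, function(d)
    .mcRejection(d, nMC, B, r1, r2, alpha, seed, nWorkers, designFun))
}

#' Identification accuracy of the argmax rule
#'
#' Fraction of simulated repetitions in which the argmax set is exactly
#' the generative top-of-hierarchy TF (`TF1`).  No bootstrap is run:
#' this isolates the identification step from the existence test.
#'
#' @param delta differential-connectivity strength (> 0 for a designed
#'   master regulator; at `delta = 0` the argmax is diffuse).
#' @inheritParams empiricalSize
#' @return proportion in \[0, 1\].
#' @examples
#' identificationAccuracy(delta = 1, nMC = 5, r1 = 100, r2 = 100, seed = 1)
#' @export
identificationAccuracy <- function(delta, nMC = 50L, r1 = 500L,
                                   r2 = 500L, seed = 1L, nWorkers = 1L,
                                   designFun = hierarchicalDesign) {
  nMC <- .assertCount(nMC, "nMC")
  seeds <- .withSeed(seed, sample.int(.mrSeedMax, nMC))
  oneRep <- function(i) {
    dat <- simulateDataset(designFun(delta = delta, r1 = r1, r2 = r2,
                                     seed = seeds[i]))
    identical(masterStatistic(dat)@masterSet, "TF1")
  }
  hits <- if (nWorkers > 1L) {
    unlist(mclapply(seq_len(nMC), oneRep, mc.cores = nWorkers))
  } else {
    vapply(seq_len(nMC), oneRep, logical(1L))
  }
  mean(hits)
}
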