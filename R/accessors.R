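#' Accessors for MRExperiment
#'
#' @param x an [MRExperiment-class] object.
#' @return `groupLabels` the two-level group factor (case level first);
#'   `isTF` the logical TF flag per feature; `caseLevel` the case label;
#'   `tfNames` / `geneNames` the feature identifiers of TFs / non-TF genes.
#' @name MRExperiment-accessors
NULL

#' @rdname MRExperiment-accessors
#' @export
setMethod("groupLabels", "MRExperiment", function(x) colData(x)$group)
#' @rdname MRExperiment-accessors
#' @export
setMethod("isTF", "MRExperiment", function(x) rowData(x)$isTF)
#' @rdname MRExperiment-accessors
#' @export
setMethod("caseLevel", "MRExperiment", function(x) metadata(x)$caseLevel)
#' @rdname MRExperiment-accessors
#' @export
setMethod("tfNames", "MRExperiment", function(x) rownames(x)[isTF(x)])
#' @rdname MRExperiment-accessors
#' @export
setMethod("geneNames", "MRExperiment", function(x) rownames(x)[!isTF(x)])

setMethod("show", "MRExperiment", function(object) {
  callNextMethod()
  tab <- table(groupLabels(object))
  cat(sprintf("TFs: %d  genes: %d\n", sum(isTF(object)),
              sum(!isTF(object))))
  cat(sprintf("groups: %s (case) n=%d | %s n=%d\n",
              names(tab)[1L], tab[1L], names(tab)[2L], tab[2L]))
})

setMethod("show", "ConnectivityProfile", function(object) {
  cat(sprintf("ConnectivityProfile with %d TFs\n", length(object@x)))
  cat("differential connectivity x (top 5):\n")
  print(head(sort(object@x, decreasing = TRUE), 5L))
})

#' Accessors for MasterRegulatorResult
#'
#' @param object a [MasterRegulatorResult-class].
#' @return `kPerTF` named per-candidate concordance statistics; `kMax`
#'   their maximum K; `masterSet` the TFs attaining it; `pValue` the
#'   bootstrap p-value (`NA` before inference); `nBootstrap` B;
#'   `bootstrapStats` retained replicate statistics.
#' @name MasterRegulatorResult-accessors
NULL

#' @rdname MasterRegulatorResult-accessors
#' @export
setMethod("kPerTF", "MasterRegulatorResult", function(object) object@kPerTF)
#' @rdname MasterRegulatorResult-accessors
#' @export
setMethod("kMax", "MasterRegulatorResult", function(object) object@kMax)
#' @rdname MasterRegulatorResult-accessors
#' @export
setMethod("masterSet", "MasterRegulatorResult",
          function(object) object@masterSet)
#' @rdname MasterRegulatorResult-accessors
#' @export
setMethod("pValue", "MasterRegulatorResult", function(object) object@pValue)
#' @rdname MasterRegulatorResult-accessors
#' @export
setMethod("nBootstrap", "MasterRegulatorResult",
          function(object) object@nBootstrap)
#' @rdname MasterRegulatorResult-accessors
#' @export
setMethod("bootstrapStats", "MasterRegulatorResult",
          function(object) object@bootstrapStats)

setMethod("show", "MasterRegulatorResult", function(object) {
  cat("Master-regulator concordance test\n")
  cat(sprintf("  K = %.4f attained by: %s\n", object@kMax,
              paste(object@masterSet, collapse = ", ")))
  if (is.na(object@pValue)) {
    cat("  p-value: not yet computed (run bootstrapPValue)\n")
  } else {
    cat(sprintf("  %s p-value = %.4g  (B = %d)\n", object@method,
                object@pValue, object@nBootstrap))
  }
})

setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf("SimulationDesign: M=%d TFs, N=%d genes, r1=%d, r2=%d, delta=%.2f\n",
              object@M, object@N, object@r1, object@r2, object@delta))
  cat(sprintf("  gamma1=%.3f gamma2=%.3f seed=%d\n", object@gamma1,
              object@gamma2, object@seed))
})

#' Accessors for MonteCarloResult
#'
#' @param object a [MonteCarloResult-class].
#' @return `estimate` the rejection proportion; `stdError` its binomial
#'   standard error; `mcPValues` the retained per-repetition p-values.
#' @name MonteCarloResult-accessors
NULL

#' @rdname MonteCarloResult-accessors
#' @export
setMethod("estimate", "MonteCarloResult", function(object) object@estimate)
#' @rdname MonteCarloResult-accessors
#' @export
setMethod("stdError", "MonteCarloResult", function(object) object@stderr)
#' @rdname MonteCarloResult-accessors
#' @export
setMethod("mcPValues", "MonteCarloResult", function(object) object@pValues)

setMethod("show", "MonteCarloResult", function(object) {
  kind <- if (object@delta == 0) "empirical size" else
    sprintf("power (delta = %.2f)", object@delta)
  cat(sprintf("Monte-Carlo %s: %.3f (SE %.3f; nMC = %d, B = %d, alpha = %g)\n",
              kind, object@estimate, object@stderr, object@nMC, object@B,
              object@alpha))
})

#' Tabulate Monte-Carlo results
#'
#' @param x a `MonteCarloResult` or a list of them (as returned by
#'   [powerCurve()]).
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return a `data.frame` with columns delta, estimate, stderr, nMC, B,
#'   alpha, seed.
#' @export
as.data.frame.MonteCarloResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(delta = x@delta, estimate = x@estimate, stderr = x@stderr,
             nMC = x@nMC, B = x@B, alpha = x@alpha, seed = x@seed)
}

#' @rdname as.data.frame.MonteCarloResult
#' @param results a list of `MonteCarloResult` objects.
#' @export
mcResultTable <- function(results) {
  if (is(results, "MonteCarloResult")) results <- list(results)
  do.call(rbind, lapply(results, as.data.frame))
}
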