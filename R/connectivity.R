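# core statistics: differential connectivity and the pooled TF hierarchy.

# Extract the pieces the statistic needs once, pre-transposed to
# samples x features (the orientation stats::cor wants), so the
# bootstrap loop never re-touches the S4 container or transposes.
.statInputs <- function(data) {
  g <- groupLabels(data)
  vals <- assay(data, "exprs")
  list(tTF = t(vals[isTF(data), , drop = FALSE]),
       tG = t(vals[!isTF(data), , drop = FALSE]),
       caseIdx = which(g == levels(g)[1L]),
       ctlIdx = which(g == levels(g)[2L]),
       use = if (isTRUE(metadata(data)$allowMissing))
         "pairwise.complete.obs" else "everything")
}

# x_i = (1/N) sum_g | r(TF_i, g | case) - r(TF_i, g | ctl) |
# tTF, tG are samples x features
.diffConnectivity <- function(tTF, tG, caseIdx, ctlIdx,
                              use = "everything") {
  rCase <- .safeCor(tTF[caseIdx, , drop = FALSE],
                    tG[caseIdx, , drop = FALSE], use = use)
  rCtl <- .safeCor(tTF[ctlIdx, , drop = FALSE],
                   tG[ctlIdx, , drop = FALSE], use = use)
  rowMeans(abs(rCase - rCtl))
}

# y_jk = | r(TF_j, TF_k) | over the pooled samples, unit diagonal
.tfCorMatrix <- function(tTF, use = "everything") {
  y <- abs(.safeCor(tTF, use = use))
  diag(y) <- 1
  y
}

# bootstrap hot path: K only, no names, no S4
.coreK <- function(tTF, tG, caseIdx, ctlIdx, use = "everything") {
  max(.kendallAll(
    .diffConnectivity(tTF, tG, caseIdx, ctlIdx, use),
    .tfCorMatrix(tTF, use)))
}

.checkGroupSizes <- function(data, min = 3L) {
  tab <- table(groupLabels(data))
  if (any(tab < min))
    .mrStop("each group needs at least ", min, " samples for within-group ",
            "correlations; got ", paste(tab, collapse = " and "))
  invisible(TRUE)
}

#' Per-TF differential connectivity between case and control
#'
#' For each transcription factor, the mean over all non-TF genes of the
#' absolute difference between its within-case and within-control Pearson
#' correlation with that gene.  Scores lie in \[0, 2\]; large values mean
#' the TF's co-expression with the genes changes between conditions.
#'
#' @param data an [MRExperiment-class] with at least 3 samples per group.
#' @return named numeric vector `x`, one score per TF, in TF row order.
#' @examples
#' d <- simulateDataset(hierarchicalDesign(delta = 1, r1 = 50, r2 = 50,
#'                                         seed = 1))
#' differentialConnectivity(d)
#' @rdname differentialConnectivity
#' @export
setMethod("differentialConnectivity", "MRExperiment", function(data) {
  .checkGroupSizes(data)
  p <- .statInputs(data)
  x <- .diffConnectivity(p$tTF, p$tG, p$caseIdx, p$ctlIdx, p$use)
  setNames(x, tfNames(data))
})

#' Absolute pooled TF-TF correlation matrix
#'
#' Absolute Pearson correlations between every pair of transcription
#' factors, computed on all samples with the two groups pooled.  The
#' diagonal is exactly 1.  Row `j` ranks the other TFs by closeness to
#' TF `j` in the regulatory hierarchy.
#'
#' @param data an [MRExperiment-class] with at least 3 samples in total.
#' @return symmetric M x M numeric matrix `y` with unit diagonal.
#' @rdname tfCorrelationMatrix
#' @export
setMethod("tfCorrelationMatrix", "MRExperiment", function(data) {
  if (ncol(data) < 3L)
    .mrStop("pooled TF correlations need at least 3 samples")
  p <- .statInputs(data)
  y <- .tfCorMatrix(p$tTF, p$use)
  dimnames(y) <- list(tfNames(data), tfNames(data))
  y
})

#' Compute the connectivity profile of a dataset
#'
#' Bundles [differentialConnectivity()] and [tfCorrelationMatrix()] into a
#' [ConnectivityProfile-class], the input to [masterStatistic()].
#'
#' @param data an [MRExperiment-class].
#' @return a `ConnectivityProfile`.
#' @export
connectivityProfile <- function(data) {
  ConnectivityProfile(differentialConnectivity(data),
                      tfCorrelationMatrix(data),
                      tfNames(data))
}
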