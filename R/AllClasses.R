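#' Two-group expression container with transcription-factor annotation
#'
#' `MRExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' the structure the master-regulator test needs: a single numeric assay
#' `exprs` (assumed already normalised / log-scale), a two-level `group`
#' factor on the samples (case level first), and a logical `isTF` flag on
#' the features.  At least two features must be TFs and at least one must
#' be a non-TF gene.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [MRExperiment()] for construction from plain vectors,
#'   [readExpression()] and [attachGroupsAndTFs()] for construction from
#'   delimited files.
#' @export
setClass("MRExperiment", contains = "SummarizedExperiment")

setValidity("MRExperiment", function(object) {
  msg <- character(0)
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  v <- assay(object, "exprs")
  if (!is.numeric(v))
    msg <- c(msg, "assay 'exprs' must be numeric")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature identifiers must be present and unique")
  g <- colData(object)$group
  if (is.null(g) || !is.factor(g) || nlevels(g) != 2L)
    msg <- c(msg, "colData(x)$group must be a two-level factor")
  else if (any(table(g) == 0L))
    msg <- c(msg, "both groups must be non-empty")
  tf <- rowData(object)$isTF
  if (is.null(tf) || !is.logical(tf) || anyNA(tf))
    msg <- c(msg, "rowData(x)$isTF must be logical without NA")
  else {
    if (sum(tf) < 2L)
      msg <- c(msg, "at least 2 features must be flagged as TFs")
    if (sum(!tf) < 1L)
      msg <- c(msg, "at least 1 non-TF gene is required")
  }
  if (anyNA(v) && !isTRUE(metadata(object)$allowMissing))
    msg <- c(msg, "missing values in 'exprs'; rebuild with allowMissing ",
             "= TRUE to use pairwise-complete correlations")
  if (length(msg)) msg else TRUE
})

#' Construct an MRExperiment
#'
#' @param values numeric matrix, features x samples.  Row and column names
#'   are used as feature and sample identifiers; defaults are generated
#'   when absent.
#' @param group character or factor of length `ncol(values)` with exactly
#'   two levels.
#' @param isTF logical of length `nrow(values)` flagging transcription
#'   factors.
#' @param caseLevel which group level is the case group; defaults to the
#'   first level of `factor(group)`.  The choice does not affect the
#'   differential-connectivity statistic (an absolute difference) but fixes
#'   the bootstrap block sizes r1/r2.
#' @param allowMissing allow `NA` values; correlations then use
#'   pairwise-complete observations with a minimum overlap of `minOverlap`
#'   samples per pair.
#' @param minOverlap minimum pairwise-complete sample overlap when
#'   `allowMissing = TRUE`.
#' @return an [MRExperiment-class] object.
#' @examples
#' set.seed(1)
#' v <- matrix(rnorm(5 * 8), 5, dimnames = list(
#'   c("TF1", "TF2", "g1", "g2", "g3"), paste0("s", 1:8)))
#' mre <- MRExperiment(v, rep(c("case", "ctl"), each = 4),
#'                     isTF = c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' mre
#' @export
MRExperiment <- function(values, group, isTF, caseLevel = NULL,
                         allowMissing = FALSE, minOverlap = 3L) {
  if (!is.matrix(values) || !is.numeric(values))
    .mrStop("'values' must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feature_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    .mrStop("duplicate feature identifiers: ",
            paste(unique(rownames(values)[duplicated(rownames(values))]),
                  collapse = ", "))
  if (length(group) != ncol(values))
    .mrStop("length(group) must equal ncol(values)")
  g <- factor(as.character(group))
  if (nlevels(g) != 2L)
    .mrStop("'group' must have exactly two levels, found ", nlevels(g),
            ": ", paste(levels(g), collapse = ", "))
  if (is.null(caseLevel)) caseLevel <- levels(g)[1L]
  if (!caseLevel %in% levels(g))
    .mrStop("caseLevel '", caseLevel, "' is not a group level")
  g <- factor(g, levels = c(caseLevel, setdiff(levels(g), caseLevel)))
  if (length(isTF) != nrow(values) || !is.logical(isTF) || anyNA(isTF))
    .mrStop("'isTF' must be logical of length nrow(values) without NA")
  if (anyNA(values)) {
    if (!allowMissing)
      .mrStop("missing values in 'values'; set allowMissing = TRUE to ",
              "use pairwise-complete correlations")
    .checkOverlap(t(values), t(values), minOverlap)
  }
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    rowData = DataFrame(isTF = isTF, row.names = rownames(values)),
    colData = DataFrame(group = g, row.names = colnames(values)),
    metadata = list(caseLevel = caseLevel, allowMissing = allowMissing,
                    minOverlap = as.integer(minOverlap)))
  new("MRExperiment", se)
}

#' Differential-connectivity profile of the transcription factors
#'
#' Holds the length-M vector `x` of per-TF differential connectivity
#' scores (mean absolute difference of within-group Pearson correlations
#' with every non-TF gene; each score lies in \[0, 2\]) and the M x M
#' matrix `y` of absolute Pearson correlations between TFs computed on the
#' pooled samples (unit diagonal, symmetric).
#'
#' @slot x numeric, per-TF differential connectivity.
#' @slot y numeric matrix, absolute pooled TF-TF correlations.
#' @slot tfIds character, TF identifiers aligned with `x` and `y`.
#' @seealso [connectivityProfile()], [masterStatistic()]
#' @export
setClass("ConnectivityProfile",
         representation(x = "numeric", y = "matrix", tfIds = "character"))

setValidity("ConnectivityProfile", function(object) {
  msg <- character(0)
  m <- length(object@x)
  if (m < 2L) msg <- c(msg, "at least 2 TFs required")
  if (!all(dim(object@y) == c(m, m)))
    msg <- c(msg, "'y' must be an M x M matrix matching length(x)")
  if (length(object@tfIds) != m)
    msg <- c(msg, "'tfIds' must align with 'x'")
  tol <- 1e-8
  if (any(object@x < -tol | object@x > 2 + tol))
    msg <- c(msg, "'x' entries must lie in [0, 2]")
  if (all(dim(object@y) == c(m, m))) {
    if (max(abs(object@y - t(object@y))) > tol)
      msg <- c(msg, "'y' must be symmetric")
    if (any(abs(diag(object@y) - 1) > tol))
      msg <- c(msg, "diag(y) must be 1")
    if (any(object@y < -tol | object@y > 1 + tol))
      msg <- c(msg, "'y' entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ConnectivityProfile from its components
#'
#' Low-level constructor used mainly in tests and examples;
#' [connectivityProfile()] computes a profile from data.
#'
#' @param x,y,tfIds see [ConnectivityProfile-class].
#' @return a `ConnectivityProfile`.
#' @export
ConnectivityProfile <- function(x, y, tfIds = NULL) {
  if (is.null(tfIds))
    tfIds <- if (!is.null(names(x))) names(x) else
      paste0("TF", seq_along(x))
  x <- setNames(as.numeric(x), tfIds)
  dimnames(y) <- list(tfIds, tfIds)
  new("ConnectivityProfile", x = x, y = y, tfIds = tfIds)
}

#' Result of the master-regulator concordance test
#'
#' Per-candidate Kendall concordance statistics `K_j`, their maximum `K`,
#' the set of TFs attaining the maximum (ties are reported together, as
#' co-master regulators), and -- once [bootstrapPValue()] has been run --
#' the bootstrap p-value.
#'
#' @slot kPerTF named numeric, concordance statistic per candidate TF.
#' @slot kMax numeric, `max(kPerTF)`.
#' @slot masterSet character, TFs within tie tolerance of the maximum.
#' @slot pValue numeric, bootstrap p-value; `NA` until inference is run.
#' @slot nBootstrap integer, number of bootstrap replicates B.
#' @slot bootstrapStats numeric, retained replicate statistics K_b
#'   (length 0 unless requested).
#' @slot method character, `"bootstrap"` or `"permutation"`.
#' @slot seed integer, RNG seed used for resampling (`NA` before).
#' @export
setClass("MasterRegulatorResult",
         representation(kPerTF = "numeric", kMax = "numeric",
                        masterSet = "character", pValue = "numeric",
                        nBootstrap = "integer", bootstrapStats = "numeric",
                        method = "character", seed = "integer"))

setValidity("MasterRegulatorResult", function(object) {
  msg <- character(0)
  if (length(object@kPerTF) < 2L)
    msg <- c(msg, "kPerTF must have length >= 2")
  if (any(object@kPerTF < -1 - 1e-12 | object@kPerTF > 1 + 1e-12))
    msg <- c(msg, "all K_j must lie in [-1, 1]")
  if (length(object@kMax) != 1L || object@kMax != max(object@kPerTF))
    msg <- c(msg, "kMax must equal max(kPerTF) exactly")
  tied <- names(object@kPerTF)[
    abs(object@kPerTF - max(object@kPerTF)) <= .mrTieTol]
  if (!setequal(object@masterSet, tied))
    msg <- c(msg, "masterSet must be exactly the TFs tied at the maximum")
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Simulation design for the hierarchical two-group generative model
#'
#' Parameters of the three-layer generative scheme: a top factor TF1 with
#' group means `mu` (case) and `vartheta` (control) and unit variance;
#' downstream factors `TF_i = (rho_i TF1 + V_i) / sqrt(1 + rho_i^2)` with
#' `rho` strictly decreasing (the regulatory hierarchy); and gene blocks of
#' sizes `m` (summing to N) loaded on TF1 with coefficient `gamma1` /
#' `gamma2` (case/control) or on the idiosyncratic factor `V_i` with
#' coefficients `r1i` / `r2i`.  `delta` in \[0, 1\] indexes the
#' differential-connectivity strength in the canonical parameterisation
#' (see [hierarchicalDesign()]); `delta = 0` is the null.
#'
#' @slot M,N integer, number of TFs and of non-TF genes.
#' @slot r1,r2 integer, case and control sample sizes.
#' @slot mu,vartheta numeric, TF1 means in case and control.
#' @slot rho numeric length M-1, hierarchy coefficients for TF2..TFM,
#'   strictly decreasing, in (0, 1].
#' @slot m integer length M, genes per TF block; `sum(m) == N`.
#' @slot gamma1,gamma2 numeric, TF1-to-gene loadings in case/control.
#' @slot r1i,r2i numeric length M-1, V_i-to-gene loadings in case/control.
#' @slot delta numeric in \[0, 1\].
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationDesign",
         representation(M = "integer", N = "integer", r1 = "integer",
                        r2 = "integer", mu = "numeric",
                        vartheta = "numeric", rho = "numeric",
                        m = "integer", gamma1 = "numeric",
                        gamma2 = "numeric", r1i = "numeric",
                        r2i = "numeric", delta = "numeric",
                        seed = "integer"))

setValidity("SimulationDesign", function(object) {
  msg <- character(0)
  if (object@M < 2L) msg <- c(msg, "M >= 2 required")
  if (object@N < 1L) msg <- c(msg, "N >= 1 required")
  if (object@r1 < 1L || object@r2 < 1L)
    msg <- c(msg, "r1 and r2 must be >= 1")
  if (length(object@rho) != object@M - 1L)
    msg <- c(msg, "rho must have length M - 1")
  else {
    if (any(object@rho <= 0 | object@rho > 1))
      msg <- c(msg, "rho entries must lie in (0, 1]")
    if (object@M > 2L && any(diff(object@rho) >= 0))
      msg <- c(msg, "rho must be strictly decreasing")
  }
  if (length(object@m) != object@M)
    msg <- c(msg, "m must have length M")
  else {
    if (any(object@m < 1L)) msg <- c(msg, "all block sizes m_i must be >= 1")
    if (sum(object@m) != object@N) msg <- c(msg, "sum(m) must equal N")
  }
  if (length(object@r1i) != object@M - 1L ||
      length(object@r2i) != object@M - 1L)
    msg <- c(msg, "r1i and r2i must have length M - 1")
  if (object@delta < 0 || object@delta > 1)
    msg <- c(msg, "delta must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Monte-Carlo size / power estimate
#'
#' The rejection proportion `estimate = mean(pValues < alpha)` over `nMC`
#' independent simulated datasets, each tested with `B` bootstrap
#' replicates, together with its binomial standard error.
#'
#' @slot estimate numeric rejection proportion in \[0, 1\].
#' @slot stderr numeric, `sqrt(estimate * (1 - estimate) / nMC)`.
#' @slot nMC,B integer, repetitions and bootstrap replicates.
#' @slot alpha numeric rejection threshold.
#' @slot delta numeric, design delta (0 for the size study).
#' @slot seed integer master seed.
#' @slot pValues numeric, retained per-repetition p-values.
#' @export
setClass("MonteCarloResult",
         representation(estimate = "numeric", stderr = "numeric",
                        nMC = "integer", B = "integer", alpha = "numeric",
                        delta = "numeric", seed = "integer",
                        pValues = "numeric"))

setValidity("MonteCarloResult", function(object) {
  msg <- character(0)
  if (object@estimate < 0 || object@estimate > 1)
    msg <- c(msg, "estimate must lie in [0, 1]")
  if (length(object@pValues) &&
      object@estimate != mean(object@pValues < object@alpha))
    msg <- c(msg, "estimate must equal mean(pValues < alpha) exactly")
  if (length(msg)) msg else TRUE
})
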