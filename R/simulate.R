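# hierarchical latent-factor generator for two-group expression data.

#' Construct a SimulationDesign
#'
#' @param M,N number of TFs / non-TF genes.
#' @param r1,r2 case / control sample sizes.
#' @param mu,vartheta TF1 group means (variance is 1 in both groups).
#' @param rho length M-1 strictly decreasing hierarchy coefficients in
#'   (0, 1] for TF2..TFM.
#' @param m length-M gene-block sizes, `sum(m) == N`; blocks are
#'   consecutive runs of rows, block i regulated by TF i.
#' @param gamma1,gamma2 TF1-to-gene loadings (case / control) for block 1.
#' @param r1i,r2i length M-1 loadings of blocks 2..M on their own latent
#'   factor V_i (case / control).
#' @param delta differential-connectivity index in \[0, 1\]; purely
#'   descriptive here (stored for bookkeeping), but tied to the loadings
#'   by [hierarchicalDesign()].
#' @param seed RNG seed for [simulateDataset()].
#' @return a [SimulationDesign-class].
#' @export
SimulationDesign <- function(M, N, r1, r2, mu, vartheta, rho, m,
                             gamma1, gamma2, r1i, r2i, delta = 0,
                             seed = 1L) {
  new("SimulationDesign", M = as.integer(M), N = as.integer(N),
      r1 = as.integer(r1), r2 = as.integer(r2), mu = as.numeric(mu),
      vartheta = as.numeric(vartheta), rho = as.numeric(rho),
      m = as.integer(m), gamma1 = as.numeric(gamma1),
      gamma2 = as.numeric(gamma2), r1i = as.numeric(r1i),
      r2i = as.numeric(r2i), delta = as.numeric(delta),
      seed = as.integer(seed))
}

#' The canonical 10-TF / 105-gene benchmark design
#'
#' The parameterisation used throughout the size and power studies:
#' M = 10 TFs, N = 105 genes in blocks m = (30, 10, 10, 10, 10, 10, 10,
#' 5, 5, 5), TF1 means mu = 50 (case) and vartheta = 5 (control),
#' hierarchy rho = (0.95, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1),
#' gamma2 = 0.5, case loadings r1i descending from r12 = 0.45 in steps of
#' 0.05, and the delta-parameterised alternative
#' `r2i = (1 - delta) * r1i`, `gamma1 = gamma2 + delta^2 * r12`.
#' `delta = 0` gives the null (gamma1 = gamma2, r1i = r2i: no
#' differential regulation); `delta = 1` the maximal alternative
#' (gamma1 = 0.95, r2i = 0).
#'
#' @param delta differential-connectivity strength in \[0, 1\].
#' @param r1,r2 group sample sizes.
#' @param seed RNG seed.
#' @return a [SimulationDesign-class].
#' @examples
#' hierarchicalDesign(delta = 0.6)@gamma1  # 0.5 + 0.36 * 0.45
#' @export
hierarchicalDesign <- function(delta = 0, r1 = 500L, r2 = 500L,
                               seed = 1L) {
  if (length(delta) != 1L || is.na(delta) || delta < 0 || delta > 1)
    .mrStop("delta must be a single value in [0, 1]")
  r1i <- 0.45 - 0.05 * (0:8)
  SimulationDesign(
    M = 10L, N = 105L, r1 = r1, r2 = r2, mu = 50, vartheta = 5,
    rho = c(0.95, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1),
    m = c(30L, 10L, 10L, 10L, 10L, 10L, 10L, 5L, 5L, 5L),
    gamma1 = 0.5 + delta^2 * 0.45, gamma2 = 0.5,
    r1i = r1i, r2i = (1 - delta) * r1i,
    delta = delta, seed = seed)
}

# one group's block of the generative model; fixed draw order
# (TF1, V, block-1 eps, block-i eps in order) for reproducibility
.simGroup <- function(d, case) {
  r <- if (case) d@r1 else d@r2
  tf1 <- rnorm(r, if (case) d@mu else d@vartheta, 1)
  v <- matrix(rnorm((d@M - 1L) * r), nrow = d@M - 1L)
  tfs <- rbind(tf1,
               (d@rho * matrix(tf1, d@M - 1L, r, byrow = TRUE) + v) /
                 sqrt(1 + d@rho^2))
  gamma <- if (case) d@gamma1 else d@gamma2
  ri <- if (case) d@r1i else d@r2i
  genes <- matrix(0, d@N, r)
  genes[seq_len(d@m[1L]), ] <-
    matrix(tf1 * gamma, d@m[1L], r, byrow = TRUE) +
    matrix(rnorm(d@m[1L] * r), d@m[1L], r)
  off <- d@m[1L]
  for (i in 2:d@M) {
    rows <- off + seq_len(d@m[i])
    genes[rows, ] <-
      matrix(v[i - 1L, ] * ri[i - 1L], d@m[i], r, byrow = TRUE) +
      matrix(rnorm(d@m[i] * r), d@m[i], r)
    off <- off + d@m[i]
  }
  rbind(tfs, genes)
}

#' Simulate a two-group expression dataset under the hierarchical model
#'
#' Per subject: the top factor `TF1 ~ N(mu, 1)` in the case group,
#' `N(vartheta, 1)` in the control group; independent `V_i ~ N(0, 1)` for
#' i = 2..M; downstream TFs `TF_i = (rho_i TF1 + V_i) / sqrt(1 + rho_i^2)`
#' so that `Corr(TF1, TF_i) = rho_i / sqrt(1 + rho_i^2)` decreases in i
#' (the hierarchy).  The first `m[1]` genes load on TF1
#' (`g = gamma * TF1 + eps`, gamma group-specific); block i loads on `V_i`
#' (`g = r_i * V_i + eps`, r group-specific); all noise is standard
#' normal.  Case columns come first; generation is bit-reproducible from
#' `design@seed`.
#'
#' @param design a [SimulationDesign-class].
#' @return an [MRExperiment-class] with features `TF1..TFM, g1..gN` and
#'   group labels `case` / `control`.
#' @examples
#' d <- simulateDataset(hierarchicalDesign(delta = 0.6, r1 = 20, r2 = 20,
#'                                         seed = 42))
#' d
#' @export
simulateDataset <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  validObject(design)
  vals <- .withSeed(design@seed,
                    cbind(.simGroup(design, TRUE),
                          .simGroup(design, FALSE)))
  rownames(vals) <- c(paste0("TF", seq_len(design@M)),
                      paste0("g", seq_len(design@N)))
  colnames(vals) <- c(paste0("case_", seq_len(design@r1)),
                      paste0("ctl_", seq_len(design@r2)))
  MRExperiment(vals,
               group = rep(c("case", "control"),
                           c(design@r1, design@r2)),
               isTF = rep(c(TRUE, FALSE), c(design@M, design@N)),
               caseLevel = "case")
}

#' Simulate two independent master regulators over the same subjects
#'
#' Stacks two independently generated feature blocks (disjoint TF sets
#' and gene sets, independent latent factors) over one cohort of
#' subjects, emulating a system with two master regulators each at the
#' top of its own regulatory hierarchy.  Feature identifiers are prefixed
#' `A_` and `B_`.
#'
#' @param designA,designB [SimulationDesign-class] objects with equal
#'   `r1` and `r2`; each block uses its own seed.
#' @return an [MRExperiment-class] with `M_A + M_B` TFs and
#'   `N_A + N_B` genes.
#' @export
simulateTwoMasters <- function(designA, designB) {
  if (designA@r1 != designB@r1 || designA@r2 != designB@r2)
    .mrStop("the two designs must share r1 and r2")
  if (designA@seed == designB@seed)
    warning("designA and designB use the same seed; the two blocks will ",
            "be identical rather than independent", call. = FALSE)
  a <- simulateDataset(designA)
  b <- simulateDataset(designB)
  vals <- rbind(assay(a, "exprs"), assay(b, "exprs"))
  rownames(vals) <- c(paste0("A_", rownames(a)), paste0("B_", rownames(b)))
  MRExperiment(vals,
               group = as.character(groupLabels(a)),
               isTF = c(isTF(a), isTF(b)),
               caseLevel = caseLevel(a))
}
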