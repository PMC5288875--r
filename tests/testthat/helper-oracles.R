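# Independent brute-force oracles and small fixture builders.  The
# oracles deliberately share no code with the package internals.

# Kendall concordance by explicit enumeration of all unordered pairs:
# concordant +1, discordant -1, ties (product 0) neither; fixed
# denominator m(m-1)/2.
oracleKendall <- function(x, yj) {
  m <- length(x)
  nc <- nd <- 0L
  for (i in seq_len(m - 1L)) {
    for (k in (i + 1L):m) {
      prod <- (x[i] - x[k]) * (yj[i] - yj[k])
      if (prod > 0) nc <- nc + 1L
      if (prod < 0) nd <- nd + 1L
    }
  }
  (nc - nd) / (m * (m - 1) / 2)
}

# Eq.-by-eq differential connectivity: per TF, per gene, per group, one
# stats::cor call each.
oracleDiffConnectivity <- function(data) {
  v <- SummarizedExperiment::assay(data, "exprs")
  g <- groupLabels(data)
  caseIdx <- g == levels(g)[1L]
  tfs <- tfNames(data)
  genes <- geneNames(data)
  sapply(tfs, function(tf) {
    mean(sapply(genes, function(gn) {
      abs(cor(v[tf, caseIdx], v[gn, caseIdx]) -
            cor(v[tf, !caseIdx], v[gn, !caseIdx]))
    }))
  })
}

# pairwise pooled absolute TF correlations, one cor call per pair
oracleTFCor <- function(data) {
  v <- SummarizedExperiment::assay(data, "exprs")
  tfs <- tfNames(data)
  m <- length(tfs)
  y <- diag(m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (j != k) y[j, k] <- abs(cor(v[tfs[j], ], v[tfs[k], ]))
    }
  }
  dimnames(y) <- list(tfs, tfs)
  y
}

# small random dataset: nTF TFs, nGene genes, n1 + n2 samples
toyDataset <- function(nTF = 3L, nGene = 5L, n1 = 10L, n2 = 10L,
                       seed = 1L) {
  set.seed(seed)
  v <- matrix(rnorm((nTF + nGene) * (n1 + n2)), nTF + nGene,
              dimnames = list(c(paste0("TF", seq_len(nTF)),
                                paste0("g", seq_len(nGene))),
                              paste0("s", seq_len(n1 + n2))))
  MRExperiment(v, rep(c("case", "control"), c(n1, n2)),
               isTF = rep(c(TRUE, FALSE), c(nTF, nGene)),
               caseLevel = "case")
}
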