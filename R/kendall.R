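# Kendall concordance with the tau-a denominator.

# K_j for every row j of y against x, sharing the sign matrix of x.
# A pair (i, k) is concordant when (x_i - x_k)(y_ji - y_jk) > 0,
# discordant when < 0; ties count toward neither.  Denominator is fixed
# at n0 = M(M-1)/2 (no tie correction).
.kendallAll <- function(x, y) {
  m <- length(x)
  ut <- upper.tri(matrix(0, m, m))
  dx <- sign(outer(x, x, "-"))[ut]
  n0 <- m * (m - 1) / 2
  vapply(seq_len(m), function(j) {
    dy <- sign(outer(y[j, ], y[j, ], "-"))[ut]
    sum(dx * dy) / n0
  }, numeric(1L))
}

#' Kendall concordance between differential connectivity and one TF's
#' correlation ranking
#'
#' Tau-a style concordance over the M paired observations
#' `(x_1, y_j1), ..., (x_M, y_jM)` -- note the pair for TF j itself, with
#' `y_jj = 1`, is included.  Over all `n0 = M(M-1)/2` unordered index
#' pairs, concordant pairs count +1, discordant -1, ties 0, and the sum is
#' divided by the fixed denominator `n0`, giving a value in \[-1, 1\].
#'
#' @param x numeric length-M differential-connectivity vector.
#' @param yJ numeric length-M row of the pooled TF correlation matrix for
#'   the candidate master TF j (including the diagonal element 1).
#' @return scalar concordance statistic `K_j`.
#' @examples
#' kendallConcordance(c(3, 2, 1), c(1, 0.9, 0.5))  # +1, fully concordant
#' kendallConcordance(c(1, 2, 3), c(1, 0.9, 0.5))  # -1, fully discordant
#' @export
kendallConcordance <- function(x, yJ) {
  if (length(x) != length(yJ))
    .mrStop("x and yJ must have the same length")
  if (length(x) < 2L)
    .mrStop("at least 2 TFs are required")
  if (anyNA(x) || anyNA(yJ))
    .mrStop("x and yJ must not contain NA")
  m <- length(x)
  ut <- upper.tri(matrix(0, m, m))
  dx <- sign(outer(x, x, "-"))[ut]
  dy <- sign(outer(yJ, yJ, "-"))[ut]
  sum(dx * dy) / (m * (m - 1) / 2)
}
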