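# Internal helpers shared across modules.

# largest admissible seed (R integer range)
.mrSeedMax <- 2147483646L

# tie tolerance when collecting the argmax set; K_j values are rationals
# with denominator M(M-1)/2, so exact equality is the norm and the
# tolerance only absorbs float noise
.mrTieTol <- 1e-10

# validation failure with a dedicated condition class so the CLI can map
# it to exit code 2
.mrStop <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("mrValidationError", "error", "condition")))
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != as.integer(x))
    .mrStop(name, " must be a single integer >= ", min)
  as.integer(x)
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Pearson correlation between columns, with the zero-variance policy: a
# feature constant over the relevant samples has no defined correlation,
# which we set to 0 (it carries no connectivity signal) with a warning
# naming the feature.  `use` switches to pairwise-complete when the
# dataset was loaded with allowMissing = TRUE.
.safeCor <- function(x, y = NULL, use = "everything") {
  r <- suppressWarnings(cor(x, y, use = use))
  if (anyNA(r)) {
    bad <- colnames(x)[apply(x, 2L, function(v) sd(v, na.rm = TRUE) == 0)]
    if (!is.null(y))
      bad <- c(bad, colnames(y)[apply(y, 2L, function(v)
        sd(v, na.rm = TRUE) == 0)])
    bad <- unique(bad[!is.na(bad)])
    if (length(bad))
      warning("zero-variance feature(s); correlations involving them set ",
              "to 0: ", paste(bad, collapse = ", "), call. = FALSE)
    r[is.na(r)] <- 0
  }
  r
}

# minimum pairwise-complete overlap guard for missing-data correlations
.checkOverlap <- function(x, y, minOverlap) {
  ok <- crossprod(!is.na(x), !is.na(y))
  if (any(ok < minOverlap))
    .mrStop("pairwise-complete correlation requires at least ", minOverlap,
            " shared non-missing samples for every feature pair; ",
            sum(ok < minOverlap), " pair(s) fall short")
  invisible(TRUE)
}
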