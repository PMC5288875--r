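# Delimited-text input/output, validation, the convenience pre-filter
# and the JSON analysis report.

.sepFor <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Expects features as rows, a header row of sample identifiers and the
#' feature identifier in the first column (tab-separated by default,
#' comma for `.csv`).  Use `transposed = TRUE` for samples-as-rows files.
#' Duplicate feature identifiers and non-numeric cells are rejected with
#' messages naming the offenders.
#'
#' @param path file path.
#' @param transposed the file stores samples as rows.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs` (group labels and TF flags not yet attached; see
#'   [attachGroupsAndTFs()]).
#' @export
readExpression <- function(path, transposed = FALSE, sep = NULL) {
  if (!file.exists(path)) .mrStop("file not found: ", path)
  df <- read.delim(path, sep = .sepFor(path, sep), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    .mrStop("duplicate feature identifiers in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad))
        .mrStop("non-numeric value '", v[bad[1L]], "' at feature '",
                ids[bad[1L]], "', column '", names(body)[j], "'")
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  if (transposed) {
    mat <- t(mat)
    if (anyDuplicated(rownames(mat)))
      .mrStop("duplicate feature identifiers after transposition: ",
              paste(unique(rownames(mat)[duplicated(rownames(mat))]),
                    collapse = ", "))
  }
  SummarizedExperiment(assays = list(exprs = mat))
}

#' Write an expression matrix, group labels, or a TF list
#'
#' `writeExpression` writes the features-x-samples matrix with a header
#' of sample identifiers and feature identifiers in the first column.
#' `writeGroups` writes the two-column (sample, group) file and
#' `writeTFs` the one-column TF identifier list, the formats
#' [attachGroupsAndTFs()] reads back.
#'
#' @param data an [MRExperiment-class] (or any `SummarizedExperiment`
#'   with an `exprs` assay for `writeExpression`).
#' @param path output file; `.csv` switches to comma separation.
#' @param sep field separator override.
#' @return the path, invisibly.
#' @export
writeExpression <- function(data, path, sep = NULL) {
  mat <- assay(data, "exprs")
  # 17 significant digits round-trip doubles exactly
  chr <- matrix(sprintf("%.17g", mat), nrow(mat),
                dimnames = dimnames(mat))
  df <- data.frame(feature_id = rownames(mat), chr, check.names = FALSE)
  write.table(df, path, sep = .sepFor(path, sep), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpression
#' @export
writeGroups <- function(data, path, sep = NULL) {
  df <- data.frame(sample_id = colnames(data),
                   group = as.character(groupLabels(data)))
  write.table(df, path, sep = .sepFor(path, sep), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeExpression
#' @export
writeTFs <- function(data, path) {
  writeLines(tfNames(data), path)
  invisible(path)
}

#' Attach group labels and TF annotation to an expression matrix
#'
#' @param data a `SummarizedExperiment` from [readExpression()].
#' @param groupsPath two-column delimited file (no header): sample
#'   identifier, group label.  Exactly two label levels; every sample in
#'   the matrix must be labelled.
#' @param tfsPath one feature identifier per line; all must be rows of
#'   the matrix.
#' @param caseLevel which group level is the case group; defaults to the
#'   first level alphabetically.
#' @param allowMissing,minOverlap see [MRExperiment()].
#' @return a fully validated [MRExperiment-class].
#' @export
attachGroupsAndTFs <- function(data, groupsPath, tfsPath,
                               caseLevel = NULL, allowMissing = FALSE,
                               minOverlap = 3L) {
  if (!file.exists(groupsPath)) .mrStop("file not found: ", groupsPath)
  if (!file.exists(tfsPath)) .mrStop("file not found: ", tfsPath)
  gdf <- read.delim(groupsPath, sep = .sepFor(groupsPath, NULL),
                    header = FALSE, stringsAsFactors = FALSE)
  if (ncol(gdf) < 2L)
    .mrStop("groups file must have two columns: sample_id, group")
  labels <- setNames(as.character(gdf[[2L]]), as.character(gdf[[1L]]))
  missing <- setdiff(colnames(data), names(labels))
  if (length(missing))
    .mrStop("unlabelled sample(s): ", paste(missing, collapse = ", "))
  group <- labels[colnames(data)]
  lev <- unique(group)
  if (length(lev) != 2L)
    .mrStop("exactly two group levels required, found ", length(lev),
            ": ", paste(lev, collapse = ", "))
  tfs <- readLines(tfsPath)
  tfs <- tfs[nzchar(tfs)]
  if (!length(tfs)) .mrStop("TF list is empty")
  unknown <- setdiff(tfs, rownames(data))
  if (length(unknown))
    .mrStop("TF identifier(s) not in the matrix: ",
            paste(unknown, collapse = ", "))
  MRExperiment(assay(data, "exprs"), group = group,
               isTF = rownames(data) %in% tfs, caseLevel = caseLevel,
               allowMissing = allowMissing, minOverlap = minOverlap)
}

#' Generic differential-expression pre-filter (Welch t + BH)
#'
#' Convenience plumbing only: retains features whose per-feature Welch
#' two-sample t-test, Benjamini-Hochberg adjusted across features, falls
#' below `alphaFdr`.  This is an explicitly generic substitute for the
#' moderated (limma-style) filtering used in published microarray
#' workflows -- it is NOT equivalent to them, and feature counts on real
#' data will differ.  The master-regulator test itself does not require
#' pre-filtering.
#'
#' @param data an [MRExperiment-class] with at least 2 samples per group.
#' @param alphaFdr BH-adjusted significance threshold; `alphaFdr >= 1`
#'   retains everything.
#' @return the filtered [MRExperiment-class]; errors if fewer than 2 TFs
#'   or 1 gene would remain (advice: skip pre-filtering).
#' @export
prefilterFeatures <- function(data, alphaFdr = 0.05) {
  tab <- table(groupLabels(data))
  if (any(tab < 2L))
    .mrStop("prefilter needs at least 2 samples per group")
  if (alphaFdr >= 1) return(data)
  v <- assay(data, "exprs")
  case <- groupLabels(data) == levels(groupLabels(data))[1L]
  n1 <- sum(case); n2 <- sum(!case)
  m1 <- rowMeans(v[, case, drop = FALSE])
  m2 <- rowMeans(v[, !case, drop = FALSE])
  s1 <- rowSums((v[, case, drop = FALSE] - m1)^2) / (n1 - 1)
  s2 <- rowSums((v[, !case, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- s1 / n1 + s2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1  # zero variance in both groups, equal means
  keep <- p.adjust(p, "BH") < alphaFdr
  if (sum(keep & isTF(data)) < 2L)
    .mrStop("pre-filtering would leave fewer than 2 TFs (",
            sum(keep & isTF(data)), " retained); run without --prefilter")
  if (sum(keep & !isTF(data)) < 1L)
    .mrStop("pre-filtering would remove every non-TF gene; ",
            "run without --prefilter")
  message(sprintf("prefilter: retained %d of %d features (%d TFs, %d genes)",
                  sum(keep), length(keep), sum(keep & isTF(data)),
                  sum(keep & !isTF(data))))
  data[keep, ]
}

#' JSON analysis report
#'
#' `analysisReport` assembles a serialisable record of a test run:
#' input file paths with MD5 checksums, dataset dimensions, group sizes,
#' the full result (per-TF statistics, max, argmax set, p-value, B,
#' method, seed) and software version.  `writeReport` / `readReport`
#' round-trip it through JSON losslessly (full double precision).
#'
#' @param result a [MasterRegulatorResult-class].
#' @param data the [MRExperiment-class] tested.
#' @param files optional named character vector of input paths to
#'   checksum.
#' @return `analysisReport`: a nested list; `readReport`: that list back
#'   from disk.
#' @export
analysisReport <- function(result, data, files = NULL) {
  inputs <- if (length(files)) {
    lapply(seq_along(files), function(i)
      list(path = unname(files[i]),
           md5 = unname(tools::md5sum(files[i]))))
  } else list()
  list(
    inputs = inputs,
    m_tf = sum(isTF(data)),
    n_gene = sum(!isTF(data)),
    group_sizes = as.list(setNames(as.integer(table(groupLabels(data))),
                                   levels(groupLabels(data)))),
    case_level = caseLevel(data),
    result = list(
      k_per_tf = as.list(kPerTF(result)),
      k_max = kMax(result),
      master_set = as.list(masterSet(result)),
      p_value = if (is.na(pValue(result))) NULL else pValue(result),
      n_bootstrap = nBootstrap(result),
      method = result@method,
      seed = result@seed),
    software = list(package = "MRconcord",
                    version = as.character(packageVersion("MRconcord"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @rdname analysisReport
#' @param report a list from `analysisReport`.
#' @param path JSON file path.
#' @export
writeReport <- function(report, path) {
  # 17 significant digits make the double round-trip lossless
  write_json(report, path, auto_unbox = TRUE, digits = I(17),
             null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname analysisReport
#' @export
readReport <- function(path) {
  read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
            simplifyMatrix = FALSE)
}
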