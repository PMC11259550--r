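#' Read / write beta and expression matrices as TSV
#'
#' Matrices are stored probes (or genes) in rows, samples in columns, with a
#' header row of sample ids and the row id in the first column (`probe` /
#' `gene`).
#'
#' @param path TSV file path.
#' @param ms a [MethylSet-class] or plain matrix (for writers).
#' @return `readBetaMatrix` returns a numeric matrix with dimnames;
#'   `writeBetaMatrix` returns `path` invisibly.
#' @export
readBetaMatrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' @rdname readBetaMatrix
#' @export
writeBetaMatrix <- function(ms, path) {
  m <- if (is(ms, "SummarizedExperiment")) betaValues(ms) else as.matrix(ms)
  dt <- data.table::data.table(probe = rownames(m), m)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname readBetaMatrix
#' @export
readExpressionMatrix <- readBetaMatrix

#' @rdname readBetaMatrix
#' @param expr expression matrix, genes x samples.
#' @export
writeExpressionMatrix <- function(expr, path) {
  dt <- data.table::data.table(gene = rownames(expr), expr)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write sample metadata and probe annotation as CSV
#'
#' Sample tables are keyed by a `sample` column, probe annotation by a
#' `probe` column; `readProbeAnnotation` checks the required annotation
#' columns (`chrom`, `pos`, `islandClass`, `featureClass`) and validates
#' the class enumerations.
#'
#' @param path CSV file path.
#' @param df data.frame to write (row names become the key column).
#' @return readers return a data.frame with the key column as row names.
#' @export
readSampleTable <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!"sample" %in% colnames(df)) stop("sample table needs a 'sample' column")
  rownames(df) <- df$sample
  df[, setdiff(colnames(df), "sample"), drop = FALSE]
}

#' @rdname readSampleTable
#' @export
writeSampleTable <- function(df, path) {
  out <- data.table::data.table(sample = rownames(df), df)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname readSampleTable
#' @export
readProbeAnnotation <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  req <- c("probe", "chrom", "pos", "islandClass", "featureClass")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("probe annotation missing columns: ", paste(miss, collapse = ", "))
  if (any(df$pos < 1, na.rm = TRUE)) stop("positions must be 1-based (>= 1)")
  badI <- setdiff(stats::na.omit(unique(df$islandClass)), ISLAND_CLASSES)
  badF <- setdiff(stats::na.omit(unique(df$featureClass)), FEATURE_CLASSES)
  if (length(badI)) stop("unknown islandClass values: ", paste(badI, collapse = ", "))
  if (length(badF)) stop("unknown featureClass values: ", paste(badF, collapse = ", "))
  rownames(df) <- df$probe
  df[, setdiff(colnames(df), "probe"), drop = FALSE]
}

#' @rdname readSampleTable
#' @export
writeProbeAnnotation <- function(df, path) {
  out <- data.table::data.table(probe = rownames(df), df)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Assemble a MethylSet from files on disk
#'
#' @param betaPath beta TSV (see [readBetaMatrix()]).
#' @param samplePath sample CSV (see [readSampleTable()]).
#' @param annotPath optional probe annotation CSV.
#' @return a [MethylSet-class].
#' @export
readMethylSet <- function(betaPath, samplePath, annotPath = NULL) {
  beta <- readBetaMatrix(betaPath)
  sdf <- readSampleTable(samplePath)
  sdf <- sdf[colnames(beta), , drop = FALSE]
  ann <- if (!is.null(annotPath)) {
    a <- readProbeAnnotation(annotPath)
    a[rownames(beta), , drop = FALSE]
  } else NULL
  MethylSet(beta, sampleData = sdf, probeData = ann)
}
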