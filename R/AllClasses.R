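#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assayNames
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

# Enumerations shared across modules: CpG-island relation and gene-feature
# context classes as annotated on Illumina methylation arrays.
ISLAND_CLASSES  <- c("Island", "Shore", "Shelf", "OpenSea")
FEATURE_CLASSES <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body",
                     "ExonBnd", "3'UTR", "IGR")

# Blood leukocyte types resolved by the reference-based deconvolution:
# CD8+ T, CD4+ T, natural killer, monocytes, B cells, neutrophils.
BLOOD_CELL_TYPES <- c("CD8T", "CD4T", "NK", "Mono", "Bcell", "Neu")

#' MethylSet: a beta-value matrix with sample and probe metadata
#'
#' `MethylSet` extends [SummarizedExperiment::SummarizedExperiment] with the
#' constraint that its first assay, named `"beta"`, holds methylation
#' fractions in \[0, 1\] (`NA` allowed for missing calls). Probe annotation
#' (chromosome, position, nearest gene, CpG-island class, gene-feature class,
#' distal flag) lives in `rowData`; per-sample covariates (age, sex, BMI,
#' cell-type proportions, optional multi-modal ages) live in `colData`.
#'
#' @slot .. inherited from `SummarizedExperiment`; no additional slots.
#' @export
setClass("MethylSet", contains = "SummarizedExperiment")

setValidity("MethylSet", function(object) {
  msgs <- character()
  if (!"beta" %in% assayNames(object))
    msgs <- c(msgs, "first assay must be named 'beta'")
  else {
    b <- assay(object, "beta")
    if (!is.numeric(b))
      msgs <- c(msgs, "'beta' assay must be numeric")
    else {
      rng <- suppressWarnings(range(b, na.rm = TRUE))
      if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
        msgs <- c(msgs, "beta values must lie in [0, 1]")
    }
  }
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "probe ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample ids (colnames) must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MethylSet
#'
#' @param beta numeric matrix of methylation fractions, probes in rows
#'   (unique rownames), samples in columns (unique colnames).
#' @param sampleData data.frame / DataFrame of per-sample covariates, one row
#'   per column of `beta`.
#' @param probeData data.frame / DataFrame of probe annotation, one row per
#'   row of `beta`.
#' @return A [MethylSet-class] object.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' ms <- MethylSet(b, sampleData = data.frame(age = c(30, 60)))
#' @export
MethylSet <- function(beta, sampleData = NULL, probeData = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)))
    rownames(beta) <- sprintf("cg%08d", seq_len(nrow(beta)))
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("S%04d", seq_len(ncol(beta)))
  args <- list(assays = list(beta = beta))
  if (!is.null(sampleData)) args$colData <- DataFrame(sampleData,
                                                      row.names = colnames(beta))
  if (!is.null(probeData)) args$rowData <- DataFrame(probeData,
                                                     row.names = rownames(beta))
  se <- do.call(SummarizedExperiment, args)
  new("MethylSet", se)
}

#' @describeIn MethylSet beta-value matrix accessor.
#' @param object,x a `MethylSet`.
#' @export
betaValues <- function(object) assay(object, "beta")

#' @describeIn MethylSet probe annotation as a data.frame.
#' @export
probeAnnotation <- function(object) {
  as.data.frame(rowData(object), optional = TRUE)
}

#' @describeIn MethylSet sample covariates as a data.frame.
#' @export
sampleData <- function(object) {
  as.data.frame(colData(object), optional = TRUE)
}

setMethod("show", "MethylSet", function(object) {
  cat("MethylSet with", nrow(object), "probes and", ncol(object), "samples\n")
  b <- assay(object, "beta")
  cat(sprintf("  beta range: [%.3f, %.3f]  missing: %d\n",
              suppressWarnings(min(b, na.rm = TRUE)),
              suppressWarnings(max(b, na.rm = TRUE)), sum(is.na(b))))
  cat("  rowData:", paste(colnames(rowData(object)), collapse = ", "), "\n")
  cat("  colData:", paste(colnames(colData(object)), collapse = ", "), "\n")
})

#' ClockModel: a sparse linear epigenetic-age predictor
#'
#' Holds the intercept, the sparse CpG weight vector, the age transform used
#' at training time (`"horvath_piecewise"` for chronological-age clocks,
#' `"identity"` for multi-modal or OLS panels), the adult-age knot of the
#' piecewise transform, the training-set mean beta of each model probe (used
#' to impute probes missing at prediction time), and training metadata
#' (elastic-net alpha/lambda, validation MAE, target name).
#'
#' @slot name character model name.
#' @slot transform `"horvath_piecewise"` or `"identity"`.
#' @slot adultAge numeric knot (years) of the piecewise transform.
#' @slot intercept numeric.
#' @slot weights named numeric vector, probe id -> coefficient (beta scale).
#' @slot trainingMeans named numeric vector, training mean beta per model probe.
#' @slot meta list of training provenance (alpha, lambda, validation MAE,
#'   target).
#' @export
setClass("ClockModel",
  representation(name = "character", transform = "character",
                 adultAge = "numeric", intercept = "numeric",
                 weights = "numeric", trainingMeans = "numeric",
                 meta = "list"),
  prototype(name = "clock", transform = "horvath_piecewise", adultAge = 20,
            intercept = 0, weights = numeric(), trainingMeans = numeric(),
            meta = list()))

setValidity("ClockModel", function(object) {
  msgs <- character()
  if (!object@transform %in% c("horvath_piecewise", "identity"))
    msgs <- c(msgs, "transform must be 'horvath_piecewise' or 'identity'")
  if (object@transform == "horvath_piecewise" &&
      (length(object@adultAge) != 1 || !is.finite(object@adultAge)))
    msgs <- c(msgs, "horvath_piecewise transform requires a numeric adultAge")
  if (length(object@weights) && any(!is.finite(object@weights)))
    msgs <- c(msgs, "weights must be finite")
  if (length(object@weights) && is.null(names(object@weights)))
    msgs <- c(msgs, "weights must be named by probe id")
  if (length(msgs)) msgs else TRUE
})

ClockModel <- function(name, intercept, weights, transform = "horvath_piecewise",
                       adultAge = 20, trainingMeans = numeric(), meta = list()) {
  new("ClockModel", name = name, transform = transform, adultAge = adultAge,
      intercept = unname(intercept), weights = weights,
      trainingMeans = trainingMeans, meta = meta)
}

#' @describeIn ClockModel number of CpGs with nonzero weight.
#' @param object a `ClockModel`.
#' @export
clockSize <- function(object) sum(object@weights != 0)

#' @describeIn ClockModel named coefficient vector accessor.
#' @export
clockWeights <- function(object) object@weights

setMethod("show", "ClockModel", function(object) {
  cat(sprintf("ClockModel '%s': %d CpGs, transform=%s, intercept=%.4g\n",
              object@name, clockSize(object), object@transform,
              object@intercept))
  if (!is.null(object@meta$alpha))
    cat(sprintf("  alpha=%.2g lambda=%.4g", object@meta$alpha,
                object@meta$lambda %||% NA_real_))
  if (!is.null(object@meta$validationMAE))
    cat(sprintf("  validation MAE=%.3f years", object@meta$validationMAE))
  cat("\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
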