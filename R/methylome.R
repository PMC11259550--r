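#' Beta value from methylated / unmethylated intensities
#'
#' `beta = M / (M + U)`, the methylated-signal fraction of a CpG probe.
#' Vectorized; positions with `M + U == 0` have no signal and return `NA`
#' (counted in a message).
#'
#' @param M,U non-negative intensity vectors (recycled to common length).
#' @return numeric vector of beta fractions in \[0, 1\], `NA` where
#'   `M + U == 0`.
#' @examples
#' computeBeta(300, 100)  # 0.75
#' @export
computeBeta <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  tot <- M + U
  beta <- ifelse(tot > 0, M / tot, NA_real_)
  nMiss <- sum(tot == 0, na.rm = TRUE)
  if (nMiss > 0)
    message(sprintf("computeBeta: %d positions with zero total intensity set to NA",
                    nMiss))
  beta
}

#' Filter probes by exclusion lists and sex chromosomes
#'
#' Removes probes named in any exclusion set (SNP-related probes, multi-hit
#' probes, custom lists) and, optionally, all probes on chrX/chrY. Probe
#' order is preserved; excluded ids absent from the matrix are ignored with
#' a message. Idempotent.
#'
#' @param ms a [MethylSet-class].
#' @param exclude character vector (or list of vectors) of probe ids to drop.
#' @param dropSex drop probes with `chrom` in chrX/chrY (requires a `chrom`
#'   column in the probe annotation).
#' @return the filtered `MethylSet`.
#' @export
filterProbes <- function(ms, exclude = character(), dropSex = FALSE) {
  exclude <- unique(unlist(exclude, use.names = FALSE))
  keep <- rep(TRUE, nrow(ms))
  if (length(exclude)) {
    missing <- setdiff(exclude, rownames(ms))
    if (length(missing))
      message(sprintf("filterProbes: %d excluded ids not present in matrix",
                      length(missing)))
    keep <- keep & !(rownames(ms) %in% exclude)
    if (!any(keep)) stop("exclusion lists removed every probe")
  }
  if (dropSex) {
    ann <- probeAnnotation(ms)
    if (is.null(ann$chrom)) stop("dropSex requires a 'chrom' annotation column")
    keep <- keep & !(ann$chrom %in% c("chrX", "chrY", "X", "Y"))
    if (!any(keep)) stop("sex-chromosome filter removed every probe")
  }
  ms[keep, ]
}

#' Per-sample mean methylation
#'
#' Arithmetic mean beta over non-missing probes, per sample. Global mean
#' methylation declines with age in whole blood when hypomethylating probes
#' dominate.
#'
#' @param ms a [MethylSet-class].
#' @return named numeric vector, one mean in \[0, 1\] per sample.
#' @export
meanMethylation <- function(ms) {
  b <- betaValues(ms)
  ok <- colSums(!is.na(b)) > 0
  if (!all(ok))
    stop("samples with no non-missing probes: ",
         paste(colnames(b)[!ok], collapse = ", "))
  colMeans(b, na.rm = TRUE)
}

#' Per-sample methylation entropy
#'
#' Mean over probes of the binary Shannon entropy
#' `-(b log2 b + (1-b) log2(1-b))`, with betas clipped to
#' `[eps, 1 - eps]` first. Normalized to \[0, 1\] (1 at beta = 0.5
#' everywhere) and symmetric under `beta -> 1 - beta`. Methylation entropy
#' rises with age as the methylome drifts toward intermediate values.
#'
#' @param ms a [MethylSet-class].
#' @param eps clip bound keeping the logarithms finite.
#' @return named numeric vector, one entropy in \[0, 1\] per sample.
#' @examples
#' b <- matrix(0.25, 1, 2, dimnames = list("cg1", c("a", "b")))
#' methylationEntropy(MethylSet(b))  # 0.8113
#' @export
methylationEntropy <- function(ms, eps = 1e-6) {
  b <- betaValues(ms)
  b <- pmin(pmax(b, eps), 1 - eps)
  h <- -(b * log2(b) + (1 - b) * log2(1 - b))
  colMeans(h, na.rm = TRUE)
}

#' Reference-based blood cell deconvolution (Houseman-style projection)
#'
#' Estimates per-sample cell-type proportions by constrained least squares
#' of each sample's marker-probe betas on purified reference profiles:
#' minimize `||ref %*% w - beta||^2` subject to `w >= 0` and `sum(w) = 1`.
#' The sum-to-one constraint is enforced via a heavily weighted augmentation
#' row in the non-negative least-squares system, followed by renormalization
#' (exact to well below 1e-8).
#'
#' @param ms a [MethylSet-class] (or plain beta matrix) containing the
#'   marker probes.
#' @param ref reference matrix, marker probes x cell types, betas in
#'   \[0, 1\], no missing values.
#' @return matrix samples x cell types; rows are non-negative and sum to 1.
#' @examples
#' ref <- simulateCellReference(k = 2, nMarkers = 4)
#' mix <- ref %*% c(0.3, 0.7)
#' estimateCellProportions(mix, ref)  # 0.3 / 0.7
#' @export
estimateCellProportions <- function(ms, ref) {
  b <- if (is(ms, "SummarizedExperiment")) betaValues(ms) else as.matrix(ms)
  ref <- as.matrix(ref)
  if (anyNA(ref)) stop("reference matrix must have no missing values")
  k <- ncol(ref)
  if (k < 2) stop("reference must contain >= 2 cell types")
  shared <- intersect(rownames(b), rownames(ref))
  if (is.null(rownames(b)) || is.null(rownames(ref))) {
    if (nrow(b) != nrow(ref))
      stop("unnamed inputs must have matching row counts")
    shared <- seq_len(nrow(b))
  }
  if (length(shared) < k)
    stop(sprintf("only %d marker probes shared between data and reference (need >= %d)",
                 length(shared), k))
  R <- ref[shared, , drop = FALSE]
  if (qr(R)$rank < k) stop("reference profiles are rank-deficient")
  B <- b[shared, , drop = FALSE]
  lambda <- 1e4  # weight of the sum-to-one augmentation row
  A <- rbind(R, rep(lambda, k))
  out <- t(apply(B, 2, function(y) {
    w <- pracma::lsqnonneg(A, c(y, lambda))$x
    s <- sum(w)
    if (s <= 0) stop("deconvolution degenerate: all-zero solution")
    w / s
  }))
  colnames(out) <- colnames(ref)
  out
}
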