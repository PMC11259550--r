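#' Per-probe linear models of methylation on age
#'
#' Fits, for every probe, an ordinary least-squares model of beta on age
#' plus optional covariates (sex as 0/1, BMI, estimated cell-type
#' proportions), all probes sharing one design matrix. The reported slope is
#' the age coefficient in beta units per year; its p-value is the two-sided
#' t-test on that coefficient. The fit is a single QR decomposition applied
#' to all probes at once, so it scales to full arrays.
#'
#' @param ms a [MethylSet-class]; `colData` must contain `age` and every
#'   requested covariate as numeric columns.
#' @param covariates character vector of `colData` column names adjusted
#'   for (e.g. `c("sex", "bmi", "CD8T", ..., "Neu")`).
#' @return data.frame with one row per probe: `probe`, `slope` (beta/year),
#'   `se`, `t`, `p`, plus attribute `df` (residual degrees of freedom).
#' @seealso [callDmps()] to apply the effect-size and FDR gates.
#' @export
fitSiteModels <- function(ms, covariates = character()) {
  sd <- sampleData(ms)
  if (is.null(sd$age)) stop("colData must contain an 'age' column")
  miss <- setdiff(covariates, colnames(sd))
  if (length(miss))
    stop("covariate columns not found: ", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, age = sd$age)
  for (cv in covariates) {
    v <- sd[[cv]]
    if (!is.numeric(v)) stop(sprintf("covariate '%s' must be numeric", cv))
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1) stop("need n > #covariates + 2 samples")
  qrX <- qr(X)
  if (qrX$rank < k || kappa(X, exact = TRUE) > 1e10)
    stop("collinear design matrix; check columns: ",
         paste(colnames(X)[-1], collapse = ", "))
  Y <- t(betaValues(ms))                      # samples x probes
  coefs <- qr.coef(qrX, Y)                    # k x probes
  res <- Y - X %*% coefs
  df <- n - k
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  seAge <- sqrt(sigma2 * XtXinv[2, 2])
  slope <- coefs["age", ]
  tstat <- slope / seAge
  p <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(probe = rownames(ms), slope = unname(slope),
                    se = unname(seAge), t = unname(tstat), p = unname(p),
                    stringsAsFactors = FALSE)
  attr(out, "df") <- df
  out
}

#' Call age-related DMPs from per-probe fits
#'
#' Applies Benjamini-Hochberg adjustment across all tested probes, then the
#' joint gate: adjusted p below `alpha` and `|slope|` above
#' `slopeThreshold` (beta units per year). Direction is the slope sign among
#' passing probes; genomic context is attached from the annotation when
#' available.
#'
#' @param fits output of [fitSiteModels()].
#' @param annot optional probe annotation data.frame (rownames or `probe`
#'   column matching fit probes) contributing `chrom`, `pos`, `islandClass`,
#'   `featureClass`, `distalFlag`.
#' @param slopeThreshold minimum absolute slope, beta/year (default 0.002).
#' @param alpha BH-adjusted p cutoff (default 0.01).
#' @return data.frame of DMP records: fit columns plus `padj`, `direction`
#'   (`up`/`down`/`ns`) and any annotation columns.
#' @export
callDmps <- function(fits, annot = NULL, slopeThreshold = 0.002,
                     alpha = 0.01) {
  out <- fits
  out$padj <- stats::p.adjust(out$p, method = "BH")
  pass <- out$padj < alpha & abs(out$slope) > slopeThreshold
  out$direction <- ifelse(!pass, "ns", ifelse(out$slope > 0, "up", "down"))
  if (!is.null(annot)) {
    ann <- as.data.frame(annot)
    key <- if (!is.null(ann$probe)) ann$probe else rownames(ann)
    idx <- match(out$probe, key)
    for (col in intersect(c("chrom", "pos", "islandClass", "featureClass",
                            "distalFlag"), colnames(ann)))
      out[[col]] <- ann[[col]][idx]
  }
  out
}

#' Genomic-context composition of DMPs by direction
#'
#' Per direction (up / down), the proportion of DMPs in each CpG-island
#' class and each gene-feature class, each set of proportions summing to 1.
#'
#' @param dmps data.frame from [callDmps()] with `direction`, `islandClass`,
#'   `featureClass`.
#' @return data.frame with columns `direction`, `classType`
#'   (`island`/`feature`), `class`, `count`, `proportion`.
#' @export
contextComposition <- function(dmps) {
  rows <- list()
  for (dir in c("up", "down")) {
    sub <- dmps[dmps$direction == dir, , drop = FALSE]
    if (!nrow(sub)) {
      message(sprintf("contextComposition: no DMPs in direction '%s'", dir))
      next
    }
    for (ct in c("island", "feature")) {
      classes <- if (ct == "island") ISLAND_CLASSES else FEATURE_CLASSES
      col <- if (ct == "island") "islandClass" else "featureClass"
      counts <- table(factor(sub[[col]], levels = classes))
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dir, classType = ct, class = classes,
        count = as.integer(counts),
        proportion = as.numeric(counts) / nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(direction = character(), classType = character(),
                      class = character(), count = integer(),
                      proportion = numeric()))
  do.call(rbind, rows)
}

#' DMP density in fixed-width genomic bins
#'
#' Counts DMPs per chromosome in half-open bins
#' `[k * binSize, (k + 1) * binSize)` and reports per-chromosome totals.
#' Probes without a position are excluded with a message.
#'
#' @param dmps data.frame with `direction`, `chrom`, `pos` (1-based bp);
#'   only rows with direction up/down are counted.
#' @param binSize bin width in bp (default 1 Mb).
#' @return list with `bins` (data.frame chrom / binStart / binEnd / count)
#'   and `chromTotals` (named integer vector).
#' @export
genomicDensity <- function(dmps, binSize = 1e6) {
  sig <- dmps[dmps$direction %in% c("up", "down"), , drop = FALSE]
  if (!nrow(sig))
    return(list(bins = data.frame(chrom = character(), binStart = numeric(),
                                  binEnd = numeric(), count = integer()),
                chromTotals = integer()))
  noPos <- is.na(sig$pos) | is.na(sig$chrom)
  if (any(noPos)) {
    message(sprintf("genomicDensity: %d DMPs lack a position and were excluded",
                    sum(noPos)))
    sig <- sig[!noPos, , drop = FALSE]
  }
  bin <- floor(sig$pos / binSize)
  tab <- as.data.frame(table(chrom = sig$chrom, bin = bin),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  bins <- data.frame(chrom = tab$chrom,
                     binStart = as.numeric(tab$bin) * binSize,
                     binEnd = (as.numeric(tab$bin) + 1) * binSize,
                     count = as.integer(tab$Freq),
                     stringsAsFactors = FALSE)
  bins <- bins[order(bins$chrom, bins$binStart), , drop = FALSE]
  rownames(bins) <- NULL
  totals <- vapply(split(bins$count, bins$chrom), sum, integer(1))
  list(bins = bins, chromTotals = totals)
}

#' Sliding-window scan for methylation change-points across age
#'
#' For each window center `c` (spaced `parcel` years apart) the samples one
#' window below the center (`age` in `[c - window, c)`) are contrasted with
#' the samples one window above (`age` in `[c, c + window]`) by a per-probe
#' Welch t-test; p-values are BH-adjusted across probes within the center,
#' and the number of significant probes (split by sign of the old-minus-young
#' mean difference) is reported. A peak in these counts marks an age at
#' which the methylome changes most.
#'
#' @param ms a [MethylSet-class] with an `age` column.
#' @param window half-contrast width in years (default 5).
#' @param parcel spacing of window centers in years (default 5).
#' @param alpha BH-adjusted p cutoff within each center (default 0.05).
#' @param minPerGroup skip centers where either group has fewer samples.
#' @return data.frame with one row per evaluated center: `center`, `nYoung`,
#'   `nOld`, `up`, `down`, `total`.
#' @export
slidingWindowDmp <- function(ms, window = 5, parcel = 5, alpha = 0.05,
                             minPerGroup = 2) {
  age <- sampleData(ms)$age
  if (is.null(age)) stop("colData must contain an 'age' column")
  b <- betaValues(ms)
  # centers on the parcel grid, far enough from both age extremes
  lo <- parcel * ceiling((min(age) + window) / parcel)
  hi <- floor(max(age)) - window
  if (lo > hi) stop("age span too narrow for the requested window")
  centers <- seq(lo, hi, by = parcel)
  rows <- lapply(centers, function(cc) {
    young <- age >= cc - window & age < cc
    old <- age >= cc & age <= cc + window
    if (sum(young) < minPerGroup || sum(old) < minPerGroup) {
      message(sprintf("slidingWindowDmp: center %.1f skipped (%d vs %d samples)",
                      cc, sum(young), sum(old)))
      return(NULL)
    }
    tt <- .rowWelch(b[, young, drop = FALSE], b[, old, drop = FALSE])
    padj <- stats::p.adjust(tt$p, method = "BH")
    sig <- !is.na(padj) & padj < alpha
    data.frame(center = cc, nYoung = sum(young), nOld = sum(old),
               up = sum(sig & tt$delta > 0), down = sum(sig & tt$delta < 0),
               total = sum(sig))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(center = numeric(), nYoung = integer(),
                      nOld = integer(), up = integer(), down = integer(),
                      total = integer())
  rownames(out) <- NULL
  out
}

# Vectorized per-row Welch t-test: rows of x vs rows of y.
# delta = mean(y) - mean(x); degenerate rows (both variances 0) get p = 1.
.rowWelch <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1
  list(delta = m2 - m1, t = tstat, df = df, p = p)
}
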