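#' Age pace: residual of predicted age on chronological age
#'
#' The pace of aging is the residual of an OLS regression of predicted
#' (epigenetic) age on chronological age: positive pace = older epigenome
#' than the cohort trend predicts (accelerated aging), negative =
#' decelerated. By construction paces have mean 0 and are uncorrelated with
#' chronological age.
#'
#' @param predicted numeric predicted ages (years).
#' @param chronological matching chronological ages (years), non-constant.
#' @param sampleIds optional ids (defaults to names of `predicted` or an
#'   index).
#' @return data.frame: `sample`, `predicted`, `chronological`, `pace`,
#'   `accelerated` (pace > 0).
#' @export
computeAgePace <- function(predicted, chronological, sampleIds = NULL) {
  if (length(predicted) != length(chronological))
    stop("predicted and chronological must have equal length")
  if (length(predicted) < 10) stop("need >= 10 paired values")
  if (stats::sd(chronological) == 0)
    stop("chronological ages are constant; regression undefined")
  if (is.null(sampleIds))
    sampleIds <- names(predicted) %||% as.character(seq_along(predicted))
  fit <- stats::lm.fit(cbind(1, chronological), predicted)
  pace <- unname(fit$residuals)
  data.frame(sample = sampleIds, predicted = unname(predicted),
             chronological = unname(chronological), pace = pace,
             accelerated = pace > 0, stringsAsFactors = FALSE)
}

#' Stratify samples into pace groups
#'
#' The top `q` fraction of paces become accelerators, the bottom `q`
#' decelerators (each of size `ceiling(q * n)`), the rest `middle`. Ties
#' are broken deterministically by sample id.
#'
#' @param paceDf data.frame from [computeAgePace()].
#' @param q extreme fraction per tail (default 0.20).
#' @return `paceDf` with a `group` factor
#'   (`accelerator`/`middle`/`decelerator`).
#' @export
classifyPaceGroups <- function(paceDf, q = 0.2) {
  n <- nrow(paceDf)
  k <- ceiling(q * n)
  if (k < 2) stop("q * n must be >= 2")
  if (2 * k > n) k <- floor(n / 2)
  ord <- order(paceDf$pace, paceDf$sample)   # id breaks ties
  group <- rep("middle", n)
  group[ord[seq_len(k)]] <- "decelerator"
  group[ord[seq.int(n - k + 1L, n)]] <- "accelerator"
  paceDf$group <- factor(group,
                         levels = c("accelerator", "middle", "decelerator"))
  paceDf
}

#' Compare numeric features between pace groups
#'
#' Two-sided Welch two-sample t-test per numeric feature between
#' accelerators and decelerators; features with p below `pCut` are flagged.
#'
#' @param features data.frame of per-sample numeric features (rows aligned
#'   with `groups`).
#' @param groups factor/character with levels containing `accelerator` and
#'   `decelerator`; other samples are ignored.
#' @param pCut significance cutoff (default 0.05).
#' @param modality label stored in the output (default `"phenotype"`).
#' @return data.frame: `feature`, `modality`, `effect` (accelerator minus
#'   decelerator mean), `t`, `p`, `significant`, `test`.
#' @export
compareNumericFeatures <- function(features, groups, pCut = 0.05,
                                   modality = "phenotype") {
  a <- groups == "accelerator"
  d <- groups == "decelerator"
  if (sum(a) < 3 || sum(d) < 3) stop("need >= 3 samples per group")
  rows <- lapply(colnames(features), function(f) {
    x <- features[[f]][a]; y <- features[[f]][d]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3) return(NULL)
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      message(sprintf("compareNumericFeatures: '%s' has zero variance, skipped", f))
      return(NULL)
    }
    tt <- stats::t.test(x, y)
    data.frame(feature = f, modality = modality,
               effect = mean(x) - mean(y), t = unname(tt$statistic),
               p = tt$p.value, significant = tt$p.value < pCut,
               test = "t", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature = character(), modality = character(),
                      effect = numeric(), t = numeric(), p = numeric(),
                      significant = logical(), test = character())
  rownames(out) <- NULL
  out
}

#' Compare dichotomous features between pace groups
#'
#' Chi-squared test on the 2x2 table of each dichotomous feature versus
#' group; when any expected cell is below 5 the test falls back to Fisher's
#' exact test (noted in the `test` column).
#'
#' @inheritParams compareNumericFeatures
#' @param modality label stored in the output (default `"lifestyle"`).
#' @return data.frame: `feature`, `modality`, `effect` (difference in level
#'   proportions), `p`, `significant`, `test`.
#' @export
compareBinaryFeatures <- function(features, groups, pCut = 0.05,
                                  modality = "lifestyle") {
  sel <- groups %in% c("accelerator", "decelerator")
  rows <- lapply(colnames(features), function(f) {
    v <- features[[f]][sel]
    g <- droplevels(factor(groups[sel]))
    ok <- !is.na(v)
    v <- factor(v[ok]); g <- g[ok]
    if (nlevels(v) != 2) {
      message(sprintf("compareBinaryFeatures: '%s' is not dichotomous, skipped", f))
      return(NULL)
    }
    tab <- table(g, v)
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp < 5)) {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
      test <- "chisq"
    }
    prop <- tab[, 2] / rowSums(tab)
    data.frame(feature = f, modality = modality,
               effect = unname(prop["accelerator"] - prop["decelerator"]),
               p = p, significant = p < pCut, test = test,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature = character(), modality = character(),
                      effect = numeric(), p = numeric(),
                      significant = logical(), test = character())
  rownames(out) <- NULL
  out
}

#' Differential protein / metabolite / transcript features between groups
#'
#' Features detected (non-missing) in more than `detectFrac` of the
#' accelerator+decelerator samples are retained; abundances are optionally
#' normalized by each sample's mean and log2-transformed; each feature is
#' then tested with a two-sided Welch t-test (complete cases) and scored by
#' log2 fold change (accelerator minus decelerator mean on the log2 scale).
#' A feature passes when `p < pCut` and `|lfc| > lfcCut`; for
#' `modality = "transcript"` the p-value gate uses BH-adjusted p-values.
#'
#' @param abundance non-negative matrix, features x samples.
#' @param groups factor/character per sample.
#' @param detectFrac detection fraction gate (default 2/3).
#' @param pCut p-value gate (default 0.05).
#' @param lfcCut absolute log2-fold-change gate (default 0.5).
#' @param normalize `"sample_mean_log"` (divide by per-sample mean, then
#'   log2) or `"none"` (log2 of raw abundances).
#' @param modality one of protein / metabolite / transcript.
#' @return data.frame: `feature`, `modality`, `effect` (log2 fold change),
#'   `p`, `padj`, `significant`, `test`.
#' @export
differentialOmics <- function(abundance, groups, detectFrac = 2 / 3,
                              pCut = 0.05, lfcCut = 0.5,
                              normalize = c("sample_mean_log", "none"),
                              modality = "protein") {
  normalize <- match.arg(normalize)
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  sel <- groups %in% c("accelerator", "decelerator")
  ab <- abundance[, sel, drop = FALSE]
  g <- groups[sel]
  detected <- rowMeans(!is.na(ab) & ab > 0) > detectFrac
  nDrop <- sum(!detected)
  if (nDrop)
    message(sprintf("differentialOmics: %d/%d features below the %.0f%% detection gate",
                    nDrop, nrow(ab), 100 * detectFrac))
  ab <- ab[detected, , drop = FALSE]
  if (!nrow(ab))
    return(data.frame(feature = character(), modality = character(),
                      effect = numeric(), p = numeric(), padj = numeric(),
                      significant = logical(), test = character()))
  if (normalize == "sample_mean_log") {
    sm <- colMeans(ab, na.rm = TRUE)
    ab <- sweep(ab, 2, sm, "/")
  }
  lab <- log2(ab)
  lab[!is.finite(lab)] <- NA
  a <- g == "accelerator"; d <- g == "decelerator"
  res <- lapply(rownames(lab), function(f) {
    x <- lab[f, a]; y <- lab[f, d]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3 ||
        (stats::var(x) == 0 && stats::var(y) == 0)) return(NULL)
    tt <- stats::t.test(x, y)
    data.frame(feature = f, modality = modality,
               effect = mean(x) - mean(y), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(feature = character(), modality = character(),
                      effect = numeric(), p = numeric(), padj = numeric(),
                      significant = logical(), test = character()))
  out$padj <- stats::p.adjust(out$p, method = "BH")
  pGate <- if (modality == "transcript") out$padj else out$p
  out$significant <- pGate < pCut & abs(out$effect) > lfcCut
  out$test <- "t"
  rownames(out) <- NULL
  out
}
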