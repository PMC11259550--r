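#' Select DMPs in distal or promoter feature regions
#'
#' Probe-gene pairing is restricted to DMPs that can plausibly act on
#' transcription: probes flagged distal (enhancer-like) or falling in
#' promoter feature classes (TSS200 / TSS1500).
#'
#' @param dmps data.frame from [callDmps()] with `direction`, `distalFlag`,
#'   `featureClass`.
#' @return the subset of rows with direction up/down satisfying the
#'   distal-or-promoter predicate.
#' @export
selectFeatureProbes <- function(dmps) {
  keep <- dmps$direction %in% c("up", "down") &
    (isTRUE_vec(dmps$distalFlag) | dmps$featureClass %in% c("TSS200", "TSS1500"))
  dmps[keep, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Extreme-group expression test for one probe-gene pair
#'
#' Samples are ranked by the probe's beta; the top `q` fraction forms group
#' M (highest methylation) and the bottom `q` fraction group U (lowest).
#' A one-sided Mann-Whitney / Wilcoxon rank-sum test compares the gene's
#' expression between the groups; the default alternative `"less"` asks
#' whether expression in M is lower than in U, i.e. the anti-correlation
#' expected when methylation represses (or its loss activates)
#' transcription.
#'
#' @param betaVec named beta values for one probe (one per sample).
#' @param exprVec named expression values for one gene, same samples.
#' @param q extreme-group fraction (default 0.20); group size is
#'   `ceiling(q * n)`.
#' @param alternative passed to [stats::wilcox.test()]; `"less"` tests
#'   expression lower in M.
#' @return list with `statistic` (Mann-Whitney U of group M), `p`, and the
#'   sample indices `idxM`, `idxU`.
#' @export
extremeGroupTest <- function(betaVec, exprVec, q = 0.2,
                             alternative = "less") {
  n <- length(betaVec)
  stopifnot(length(exprVec) == n)
  nExt <- ceiling(q * n)
  if (nExt < 2) stop("extreme groups need >= 2 samples; increase q or n")
  ord <- order(betaVec)
  idxU <- ord[seq_len(nExt)]
  idxM <- ord[seq.int(n - nExt + 1L, n)]
  wt <- suppressWarnings(
    stats::wilcox.test(exprVec[idxM], exprVec[idxU],
                       alternative = alternative))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       idxM = idxM, idxU = idxU)
}

#' Empirical p-value from a permutation null of p-values
#'
#' Add-one rule: `(1 + #\{null <= observed\}) / (1 + n_null)`, comparing
#' one-sided p-values (smaller = more extreme). Never returns 0 and
#' converges to the exhaustive-enumeration p as the null grows.
#'
#' @param observedP observed one-sided p-value.
#' @param nullP vector of p-values from the permutation null.
#' @return empirical p in (0, 1\].
#' @export
empiricalP <- function(observedP, nullP) {
  (1 + sum(nullP <= observedP)) / (1 + length(nullP))
}

#' Probe-gene pair discovery by extreme-group testing with permutation p
#'
#' For each candidate probe, samples are split into the `q` highest- (M) and
#' lowest- (U) methylated groups at that probe; each candidate gene (the
#' nearest genes by signed rank distance) is tested one-sided for lower
#' expression in M. An empirical p-value is obtained per probe by rerunning
#' the identical test on `nPerm` random genes drawn from the expression
#' matrix (same M/U groups) and applying the add-one rule to the observed
#' p; pairs with empirical p below `empAlpha` are reported. Pair class
#' follows the probe's DMP direction: `repressed` (beta up with age,
#' expression down) or `activated` (beta down, expression up).
#'
#' @param ms a [MethylSet-class].
#' @param expr expression matrix, genes x samples.
#' @param geneOrder data.frame `probe` / `gene` / `rankDistance` (signed,
#'   -10..10 excluding 0) listing candidate genes per probe.
#' @param dmps data.frame from [callDmps()] supplying probe directions;
#'   only up/down probes present in `geneOrder` are tested.
#' @param q extreme-group fraction (default 0.20).
#' @param nPerm random genes per probe for the empirical null.
#' @param seed RNG seed for the permutation draws.
#' @param empAlpha empirical-p cutoff for reported pairs (default 0.05).
#' @param returnAll return all tested pairs with a `significant` flag
#'   instead of only the passing ones.
#' @return data.frame: `probe`, `gene`, `rankDistance`, `rawP`,
#'   `empiricalP`, `class`, `significant`.
#' @export
probeGenePairs <- function(ms, expr, geneOrder, dmps, q = 0.2, nPerm = 1000,
                           seed = 1L, empAlpha = 0.05, returnAll = FALSE) {
  b <- betaValues(ms)
  shared <- intersect(colnames(b), colnames(expr))
  if (length(shared) < 10)
    stop("need >= 10 shared samples between methylation and expression")
  b <- b[, shared, drop = FALSE]
  expr <- expr[, shared, drop = FALSE]
  dirMap <- stats::setNames(dmps$direction, dmps$probe)
  probes <- intersect(unique(geneOrder$probe), names(dirMap)[dirMap %in% c("up", "down")])
  probes <- intersect(probes, rownames(b))
  set.seed(as.integer(seed))
  allGenes <- rownames(expr)
  rows <- list()
  for (pr in probes) {
    cand <- geneOrder[geneOrder$probe == pr, , drop = FALSE]
    if (any(table(cand$gene) > 1) || nrow(cand) > 20)
      stop("each probe needs <= 20 distinct candidate genes")
    et0 <- extremeGroupTest(b[pr, ], expr[cand$gene[1], ], q = q)
    idxM <- et0$idxM; idxU <- et0$idxU
    testGene <- function(g) {
      e <- expr[g, ]
      if (stats::var(e) == 0) return(NA_real_)
      suppressWarnings(stats::wilcox.test(e[idxM], e[idxU],
                                          alternative = "less"))$p.value
    }
    nullP <- vapply(sample(allGenes, nPerm, replace = TRUE), testGene,
                    numeric(1), USE.NAMES = FALSE)
    nullP <- nullP[!is.na(nullP)]
    for (i in seq_len(nrow(cand))) {
      g <- cand$gene[i]
      if (!g %in% rownames(expr)) next
      obsP <- testGene(g)
      if (is.na(obsP)) {
        message(sprintf("probeGenePairs: constant expression for %s, pair skipped", g))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        probe = pr, gene = g, rankDistance = cand$rankDistance[i],
        rawP = obsP, empiricalP = empiricalP(obsP, nullP),
        class = if (dirMap[[pr]] == "up") "repressed" else "activated",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe = character(), gene = character(),
               rankDistance = integer(), rawP = numeric(),
               empiricalP = numeric(), class = character())
  out$significant <- out$empiricalP < empAlpha
  if (!returnAll) out <- out[out$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif enrichment in a direction-specific probe set
#'
#' For each motif (occurrences within +/- 250 bp of probes, supplied as a
#' table), a 2x2 contingency of motif presence in the probe set versus the
#' remaining background probes is tested with Fisher's exact test. The odds
#' ratio and its Wald 95% CI on the log scale use the Haldane-Anscombe 0.5
#' correction when any cell is zero. A motif is enriched when its in-set
#' occurrence count is at least `minCount`, the CI lower bound exceeds
#' `orLower`, and the BH-adjusted p (across all tested motifs) is below
#' `alpha`.
#'
#' @param probeSet character vector of probes (must be a subset of
#'   `background`).
#' @param motifTable data.frame `motif` / `probe`: one row per motif
#'   occurrence near a probe.
#' @param background character vector of all eligible probes.
#' @param minCount minimum in-set occurrence count (default 10).
#' @param orLower CI lower-bound gate on the odds ratio (default 1.1).
#' @param alpha BH-adjusted p gate (default 0.05).
#' @param allResults return every tested motif with an `enriched` flag.
#' @return data.frame: `motif`, `countInSet`, `oddsRatio`, `ciLower`,
#'   `ciUpper`, `p`, `padj`, `enriched`.
#' @export
motifEnrichment <- function(probeSet, motifTable, background, minCount = 10,
                            orLower = 1.1, alpha = 0.05, allResults = FALSE) {
  if (!all(probeSet %in% background))
    stop("probeSet must be a subset of background")
  probeSet <- unique(probeSet)
  background <- unique(background)
  rest <- setdiff(background, probeSet)
  motifTable <- motifTable[motifTable$probe %in% background, , drop = FALSE]
  motifs <- sort(unique(motifTable$motif))
  rows <- lapply(motifs, function(m) {
    hit <- unique(motifTable$probe[motifTable$motif == m])
    a <- sum(probeSet %in% hit)            # in set, motif present
    b <- length(probeSet) - a
    cc <- sum(rest %in% hit)               # background (non-set), present
    d <- length(rest) - cc
    if (a + cc == 0) {
      message(sprintf("motifEnrichment: motif %s absent from background, skipped", m))
      return(NULL)
    }
    if ((b == 0 && d == 0) || (a == 0 && cc == 0)) {
      # motif present (or absent) in every probe everywhere: no measurable
      # association; OR fixed at 1 with a vacuous CI
      or <- 1; ci <- c(0, Inf); p <- 1
    } else {
      cells <- c(a, b, cc, d)
      if (any(cells == 0)) cells <- cells + 0.5
      or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
      seLog <- sqrt(sum(1 / cells))
      ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * seLog)
      p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    }
    data.frame(motif = m, countInSet = a, oddsRatio = or, ciLower = ci[1],
               ciUpper = ci[2], p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(motif = character(), countInSet = integer(),
                      oddsRatio = numeric(), ciLower = numeric(),
                      ciUpper = numeric(), p = numeric(), padj = numeric(),
                      enriched = logical()))
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$countInSet >= minCount & out$ciLower > orLower &
    out$padj < alpha
  rownames(out) <- NULL
  if (!allResults) out <- out[out$enriched, , drop = FALSE]
  out
}

#' Correlation of motif-site methylation with TF expression
#'
#' Averages beta across the probes carrying an enriched motif, per sample,
#' and tests its Pearson correlation with the expression of the motif's
#' TF-coding gene; a significant correlation nominates the TF as
#' methylation-sensitive during aging.
#'
#' @param ms a [MethylSet-class].
#' @param expr expression matrix, genes x samples.
#' @param probes probes carrying the motif.
#' @param tfGene gene id of the TF (row of `expr`).
#' @return list with `r` (Pearson), `p` (two-sided), `n`.
#' @export
tfMethylationCorrelation <- function(ms, expr, probes, tfGene) {
  if (!tfGene %in% rownames(expr)) stop("tfGene not found in expression matrix")
  b <- betaValues(ms)
  probes <- intersect(probes, rownames(b))
  if (!length(probes)) stop("none of the motif probes are in the beta matrix")
  shared <- intersect(colnames(b), colnames(expr))
  meanBeta <- colMeans(b[probes, shared, drop = FALSE], na.rm = TRUE)
  e <- expr[tfGene, shared]
  if (stats::var(meanBeta) == 0)
    stop("mean motif methylation is constant; correlation undefined")
  ct <- stats::cor.test(meanBeta, e, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
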