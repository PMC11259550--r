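#' Simulate a blood-methylome aging cohort with known ground truth
#'
#' Generates a [MethylSet-class] whose statistical structure mirrors what the
#' downstream analysis assumes: a fraction of probes gains methylation with
#' age (preferentially CpG-island / TSS contexts), a larger fraction loses it
#' (preferentially open sea), the remainder is age-null; ages are drawn
#' uniformly over an adult range; blood cell-type proportions are generated
#' per sample and, when `confoundCells = TRUE`, drift with age so that a
#' dedicated set of cell-driven probes shows spurious age association that
#' covariate adjustment must remove.
#'
#' The per-probe model is
#' `beta = baseline + slope * (age - ageRange[1]) + cell effect + N(0, noiseSd)`,
#' clipped to \[0, 1\]. Baselines are drawn per island context (islands low,
#' open sea high) to mimic the bimodality of real methylomes. Ground truth —
#' true slope, class (`up`/`down`/`null`), cell-driven flag, linked gene —
#' is stored in `rowData`.
#'
#' @param nSamples,nProbes cohort dimensions.
#' @param ageRange numeric length-2, years; ages drawn uniformly on it.
#' @param fracUp,fracDown fractions of probes hyper-/hypomethylating with
#'   age; `fracUp + fracDown <= 1`.
#' @param slopeRange magnitude interval of true slopes (beta units / year),
#'   within (0, 0.02].
#' @param noiseSd residual SD on the beta scale (>= 0).
#' @param confoundCells logical; add age-correlated cell-mixture confounding
#'   and a set of purely cell-driven probes.
#' @param cellDrivenFrac fraction of null probes made purely cell-driven when
#'   `confoundCells` is on.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @param ages optional explicit age vector overriding the uniform draw
#'   (length `nSamples`).
#' @return A `MethylSet`; ground truth in `rowData` (`trueSlope`, `trueClass`,
#'   `cellDriven`, `cellType`, `linkedGene`), covariates and true cell
#'   proportions in `colData`.
#' @examples
#' ms <- simulateCohort(nSamples = 40, nProbes = 100, seed = 1)
#' table(probeAnnotation(ms)$trueClass)
#' @export
simulateCohort <- function(nSamples = 250, nProbes = 2000,
                           ageRange = c(20, 87), fracUp = 0.05,
                           fracDown = 0.10, slopeRange = c(0.002, 0.008),
                           noiseSd = 0.03, confoundCells = TRUE,
                           cellDrivenFrac = 0.03, seed = 1L, ages = NULL) {
  if (nSamples < 1 || nProbes < 1)
    stop("nSamples and nProbes must be positive")
  if (ageRange[1] >= ageRange[2])
    stop("ageRange must satisfy lo < hi")
  if (fracUp + fracDown > 1)
    stop("fracUp + fracDown must not exceed 1")
  if (slopeRange[1] <= 0 || slopeRange[2] > 0.02)
    stop("slopeRange must lie within (0, 0.02]")
  if (noiseSd < 0) stop("noiseSd must be >= 0")

  set.seed(as.integer(seed))
  if (is.null(ages)) ages <- stats::runif(nSamples, ageRange[1], ageRange[2])
  stopifnot(length(ages) == nSamples)
  sex <- stats::rbinom(nSamples, 1L, 0.5)
  bmi <- stats::rnorm(nSamples, 23.5, 2.5)

  props <- .simulateCellProps(ages, confound = confoundCells)

  nUp <- round(fracUp * nProbes)
  nDown <- round(fracDown * nProbes)
  trueClass <- c(rep("up", nUp), rep("down", nDown),
                 rep("null", nProbes - nUp - nDown))
  # random order so class never aligns with row position
  ord <- sample.int(nProbes)
  trueClass <- trueClass[ord]

  islandClass <- vapply(trueClass, function(cl) {
    p <- switch(cl,
      up   = c(0.65, 0.15, 0.05, 0.15),
      down = c(0.05, 0.10, 0.10, 0.75),
      null = c(0.30, 0.15, 0.05, 0.50))
    sample(ISLAND_CLASSES, 1L, prob = p)
  }, character(1), USE.NAMES = FALSE)
  featureClass <- vapply(trueClass, function(cl) {
    p <- switch(cl,
      up   = c(0.16, 0.14, 0.08, 0.06, 0.30, 0.02, 0.04, 0.20),
      down = c(0.03, 0.05, 0.05, 0.03, 0.40, 0.02, 0.06, 0.36),
      null = c(0.05, 0.08, 0.07, 0.05, 0.35, 0.03, 0.07, 0.30))
    sample(FEATURE_CLASSES, 1L, prob = p)
  }, character(1), USE.NAMES = FALSE)
  distalFlag <- featureClass == "IGR" |
    (featureClass %in% c("Body", "3'UTR") & stats::runif(nProbes) < 0.5)

  chrom <- paste0("chr", sample(1:22, nProbes, replace = TRUE,
                                prob = 23 - (1:22)))
  pos <- sample.int(150e6, nProbes, replace = TRUE)

  baseline <- numeric(nProbes)
  for (cl in ISLAND_CLASSES) {
    idx <- islandClass == cl
    baseline[idx] <- switch(cl,
      Island  = stats::rbeta(sum(idx), 2, 8),
      Shore   = stats::rbeta(sum(idx), 2, 4),
      Shelf   = stats::rbeta(sum(idx), 3, 3),
      OpenSea = stats::rbeta(sum(idx), 8, 2))
  }

  slope <- numeric(nProbes)
  slope[trueClass == "up"] <- stats::runif(sum(trueClass == "up"),
                                           slopeRange[1], slopeRange[2])
  slope[trueClass == "down"] <- -stats::runif(sum(trueClass == "down"),
                                              slopeRange[1], slopeRange[2])
  # keep hypermethylating island probes off the floor and hypomethylating
  # open-sea probes off the ceiling over the simulated age span
  span <- diff(ageRange)
  baseline[trueClass == "up"] <- pmin(baseline[trueClass == "up"],
                                      0.95 - slope[trueClass == "up"] * span)
  baseline[trueClass == "down"] <- pmax(baseline[trueClass == "down"],
                                        0.05 - slope[trueClass == "down"] * span)

  cellDriven <- rep(FALSE, nProbes)
  cellType <- rep(NA_character_, nProbes)
  cellCoef <- numeric(nProbes)
  if (confoundCells && cellDrivenFrac > 0) {
    nullIdx <- which(trueClass == "null")
    nCell <- min(length(nullIdx), max(1L, round(cellDrivenFrac * nProbes)))
    pick <- sample(nullIdx, nCell)
    cellDriven[pick] <- TRUE
    cellType[pick] <- sample(c("Neu", "CD4T"), nCell, replace = TRUE)
    cellCoef[pick] <- stats::runif(nCell, 1.2, 2.0) *
      sample(c(-1, 1), nCell, replace = TRUE)
  }

  probeIds <- sprintf("cg%08d", seq_len(nProbes))
  sampleIds <- sprintf("S%04d", seq_len(nSamples))

  beta <- matrix(baseline, nProbes, nSamples) +
    outer(slope, ages - ageRange[1])
  if (any(cellDriven)) {
    for (ct in unique(stats::na.omit(cellType))) {
      idx <- which(cellDriven & cellType == ct)
      centred <- props[, ct] - mean(props[, ct])
      beta[idx, ] <- beta[idx, ] + outer(cellCoef[idx], centred)
    }
  }
  if (noiseSd > 0)
    beta <- beta + matrix(stats::rnorm(nProbes * nSamples, 0, noiseSd),
                          nProbes, nSamples)
  nClip <- sum(beta < 0 | beta > 1)
  if (nClip > 0)
    message(sprintf("simulateCohort: clipped %d/%d beta values (%.2f%%)",
                    nClip, length(beta), 100 * nClip / length(beta)))
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(probeIds, sampleIds)

  linkedGene <- ifelse(trueClass == "null", NA_character_,
                       paste0("G_", probeIds))

  # a multi-modal biological-age target (composite of non-DNAm modalities),
  # correlated with but noisier than chronological age; available for the
  # female subset, mirroring how such targets are usually measured
  compositeAge <- ages + stats::rnorm(nSamples, 0, 3)
  compositeAge[sex == 1] <- NA_real_

  probeData <- data.frame(
    chrom = chrom, pos = pos, gene = paste0("NG_", probeIds),
    islandClass = islandClass, featureClass = featureClass,
    distalFlag = distalFlag, trueSlope = slope, trueClass = trueClass,
    cellDriven = cellDriven, cellType = cellType, linkedGene = linkedGene,
    row.names = probeIds, stringsAsFactors = FALSE)
  sampleDf <- data.frame(age = ages, sex = sex, bmi = bmi,
                         compositeAge = compositeAge,
                         props, row.names = sampleIds)

  MethylSet(beta, sampleData = sampleDf, probeData = probeData)
}

# Dirichlet-style cell proportions; with confounding the neutrophil mean
# rises and the CD4 T-cell mean falls with age, giving |r(prop, age)| > 0.3.
.simulateCellProps <- function(ages, confound = TRUE, concentration = 400) {
  n <- length(ages)
  base <- c(CD8T = 0.08, CD4T = 0.20, NK = 0.05, Mono = 0.08,
            Bcell = 0.05, Neu = 0.54)
  m <- matrix(base, n, 6, byrow = TRUE,
              dimnames = list(NULL, names(base)))
  if (confound) {
    dev <- ages - mean(range(ages))
    m[, "Neu"] <- m[, "Neu"] + 0.0025 * dev
    m[, "CD4T"] <- m[, "CD4T"] - 0.0015 * dev
    m[, "CD8T"] <- m[, "CD8T"] - 0.0010 * dev
  }
  m <- pmax(m, 0.005)
  out <- matrix(0, n, 6, dimnames = list(NULL, names(base)))
  for (i in seq_len(n)) {
    g <- stats::rgamma(6, shape = m[i, ] * concentration)
    out[i, ] <- g / sum(g)
  }
  out
}

#' Simulate expression coupled to methylation ground truth
#'
#' For every non-null probe in the cohort's ground truth a linked gene is
#' generated whose expression is anti-correlated with the probe's beta
#' (hypermethylation with repressed expression, hypomethylation with
#' activated expression), plus unlinked noise genes. A candidate-gene table
#' (the 10 nearest genes up- and downstream, by signed rank distance) is
#' built per linked probe with the true gene at a random rank, as input for
#' [probeGenePairs()].
#'
#' @param ms a [MethylSet-class] from [simulateCohort()].
#' @param coupling non-negative effect size; expression of a linked gene is
#'   `baseline - coupling * scale(beta) + noise`. `coupling = 0` decouples
#'   everything.
#' @param noiseSd expression noise SD.
#' @param nNoiseGenes number of unlinked genes.
#' @param candidatesPerProbe candidate genes per probe (max 20: ranks
#'   -10..10 excluding 0).
#' @param seed RNG seed.
#' @return list with `expr` (genes x samples matrix), `links` (data.frame
#'   probe/gene), and `geneOrder` (data.frame probe/gene/rankDistance).
#' @export
simulateExpression <- function(ms, coupling = 1, noiseSd = 0.3,
                               nNoiseGenes = 200, candidatesPerProbe = 20,
                               seed = 1L) {
  if (!is.finite(coupling)) stop("coupling must be finite")
  ann <- probeAnnotation(ms)
  linked <- which(!is.na(ann$linkedGene))
  if (!length(linked) && coupling != 0)
    stop("cohort has no linked probes but coupling != 0")
  if (candidatesPerProbe > 20)
    stop("at most 20 candidate genes per probe (ranks -10..10)")
  set.seed(as.integer(seed))
  b <- betaValues(ms)
  n <- ncol(b)
  genes <- c(ann$linkedGene[linked], sprintf("NG%04d", seq_len(nNoiseGenes)))
  expr <- matrix(stats::rnorm(length(genes) * n, 8, 1), length(genes), n,
                 dimnames = list(genes, colnames(b)))
  for (j in seq_along(linked)) {
    z <- as.numeric(scale(b[linked[j], ]))
    if (any(!is.finite(z))) z <- rep(0, n)  # constant probe
    expr[j, ] <- 8 - coupling * z +
      if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
  }
  links <- data.frame(probe = rownames(b)[linked],
                      gene = ann$linkedGene[linked],
                      stringsAsFactors = FALSE)
  ranks <- setdiff(-10:10, 0)
  noisePool <- sprintf("NG%04d", seq_len(nNoiseGenes))
  geneOrder <- do.call(rbind, lapply(seq_len(nrow(links)), function(i) {
    rk <- sort(sample(ranks, candidatesPerProbe))
    cand <- sample(noisePool, candidatesPerProbe)
    cand[sample.int(candidatesPerProbe, 1L)] <- links$gene[i]
    data.frame(probe = links$probe[i], gene = cand, rankDistance = rk,
               stringsAsFactors = FALSE)
  }))
  list(expr = expr, links = links, geneOrder = geneOrder)
}

#' Simulate a purified cell-type methylation reference
#'
#' Builds a marker-probe x cell-type beta matrix with block structure: each
#' cell type carries a block of markers hypermethylated in that type and
#' hypomethylated elsewhere. With `k = 6` the columns are named after the
#' six blood leukocyte types resolved by reference-based deconvolution
#' (CD8T, CD4T, NK, Mono, Bcell, Neu).
#'
#' @param k number of cell types (>= 2).
#' @param nMarkers number of marker probes (>= k).
#' @param hi,lo in-type / out-of-type marker beta levels.
#' @param seed RNG seed (used only when `jitterSd > 0`).
#' @param jitterSd optional Gaussian jitter on the reference profiles.
#' @return numeric matrix, markers x cell types, values in \[0, 1\].
#' @export
simulateCellReference <- function(k = 6, nMarkers = 10 * k, hi = 0.85,
                                  lo = 0.10, seed = 1L, jitterSd = 0) {
  if (k < 2) stop("k must be >= 2")
  if (nMarkers < k) stop("need at least k marker probes")
  set.seed(as.integer(seed))
  types <- if (k == 6) BLOOD_CELL_TYPES else paste0("Cell", seq_len(k))
  ref <- matrix(lo, nMarkers, k,
                dimnames = list(sprintf("mk%05d", seq_len(nMarkers)), types))
  block <- rep(seq_len(k), length.out = nMarkers)
  for (j in seq_len(k)) ref[block == j, j] <- hi
  if (jitterSd > 0)
    ref <- ref + matrix(stats::rnorm(length(ref), 0, jitterSd),
                        nrow(ref), ncol(ref))
  pmin(pmax(ref, 0), 1)
}

#' Simulate mixed samples from a cell reference with known proportions
#'
#' @param ref reference matrix from [simulateCellReference()].
#' @param nMixtures number of mixed samples.
#' @param noiseSd beta-scale noise added to the mixtures.
#' @param seed RNG seed.
#' @return list with `beta` (markers x mixtures) and `proportions`
#'   (mixtures x cell types, rows sum to 1).
#' @export
simulateMixtures <- function(ref, nMixtures = 50, noiseSd = 0.02, seed = 1L) {
  set.seed(as.integer(seed))
  k <- ncol(ref)
  props <- t(vapply(seq_len(nMixtures), function(i) {
    g <- stats::rgamma(k, shape = 2)
    g / sum(g)
  }, numeric(k)))
  colnames(props) <- colnames(ref)
  beta <- ref %*% t(props)
  if (noiseSd > 0)
    beta <- beta + matrix(stats::rnorm(length(beta), 0, noiseSd),
                          nrow(beta), ncol(beta))
  beta <- pmin(pmax(beta, 0), 1)
  colnames(beta) <- sprintf("mix%04d", seq_len(nMixtures))
  list(beta = beta, proportions = props)
}

#' Simulate a motif-occurrence table with planted enrichment
#'
#' Builds the motif x probe occurrence table consumed by
#' [motifEnrichment()]: every motif occurs near background probes at a base
#' rate, and a designated subset of motifs occurs at an elevated rate near
#' the probes of `enrichedIn`, planting known enrichment.
#'
#' @param background all eligible probe ids.
#' @param enrichedIn probe subset in which the first `nEnriched` motifs are
#'   enriched.
#' @param nMotifs total motifs.
#' @param nEnriched motifs with planted enrichment.
#' @param baseRate occurrence probability near a background probe.
#' @param enrichedRate occurrence probability near an `enrichedIn` probe for
#'   enriched motifs.
#' @param seed RNG seed.
#' @return list with `table` (data.frame motif / probe) and `enriched`
#'   (motif ids with planted enrichment).
#' @export
simulateMotifTable <- function(background, enrichedIn, nMotifs = 30,
                               nEnriched = 5, baseRate = 0.05,
                               enrichedRate = 0.45, seed = 1L) {
  stopifnot(all(enrichedIn %in% background), nEnriched <= nMotifs)
  set.seed(as.integer(seed))
  motifs <- sprintf("MOTIF%03d", seq_len(nMotifs))
  rows <- lapply(seq_len(nMotifs), function(i) {
    rate <- ifelse(background %in% enrichedIn & i <= nEnriched,
                   enrichedRate, baseRate)
    hit <- background[stats::runif(length(background)) < rate]
    if (!length(hit)) return(NULL)
    data.frame(motif = motifs[i], probe = hit, stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), enriched = motifs[seq_len(nEnriched)])
}

#' Simulate an abundance matrix with planted group shifts
#'
#' Log-normal protein/metabolite-style abundances for two sample groups with
#' a planted log2 fold change in a known subset of features, plus optional
#' missingness; used to exercise the differential-omics contract against
#' known truth.
#'
#' @param nFeatures total features.
#' @param groupSizes integer length-2, samples per group.
#' @param nShift number of features with a true shift.
#' @param lfc true log2 fold change of shifted features (group 1 vs group 2).
#' @param cvNoise coefficient-of-variation-scale log-normal noise SD.
#' @param missingRate independent missingness probability per cell.
#' @param seed RNG seed.
#' @return list with `abundance` (features x samples), `groups` (factor) and
#'   `shifted` (feature names with a planted effect).
#' @export
simulateAbundances <- function(nFeatures = 300, groupSizes = c(20, 20),
                               nShift = 30, lfc = 1.5, cvNoise = 0.25,
                               missingRate = 0.1, seed = 1L) {
  set.seed(as.integer(seed))
  n <- sum(groupSizes)
  groups <- factor(rep(c("accelerator", "decelerator"), groupSizes),
                   levels = c("accelerator", "decelerator"))
  baseMean <- stats::runif(nFeatures, 4, 10)   # log2 scale
  logAb <- matrix(baseMean, nFeatures, n) +
    matrix(stats::rnorm(nFeatures * n, 0, cvNoise), nFeatures, n)
  shifted <- sample.int(nFeatures, nShift)
  logAb[shifted, groups == "accelerator"] <-
    logAb[shifted, groups == "accelerator"] + lfc
  ab <- 2^logAb
  if (missingRate > 0)
    ab[matrix(stats::runif(length(ab)) < missingRate, nFeatures, n)] <- NA
  dimnames(ab) <- list(sprintf("feat%04d", seq_len(nFeatures)),
                       sprintf("S%04d", seq_len(n)))
  list(abundance = ab, groups = groups,
       shifted = rownames(ab)[sort(shifted)])
}
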