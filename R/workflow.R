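#' Default pipeline configuration
#'
#' All tunables of the analysis with their defaults: the DMP gates
#' (|slope| > 0.002 beta/year, BH-adjusted p < 0.01), the sliding-window
#' settings (5-year window in 5-year parcels, BH p < 0.05), the
#' extreme-group fraction (0.20), the elastic-net alpha grid (0.1..0.9) and
#' 10 CV folds, the pace-group fraction (0.20), the motif gates
#' (count >= 10, CI lower > 1.1, BH p < 0.05), and the differential-omics
#' gates (detection > 2/3, p < 0.05, |log2FC| > 0.5).
#'
#' @return nested list of defaults; see [validateConfig()].
#' @export
epiageDefaults <- function() {
  list(
    outDir = "epiage_run",
    stages = list(simulate = TRUE, methylome = TRUE, dmp = TRUE,
                  integrate = TRUE, clocks = TRUE, pace = TRUE),
    seeds = list(simulate = 101L, expression = 102L, pairs = 103L,
                 split = 104L, clock = 105L, motifs = 106L, omics = 107L),
    simulate = list(nSamples = 250L, nProbes = 5000L, ageRange = c(20, 87),
                    fracUp = 0.05, fracDown = 0.10,
                    slopeRange = c(0.002, 0.008), noiseSd = 0.03,
                    confoundCells = TRUE),
    thresholds = list(slopeThreshold = 0.002, dmpAlpha = 0.01,
                      windowAlpha = 0.05, window = 5, parcel = 5,
                      q = 0.20, empAlpha = 0.05, nPerm = 200L,
                      minCount = 10L, orLower = 1.1, pCut = 0.05,
                      lfcCut = 0.5, detectFrac = 2 / 3),
    clock = list(alphaGrid = seq(0.1, 0.9, 0.1), cvFolds = 10L,
                 fracTrain = 0.5, adultAge = 20,
                 multimodal = list(enabled = TRUE, maxSamples = 30L,
                                   alphaGrid = c(0.2, 0.5, 0.8))),
    inputs = list(beta = NULL, samples = NULL, annotation = NULL,
                  expression = NULL, motifs = NULL, reference = NULL)
  )
}

# recursive merge of user values over defaults; unknown keys are an error
.mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

.checkRange <- function(value, key, lo, hi, loOpen = TRUE, hiOpen = FALSE) {
  bad <- any(!is.finite(value)) ||
    any(if (loOpen) value <= lo else value < lo) ||
    any(if (hiOpen) value >= hi else value > hi)
  if (bad)
    stop(sprintf("config key '%s' = %s out of range %s%g, %g%s", key,
                 paste(signif(value, 4), collapse = ","),
                 if (loOpen) "(" else "[", lo, hi,
                 if (hiOpen) ")" else "]"))
  invisible(TRUE)
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills in [epiageDefaults()],
#' rejects unknown keys, range-checks every threshold (naming the offending
#' key and its allowed range), and checks that referenced input files
#' exist.
#'
#' @param config YAML path, nested list, or `NULL` (pure defaults).
#' @return the validated, fully defaulted config list.
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .mergeConfig(epiageDefaults(), config)
  th <- cfg$thresholds
  .checkRange(th$slopeThreshold, "thresholds.slopeThreshold", 0, 0.05)
  .checkRange(th$dmpAlpha, "thresholds.dmpAlpha", 0, 1)
  .checkRange(th$windowAlpha, "thresholds.windowAlpha", 0, 1)
  .checkRange(th$q, "thresholds.q", 0, 0.5)
  .checkRange(th$empAlpha, "thresholds.empAlpha", 0, 1)
  .checkRange(th$window, "thresholds.window", 0, 50)
  .checkRange(th$parcel, "thresholds.parcel", 0, 50)
  .checkRange(th$orLower, "thresholds.orLower", 0, 100)
  .checkRange(th$pCut, "thresholds.pCut", 0, 1)
  .checkRange(th$lfcCut, "thresholds.lfcCut", 0, 10, loOpen = FALSE)
  .checkRange(th$detectFrac, "thresholds.detectFrac", 0, 1, loOpen = FALSE)
  .checkRange(cfg$clock$alphaGrid, "clock.alphaGrid", 0, 1)
  .checkRange(cfg$clock$fracTrain, "clock.fracTrain", 0, 1, hiOpen = TRUE)
  if (cfg$clock$cvFolds < 3) stop("config key 'clock.cvFolds' must be >= 3")
  sim <- cfg$simulate
  if (sim$ageRange[1] >= sim$ageRange[2])
    stop("config key 'simulate.ageRange' must satisfy lo < hi")
  .checkRange(sim$fracUp + sim$fracDown, "simulate.fracUp + fracDown",
              0, 1, loOpen = FALSE)
  .checkRange(sim$slopeRange, "simulate.slopeRange", 0, 0.02)
  .checkRange(sim$noiseSd, "simulate.noiseSd", 0, 1, loOpen = FALSE)
  for (k in names(cfg$inputs)) {
    f <- cfg$inputs[[k]]
    if (!is.null(f) && !file.exists(f))
      stop(sprintf("config input '%s' does not exist: %s", k, f))
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load
#' inputs), methylome summaries, DMP calling + density + sliding windows,
#' methylome-transcriptome integration, clock training (chronological,
#' stepwise panel, multi-modal LOO), and pace stratification with
#' differential comparisons — writing fixed-name CSV/TSV/JSON outputs under
#' the run directory plus a `manifest.json` (config hash, seeds, package
#' version, per-output row counts). Identical config and seeds give
#' byte-identical outputs.
#'
#' @param config validated config (or anything [validateConfig()] accepts).
#' @param outDir overrides `config$outDir`.
#' @return the manifest, invisibly. Output files are documented in the
#'   README.
#' @export
runPipeline <- function(config = NULL, outDir = NULL) {
  cfg <- validateConfig(config)
  if (!is.null(outDir)) cfg$outDir <- outDir
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outDir, f)
  manifest <- list(package = "epiage",
                   version = as.character(utils::packageVersion("epiage")),
                   seeds = cfg$seeds, stages = list(), rowCounts = list())
  th <- cfg$thresholds

  # the hash covers effective analysis settings; the output location is not one
  canonical <- out("config.yaml")
  hashable <- cfg
  hashable$outDir <- NULL
  yaml::write_yaml(hashable, canonical)
  manifest$configHash <- unname(tools::md5sum(canonical))

  fail <- function(stage, err) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(err)),
               out("FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(err)))
  }

  ## --- simulate / load -----------------------------------------------
  ms <- NULL; exprSim <- NULL
  if (isTRUE(cfg$stages$simulate) && is.null(cfg$inputs$beta)) {
    tryCatch({
      sim <- cfg$simulate
      ms <- simulateCohort(nSamples = sim$nSamples, nProbes = sim$nProbes,
                           ageRange = sim$ageRange, fracUp = sim$fracUp,
                           fracDown = sim$fracDown,
                           slopeRange = sim$slopeRange,
                           noiseSd = sim$noiseSd,
                           confoundCells = sim$confoundCells,
                           seed = cfg$seeds$simulate)
      writeBetaMatrix(ms, out("beta.tsv"))
      writeSampleTable(sampleData(ms), out("samples.csv"))
      ann <- probeAnnotation(ms)
      writeProbeAnnotation(ann[, c("chrom", "pos", "gene", "islandClass",
                                   "featureClass", "distalFlag")],
                           out("annotation.csv"))
      writeProbeAnnotation(ann[, c("trueSlope", "trueClass", "cellDriven",
                                   "cellType", "linkedGene")],
                           out("ground_truth.csv"))
      if (isTRUE(cfg$stages$integrate)) {
        exprSim <- simulateExpression(ms, seed = cfg$seeds$expression)
        writeExpressionMatrix(exprSim$expr, out("expression.tsv"))
        data.table::fwrite(exprSim$geneOrder, out("gene_order.csv"))
      }
      manifest$stages$simulate <- "done"
      manifest$rowCounts$beta <- nrow(ms)
    }, error = function(e) fail("simulate", e))
  } else {
    tryCatch({
      ms <- readMethylSet(cfg$inputs$beta, cfg$inputs$samples,
                          cfg$inputs$annotation)
      manifest$stages$simulate <- "skipped (inputs supplied)"
    }, error = function(e) fail("load", e))
  }

  ## --- methylome ------------------------------------------------------
  if (isTRUE(cfg$stages$methylome)) {
    tryCatch({
      summ <- data.frame(sample = colnames(ms),
                         meanMethylation = unname(meanMethylation(ms)),
                         entropy = unname(methylationEntropy(ms)))
      data.table::fwrite(summ, out("methylome_summary.csv"))
      sd <- sampleData(ms)
      cellCols <- intersect(BLOOD_CELL_TYPES, colnames(sd))
      if (!is.null(cfg$inputs$reference)) {
        refDt <- data.table::fread(cfg$inputs$reference, header = TRUE)
        ref <- as.matrix(refDt[, -1])
        rownames(ref) <- refDt[[1]]
        props <- estimateCellProportions(ms, ref)
        data.table::fwrite(data.frame(sample = rownames(props), props),
                           out("cell_proportions.csv"))
      } else if (length(cellCols)) {
        data.table::fwrite(data.frame(sample = colnames(ms),
                                      sd[, cellCols, drop = FALSE]),
                           out("cell_proportions.csv"))
      }
      manifest$stages$methylome <- "done"
      manifest$rowCounts$methylome_summary <- nrow(summ)
    }, error = function(e) fail("methylome", e))
  }

  ## --- dmp ------------------------------------------------------------
  dmps <- NULL; fits <- NULL
  if (isTRUE(cfg$stages$dmp)) {
    tryCatch({
      sd <- sampleData(ms)
      # proportions sum to 1, so one cell type (Neu) is the reference level
      covars <- intersect(c("sex", "bmi", setdiff(BLOOD_CELL_TYPES, "Neu")),
                          colnames(sd))
      fits <- fitSiteModels(ms, covariates = covars)
      dmps <- callDmps(fits, annot = probeAnnotation(ms),
                       slopeThreshold = th$slopeThreshold,
                       alpha = th$dmpAlpha)
      data.table::fwrite(dmps, out("dmps.csv"))
      comp <- contextComposition(dmps)
      data.table::fwrite(comp, out("context_composition.csv"))
      dens <- genomicDensity(dmps)
      data.table::fwrite(dens$bins, out("genomic_density.csv"))
      win <- slidingWindowDmp(ms, window = th$window, parcel = th$parcel,
                              alpha = th$windowAlpha)
      data.table::fwrite(win, out("windows.csv"))
      manifest$stages$dmp <- "done"
      manifest$rowCounts$dmps <- sum(dmps$direction != "ns")
      manifest$rowCounts$windows <- nrow(win)
    }, error = function(e) fail("dmp", e))
  }

  ## --- integrate ------------------------------------------------------
  if (isTRUE(cfg$stages$integrate) && !is.null(dmps)) {
    tryCatch({
      expr <- if (!is.null(cfg$inputs$expression))
        readExpressionMatrix(cfg$inputs$expression) else exprSim$expr
      geneOrder <- if (!is.null(exprSim)) exprSim$geneOrder else NULL
      if (!is.null(expr) && !is.null(geneOrder)) {
        feat <- selectFeatureProbes(dmps)
        pairs <- probeGenePairs(ms, expr, geneOrder, feat,
                                q = th$q, nPerm = th$nPerm,
                                seed = cfg$seeds$pairs,
                                empAlpha = th$empAlpha)
        data.table::fwrite(pairs, out("probe_gene_pairs.csv"))
        manifest$rowCounts$probe_gene_pairs <- nrow(pairs)

        upProbes <- feat$probe[feat$direction == "up"]
        motifs <- if (!is.null(cfg$inputs$motifs))
          list(table = as.data.frame(data.table::fread(cfg$inputs$motifs)))
        else simulateMotifTable(dmps$probe, upProbes,
                                seed = cfg$seeds$motifs)
        enr <- motifEnrichment(upProbes, motifs$table, dmps$probe,
                               minCount = th$minCount,
                               orLower = th$orLower, alpha = th$pCut,
                               allResults = TRUE)
        data.table::fwrite(enr, out("motif_enrichment.csv"))
        manifest$rowCounts$enriched_motifs <- sum(enr$enriched)

        hit <- enr$motif[enr$enriched]
        if (length(hit)) {
          tfRows <- lapply(utils::head(hit, 3), function(m) {
            pr <- intersect(motifs$table$probe[motifs$table$motif == m],
                            rownames(ms))
            tf <- rownames(expr)[startsWith(rownames(expr), "NG")][1]
            ct <- tfMethylationCorrelation(ms, expr, pr, tf)
            data.frame(motif = m, tfGene = tf, r = ct$r, p = ct$p,
                       n = ct$n)
          })
          data.table::fwrite(do.call(rbind, tfRows),
                             out("tf_correlation.csv"))
        }
      }
      manifest$stages$integrate <- "done"
    }, error = function(e) fail("integrate", e))
  }

  ## --- clocks ---------------------------------------------------------
  paceInput <- NULL
  if (isTRUE(cfg$stages$clocks)) {
    tryCatch({
      sd <- sampleData(ms)
      targets <- stats::setNames(sd$age, colnames(ms))
      split <- stratifiedSplit(ms, fracTrain = cfg$clock$fracTrain,
                               seed = cfg$seeds$split)
      model <- trainClock(ms, targets, split,
                          alphaGrid = cfg$clock$alphaGrid,
                          nFolds = cfg$clock$cvFolds,
                          adultAge = cfg$clock$adultAge,
                          seed = cfg$seeds$clock)
      writeClockModel(model, out("clock_model.json"))
      preds <- predictAge(model, ms[, split$validation])
      ev <- evaluateClock(preds, targets[split$validation])
      data.table::fwrite(
        data.frame(sample = split$validation, predicted = unname(preds),
                   chronological = unname(targets[split$validation])),
        out("clock_predictions.csv"))
      manifest$stages$clocks <- "done"
      manifest$rowCounts$clock_cpgs <- clockSize(model)
      manifest$clockValidation <- list(r = ev$r, mae = ev$mae)
      paceInput <- data.frame(sample = split$validation,
                              predicted = unname(preds),
                              chronological = unname(targets[split$validation]))

      # compact panel: stepwise reduction from the top age-associated CpGs
      if (!is.null(fits)) {
        top <- fits$probe[order(-abs(fits$t))][1:12]
        panel <- stepwiseReduce(ms[, split$train], targets[split$train],
                                top, stopK = 5)
        writeClockModel(panel, out("clock_5cpg.json"))
      }

      mm <- cfg$clock$multimodal
      if (isTRUE(mm$enabled) && "compositeAge" %in% colnames(sd)) {
        tgt <- stats::setNames(sd$compositeAge, colnames(ms))
        tgt <- tgt[!is.na(tgt)]
        if (length(tgt) > mm$maxSamples)
          tgt <- tgt[seq_len(mm$maxSamples)]
        mmFit <- trainMultimodalClock(ms, tgt, alphaGrid = mm$alphaGrid,
                                      nFolds = min(5L, length(tgt) - 1L),
                                      seed = cfg$seeds$clock,
                                      name = "composite")
        writeClockModel(mmFit$model, out("clock_multimodal.json"))
        manifest$multimodalValidation <- list(r = mmFit$evaluation$r,
                                              mae = mmFit$evaluation$mae)
      }
    }, error = function(e) fail("clocks", e))
  }

  ## --- pace -----------------------------------------------------------
  if (isTRUE(cfg$stages$pace) && !is.null(paceInput)) {
    tryCatch({
      pace <- computeAgePace(paceInput$predicted, paceInput$chronological,
                             paceInput$sample)
      pace <- classifyPaceGroups(pace, q = th$q)
      data.table::fwrite(pace, out("pace.csv"))
      sd <- sampleData(ms)[pace$sample, , drop = FALSE]
      num <- compareNumericFeatures(sd[, "bmi", drop = FALSE], pace$group,
                                    pCut = th$pCut)
      bin <- compareBinaryFeatures(sd[, "sex", drop = FALSE], pace$group,
                                   pCut = th$pCut)
      data.table::fwrite(rbind(num[, c("feature", "modality", "effect",
                                       "p", "significant", "test")],
                               bin[, c("feature", "modality", "effect",
                                       "p", "significant", "test")]),
                         out("pace_phenotypes.csv"))
      nAcc <- sum(pace$group == "accelerator")
      nDec <- sum(pace$group == "decelerator")
      om <- simulateAbundances(groupSizes = c(nAcc, nDec),
                               seed = cfg$seeds$omics)
      diffOm <- differentialOmics(om$abundance, om$groups,
                                  detectFrac = th$detectFrac,
                                  pCut = th$pCut, lfcCut = th$lfcCut)
      data.table::fwrite(diffOm, out("pace_proteins.csv"))
      manifest$stages$pace <- "done"
      manifest$rowCounts$accelerators <- nAcc
      manifest$rowCounts$decelerators <- nDec
    }, error = function(e) fail("pace", e))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
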