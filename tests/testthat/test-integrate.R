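test_that("feature-probe selection applies the distal-or-promoter rule", {
  dmps <- data.frame(probe = paste0("p", 1:6),
                     direction = c("up", "up", "down", "down", "up", "ns"),
                     distalFlag = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
                     featureClass = c("Body", "Body", "TSS200", "IGR",
                                      "TSS1500", "TSS200"))
  sel <- selectFeatureProbes(dmps)
  # Body+non-distal excluded; TSS200/TSS1500/distal included; ns excluded
  expect_identical(sel$probe, c("p2", "p3", "p4", "p5"))
})

test_that("extreme-group rank-sum test matches exhaustive enumeration", {
  set.seed(61)
  n <- 20
  beta <- sort(runif(n))                       # distinct, ordered
  expr <- 10 - 3 * beta + rnorm(n, 0, 0.01)    # near-perfect anti-correlation
  names(beta) <- names(expr) <- sprintf("s%02d", 1:n)
  et <- extremeGroupTest(beta, expr, q = 0.2)
  expect_length(et$idxM, 4)
  expect_length(et$idxU, 4)

  # enumerate all C(8,4) = 70 labelings of the 8 extreme samples
  pool <- c(et$idxM, et$idxU)
  vals <- expr[pool]
  combos <- combn(8, 4)
  Wof <- function(mIdx) {
    r <- rank(vals)
    sum(r[mIdx]) - 4 * 5 / 2
  }
  Wobs <- Wof(match(et$idxM, pool))
  Wnull <- apply(combos, 2, Wof)
  pEnum <- mean(Wnull <= Wobs)
  expect_equal(et$statistic, Wobs)
  expect_equal(et$p, pEnum, tolerance = 1e-12)
  expect_equal(pEnum, 1 / 70)                 # minimal achievable for 4 vs 4

  # swapping M and U flips the one-sided direction exactly
  pSwap <- suppressWarnings(
    wilcox.test(expr[et$idxU], expr[et$idxM],
                alternative = "greater"))$p.value
  expect_equal(et$p, pSwap)
})

test_that("empirical p uses the add-one rule and converges to enumeration", {
  expect_equal(empiricalP(0.01, c(0.5, 0.2, 0.005)), 2 / 4)
  expect_gt(empiricalP(1, rep(0.5, 99)), 0)      # never zero
  # with the full enumeration as the null, empirical p equals the exact p
  nullP <- (1:69) / 70
  expect_equal(empiricalP(1 / 70, nullP), (1 + sum(nullP <= 1 / 70)) / 70)
})

test_that("probe-gene pairing recovers planted links and rejects flat genes", {
  hits <- falsePos <- trueTested <- nullTested <- 0
  for (s in 1:5) {
    ms <- suppressMessages(
      simulateCohort(nSamples = 100, nProbes = 100, fracUp = 0.10,
                     fracDown = 0.10, noiseSd = 0.02, seed = 100 + s))
    ex <- simulateExpression(ms, coupling = 1.5, noiseSd = 0.2,
                             nNoiseGenes = 300, seed = 200 + s)
    fits <- fitSiteModels(ms, covariates = c("sex", "bmi"))
    dmps <- callDmps(fits, annot = probeAnnotation(ms))
    pairs <- probeGenePairs(ms, ex$expr, ex$geneOrder, dmps, nPerm = 200,
                            seed = 300 + s, returnAll = TRUE)
    truth <- paste(ex$links$probe, ex$links$gene)
    tested <- paste(pairs$probe, pairs$gene)
    isTrue <- tested %in% truth
    hits <- hits + sum(pairs$significant[isTrue])
    trueTested <- trueTested + sum(isTrue)
    falsePos <- falsePos + sum(pairs$significant[!isTrue])
    nullTested <- nullTested + sum(!isTrue)
  }
  expect_gt(hits / trueTested, 0.8)        # sensitivity for planted links
  expect_lt(falsePos / nullTested, 0.1)    # false pair rate among null pairs
})

test_that("pairs with expression identical in M and U are rejected", {
  set.seed(71)
  n <- 40
  beta <- matrix(sort(runif(n)), 1, n,
                 dimnames = list("cg1", sprintf("s%02d", 1:n)))
  expr <- matrix(rep(c(2, 9), n / 2), 2, n, byrow = FALSE,
                 dimnames = list(c("gFlat", "gRand"), colnames(beta)))
  expr["gFlat", ] <- rep(5, n)              # constant: skipped with message
  expr["gRand", ] <- rnorm(n)
  ms <- tinyMethylSet(beta)
  geneOrder <- data.frame(probe = "cg1", gene = c("gFlat", "gRand"),
                          rankDistance = c(-1, 1))
  dmps <- data.frame(probe = "cg1", direction = "up")
  expect_message(
    pairs <- probeGenePairs(ms, expr, geneOrder, dmps, nPerm = 50,
                            seed = 1, returnAll = TRUE),
    "constant expression")
  expect_false("gFlat" %in% pairs$gene)
  # same-distribution gene: one-sided p should not be extreme
  expect_gt(pairs$rawP[pairs$gene == "gRand"], 0.01)
})

test_that("motif enrichment matches a direct exact-test oracle", {
  background <- sprintf("p%04d", 1:1000)
  inSet <- background[1:100]
  withMotif <- c(inSet[1:30], background[101:120])   # 30/100 vs 20/900
  motifTable <- data.frame(motif = "M1", probe = withMotif)
  res <- motifEnrichment(inSet, motifTable, background, allResults = TRUE)
  orOracle <- (30 * 880) / (70 * 20)
  seOracle <- sqrt(1 / 30 + 1 / 70 + 1 / 20 + 1 / 880)
  pOracle <- fisher.test(matrix(c(30, 70, 20, 880), 2, byrow = TRUE))$p.value
  expect_equal(res$oddsRatio, orOracle, tolerance = 1e-12)
  expect_equal(res$ciLower, exp(log(orOracle) - qnorm(0.975) * seOracle),
               tolerance = 1e-12)
  expect_equal(res$p, pOracle, tolerance = 1e-12)
  expect_true(res$enriched)
})

test_that("motif gates reject low counts, flat odds and out-of-set motifs", {
  background <- sprintf("p%04d", 1:500)
  inSet <- background[1:50]
  ubiq <- data.frame(motif = "ALL", probe = background)       # OR = 1
  rare <- data.frame(motif = "RARE", probe = inSet[1:9])      # count 9, huge OR
  tab <- rbind(ubiq, rare)
  res <- motifEnrichment(inSet, tab, background, allResults = TRUE)
  expect_equal(res$oddsRatio[res$motif == "ALL"], 1)
  expect_false(res$enriched[res$motif == "ALL"])
  expect_false(res$enriched[res$motif == "RARE"])   # min_count gate
  expect_gt(res$oddsRatio[res$motif == "RARE"], 1.1)
  # invariance to motif row order
  res2 <- motifEnrichment(inSet, tab[rev(seq_len(nrow(tab))), ],
                          background, allResults = TRUE)
  expect_equal(res[order(res$motif), ], res2[order(res2$motif), ],
               ignore_attr = TRUE)
  expect_error(motifEnrichment(c(inSet, "pXXXX"), tab, background), "subset")
})

test_that("TF-methylation correlation matches the definitional formula", {
  set.seed(81)
  n <- 50
  beta <- matrix(runif(3 * n), 3, n,
                 dimnames = list(paste0("cg", 1:3), sprintf("s%02d", 1:n)))
  ms <- tinyMethylSet(beta)
  mB <- colMeans(beta)
  expr <- rbind(TF1 = -mB, TF2 = rnorm(n))
  colnames(expr) <- colnames(beta)
  ct <- tfMethylationCorrelation(ms, expr, paste0("cg", 1:3), "TF1")
  expect_equal(ct$r, -1, tolerance = 1e-12)
  expect_lt(ct$p, 1e-10)
  # textbook formula oracle
  ct2 <- tfMethylationCorrelation(ms, expr, paste0("cg", 1:3), "TF2")
  rOracle <- sum((mB - mean(mB)) * (expr["TF2", ] - mean(expr["TF2", ]))) /
    sqrt(sum((mB - mean(mB))^2) * sum((expr["TF2", ] - mean(expr["TF2", ]))^2))
  expect_equal(ct2$r, rOracle, tolerance = 1e-12)
})

test_that("TF correlation on independent noise is usually unremarkable", {
  flags <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 100
    beta <- matrix(runif(2 * n), 2, n,
                   dimnames = list(c("a", "b"), sprintf("s%03d", 1:n)))
    expr <- matrix(rnorm(n), 1, n, dimnames = list("TF", colnames(beta)))
    ct <- tfMethylationCorrelation(tinyMethylSet(beta), expr,
                                   c("a", "b"), "TF")
    abs(ct$r) < 0.3 && ct$p > 0.001
  }, logical(1))
  expect_gte(sum(flags), 19)
})
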