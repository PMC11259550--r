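test_that("noiseless linear probes are fit exactly", {
  ages <- seq(20, 80, length.out = 30)
  beta <- matrix(0.3 + 0.002 * ages, 1, 30,
                 dimnames = list("cg1", sprintf("s%02d", 1:30)))
  ms <- tinyMethylSet(beta, ages = ages)
  fit <- fitSiteModels(ms)
  expect_equal(fit$slope, 0.002, tolerance = 1e-12)
  expect_lt(fit$p, 1e-12)
})

test_that("site models agree with an independent normal-equations oracle", {
  set.seed(31)
  n <- 60
  ages <- runif(n, 20, 87)
  sex <- rbinom(n, 1, 0.5)
  bmi <- rnorm(n, 24, 3)
  beta <- matrix(runif(20 * n, 0.2, 0.8), 20, n,
                 dimnames = list(sprintf("cg%02d", 1:20),
                                 sprintf("s%02d", 1:n)))
  ms <- tinyMethylSet(beta, ages = ages, sex = sex, bmi = bmi)
  fit <- fitSiteModels(ms, covariates = c("sex", "bmi"))
  X <- cbind(1, ages, sex, bmi)
  for (i in 1:20) {
    o <- olsOracle(beta[i, ], X)
    expect_equal(fit$slope[i], o$coef[2], tolerance = 1e-10)
    expect_equal(fit$se[i], o$se[2], tolerance = 1e-10)
    expect_equal(fit$t[i], o$t[2], tolerance = 1e-10)
    expect_equal(fit$p[i], o$p[2], tolerance = 1e-10)
  }
})

test_that("collinear designs and bad covariates are refused", {
  ms <- suppressMessages(simulateCohort(nSamples = 40, nProbes = 10, seed = 2))
  sd <- sampleData(ms)
  expect_error(fitSiteModels(ms, covariates = c("CD8T", "CD4T", "NK", "Mono",
                                                "Bcell", "Neu")),
               "collinear")
  expect_error(fitSiteModels(ms, covariates = "notAColumn"), "not found")
})

test_that("DMP gates apply effect size and significance jointly", {
  fits <- data.frame(probe = c("a", "b", "c", "d"),
                     slope = c(0.001, 0.003, 0.005, -0.004),
                     se = 1e-4, t = 5,
                     p = c(1e-10, 0.5, 1e-8, 1e-9))
  dmps <- callDmps(fits, alpha = 0.01)
  # tiny slope: ns despite p ~ 0; big slope with p = 0.5: ns
  expect_identical(dmps$direction, c("ns", "ns", "up", "down"))
  expect_true(all(dmps$padj >= dmps$p))
  # BH monotone in raw-p rank
  ord <- order(dmps$p)
  expect_true(all(diff(dmps$padj[ord]) >= -1e-15))
  # invariance to row order
  shuf <- callDmps(fits[c(3, 1, 4, 2), ], alpha = 0.01)
  expect_identical(shuf$direction[order(shuf$probe)],
                   dmps$direction[order(dmps$probe)])
})

test_that("context composition proportions are per-direction and sum to 1", {
  dmps <- data.frame(probe = paste0("p", 1:6),
                     direction = c("up", "up", "up", "up", "down", "ns"),
                     islandClass = c("Island", "Island", "Island", "Island",
                                     "OpenSea", "Shore"),
                     featureClass = c("TSS200", "Body", "Body", "IGR",
                                      "Body", "Body"))
  comp <- contextComposition(dmps)
  up <- comp[comp$direction == "up", ]
  expect_equal(up$proportion[up$classType == "island" & up$class == "Island"], 1)
  expect_equal(up$proportion[up$classType == "feature" & up$class == "TSS200"],
               0.25)
  for (ct in c("island", "feature"))
    expect_equal(sum(up$proportion[up$classType == ct]), 1)
  solo <- dmps[dmps$direction == "up", ]
  expect_message(contextComposition(solo), "direction 'down'")
})

test_that("island-biased hypermethylation shows up in the composition", {
  ms <- suppressMessages(simulateCohort(nSamples = 150, nProbes = 1000,
                                        seed = 17))
  fits <- fitSiteModels(ms, covariates = c("sex", "bmi", "CD8T", "CD4T",
                                           "NK", "Mono", "Bcell"))
  dmps <- callDmps(fits, annot = probeAnnotation(ms))
  comp <- contextComposition(dmps)
  upIsland <- comp$proportion[comp$direction == "up" &
                                comp$classType == "island" &
                                comp$class == "Island"]
  matrixIsland <- mean(probeAnnotation(ms)$islandClass == "Island")
  expect_gt(upIsland, matrixIsland)
})

test_that("genomic density bins are half-open and partition the DMPs", {
  dmps <- data.frame(probe = c("a", "b", "c"), direction = "up",
                     chrom = "chr1", pos = c(10, 999999, 1000000))
  gd <- genomicDensity(dmps)
  expect_equal(gd$bins$count[gd$bins$binStart == 0], 2)
  expect_equal(gd$bins$count[gd$bins$binStart == 1e6], 1)
  expect_equal(sum(gd$bins$count), 3)
  expect_equal(unname(gd$chromTotals["chr1"]), 3L)
  # no DMPs -> empty table; missing positions are excluded with a message
  expect_equal(nrow(genomicDensity(dmps[0, ])$bins), 0)
  dmps$pos[1] <- NA
  expect_message(gd2 <- genomicDensity(dmps), "lack a position")
  expect_equal(sum(gd2$bins$count), 2)
})

test_that("uniform positions give multinomial-consistent bin counts", {
  set.seed(41)
  n <- 2000
  dmps <- data.frame(probe = paste0("p", 1:n), direction = "up",
                     chrom = "chr1",
                     pos = sample.int(20e6, n, replace = TRUE))
  gd <- genomicDensity(dmps)
  counts <- rep(0, 20)
  counts[gd$bins$binStart / 1e6 + 1] <- gd$bins$count
  gof <- chisq.test(counts, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)
})

test_that("sliding-window scan finds a planted change point", {
  set.seed(51)
  n <- 240
  ages <- runif(n, 20, 50)
  p <- 150
  beta <- matrix(runif(p * n, 0.3, 0.5), p, n,
                 dimnames = list(sprintf("cg%03d", 1:p),
                                 sprintf("s%03d", 1:n)))
  # 100 probes step up by 0.15 after age 35
  beta[1:100, ages >= 35] <- beta[1:100, ages >= 35] + 0.15
  ms <- tinyMethylSet(pmin(beta, 1), ages = ages)
  win <- slidingWindowDmp(ms, window = 5, parcel = 5, alpha = 0.05)
  expect_equal(win$center[which.max(win$total)], 35)
  peak <- win[win$center == 35, ]
  expect_gt(peak$up, peak$down)   # the step is upward
  expect_true(all(win$up + win$down == win$total))
})

test_that("sliding-window scan is quiet on null data and degenerate input", {
  counts <- vapply(1:8, function(s) {
    set.seed(s)
    n <- 150
    beta <- matrix(runif(100 * n, 0.3, 0.7), 100, n,
                   dimnames = list(sprintf("cg%03d", 1:100),
                                   sprintf("s%03d", 1:n)))
    ms <- tinyMethylSet(beta, ages = runif(n, 20, 60))
    mean(slidingWindowDmp(ms)$total)
  }, numeric(1))
  expect_lt(mean(counts), 2 * 0.05 * 100)
  # identical groups: zero variance everywhere -> count 0
  ms1 <- tinyMethylSet(matrix(0.5, 1, 40, dimnames = list("cg1", NULL)),
                       ages = rep(c(25, 35), each = 20))
  expect_equal(sum(slidingWindowDmp(ms1)$total), 0)
})
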