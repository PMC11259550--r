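test_that("age transform matches its printed definition and is invertible", {
  expect_equal(transformAge(20), 0)
  expect_equal(transformAge(41), 1)
  expect_equal(transformAge(9.5), log(10.5 / 21), tolerance = 1e-12)
  expect_equal(inverseTransformAge(0), 20)
  expect_equal(inverseTransformAge(1), 41)
  for (x in c(1, 19.99, 20, 55, 87))
    expect_equal(inverseTransformAge(transformAge(x)), x, tolerance = 1e-10)
  # continuity at the knot, both branches
  eps <- 1e-9
  expect_equal(transformAge(20 - eps), transformAge(20 + eps),
               tolerance = 1e-8)
  expect_error(transformAge(-1), "> -1")
  expect_error(inverseTransformAge(Inf), "finite")
})

test_that("stratified split halves the cohort within sex/age strata", {
  ms <- suppressMessages(simulateCohort(nSamples = 250, nProbes = 20,
                                        seed = 3))
  sp <- stratifiedSplit(ms, seed = 5)
  expect_length(sp$train, 125)
  expect_length(sp$validation, 125)
  expect_length(intersect(sp$train, sp$validation), 0)
  ageT <- sampleData(ms)[sp$train, "age"]
  ageV <- sampleData(ms)[sp$validation, "age"]
  expect_lt(abs(mean(ageT) - mean(ageV)), 4)
})

test_that("elastic-net clock recovers a planted linear age signal", {
  fx <- linearClockCohort(n = 200, p = 120, noiseSd = 0.02, seed = 91)
  sp <- stratifiedSplit(fx$ms, seed = 92)
  m <- trainClock(fx$ms, fx$ages, sp, alphaGrid = c(0.3, 0.6, 0.9),
                  seed = 93)
  ev <- evaluateClock(predictAge(m, fx$ms[, sp$validation]),
                      fx$ages[sp$validation])
  expect_lt(ev$mae, 1.0)
  expect_gt(ev$r, 0.99)
  expect_true(all(names(clockWeights(m)) %in% rownames(fx$ms)))
})

test_that("training refuses overlapping splits and non-finite targets", {
  fx <- linearClockCohort(n = 40, p = 20, seed = 94)
  ids <- colnames(fx$ms)
  expect_error(trainClock(fx$ms, fx$ages,
                          list(train = ids[1:25], validation = ids[20:40])),
               "disjoint")
  expect_error(trainClock(fx$ms, fx$ages,
                          list(train = ids[1:30], validation = character())),
               "empty")
  bad <- fx$ages; bad[1] <- NA
  expect_error(trainClock(fx$ms, bad,
                          list(train = ids[1:30], validation = ids[31:40])),
               "finite")
})

test_that("prediction composes the weight chain and imputes missing probes", {
  m <- new("ClockModel", name = "toy", transform = "horvath_piecewise",
           adultAge = 20, intercept = 0, weights = c(cgA = 21),
           trainingMeans = c(cgA = 0.5), meta = list())
  b <- matrix(1, 1, 1, dimnames = list("cgA", "s1"))
  expect_equal(unname(predictAge(m, b)), 21 * 21 + 20)
  # missing model probe: imputed from training mean, with a message
  b2 <- matrix(0.2, 1, 1, dimnames = list("cgOther", "s1"))
  m2 <- new("ClockModel", name = "toy2", transform = "identity",
            adultAge = 20, intercept = 1,
            weights = c(cgA = 2, cgOther = 1),
            trainingMeans = c(cgA = 0.5, cgOther = 0), meta = list())
  expect_message(p2 <- predictAge(m2, b2), "imputed")
  expect_equal(unname(p2), 1 + 2 * 0.5 + 1 * 0.2)
  # all probes missing: error
  b3 <- matrix(0.2, 1, 1, dimnames = list("cgZ", "s1"))
  expect_error(predictAge(m2, b3), "no model probes")
  # invariant to probe order and irrelevant probes
  set.seed(95)
  b4 <- matrix(runif(6), 3, 2, dimnames = list(c("x", "cgA", "cgOther"),
                                               c("s1", "s2")))
  expect_equal(predictAge(m2, b4), predictAge(m2, b4[c(3, 1, 2), ]))
})

test_that("clock evaluation matches hand-computed r and MAE", {
  truth <- c(30, 40, 50, 60)
  expect_equal(evaluateClock(truth, truth)$mae, 0)
  expect_equal(evaluateClock(truth, truth)$r, 1)
  ev <- evaluateClock(truth + 2, truth)
  expect_equal(ev$r, 1)
  expect_equal(ev$mae, 2)
  set.seed(96)
  pr <- rnorm(10); tr <- rnorm(10)
  expect_equal(evaluateClock(pr, tr)$mae, mean(abs(pr - tr)),
               tolerance = 1e-12)
  expect_warning(evaluateClock(rep(1, 5), 1:5), "constant")
})

test_that("stepwise reduction keeps signal probes and matches brute force", {
  okAll <- TRUE
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 120
    beta <- matrix(runif(7 * n), 7, n,
                   dimnames = list(paste0("cg", 1:7), sprintf("s%03d", 1:n)))
    w <- runif(5, 20, 40)
    y <- setNames(10 + as.numeric(crossprod(w, beta[1:5, ])) + rnorm(n, 0, 1),
                  colnames(beta))
    ms <- tinyMethylSet(beta)
    m <- stepwiseReduce(ms, y, paste0("cg", 1:7), stopK = 5)
    okAll <- okAll && setequal(names(clockWeights(m)), paste0("cg", 1:5))

    # brute-force oracle: greedy single-deletion search by stats::AIC on lm()
    df <- data.frame(y = y, t(beta))
    cur <- paste0("cg", 1:7)
    elim <- character()
    while (length(cur) > 5) {
      aics <- vapply(cur, function(drop) {
        f <- reformulate(setdiff(cur, drop), "y")
        stats::AIC(lm(f, data = df))
      }, numeric(1))
      worst <- names(which.min(aics))
      elim <- c(elim, worst)
      cur <- setdiff(cur, worst)
    }
    okAll <- okAll && identical(m@meta$eliminated, elim)
  }
  expect_true(okAll)
  # start set of exactly stopK: identity fit, nothing eliminated
  set.seed(97)
  beta <- matrix(runif(5 * 50), 5, 50,
                 dimnames = list(paste0("cg", 1:5), sprintf("s%02d", 1:50)))
  y <- setNames(rnorm(50, 50, 5), colnames(beta))
  m0 <- stepwiseReduce(tinyMethylSet(beta), y, paste0("cg", 1:5), stopK = 5)
  expect_length(m0@meta$eliminated, 0)
  expect_setequal(names(clockWeights(m0)), paste0("cg", 1:5))
  # collinear start set refused
  beta2 <- rbind(beta, cgDup = beta["cg1", ])
  expect_error(stepwiseReduce(tinyMethylSet(beta2), y, rownames(beta2),
                              stopK = 5), "collinear")
})

test_that("multimodal LOO clock recovers signal and is order-invariant", {
  set.seed(98)
  n <- 24; p <- 40
  beta <- matrix(runif(p * n), p, n,
                 dimnames = list(sprintf("cg%02d", 1:p), sprintf("s%02d", 1:n)))
  target <- setNames(30 + 40 * beta[1, ] + 25 * beta[2, ] + 15 * beta[3, ],
                     colnames(beta))
  ms <- tinyMethylSet(beta)
  fit <- trainMultimodalClock(ms, target, alphaGrid = c(0.5), nFolds = 5)
  expect_gt(fit$evaluation$r, 0.99)
  expect_identical(fit$model@transform, "identity")
  # permuting the other samples leaves a LOO prediction unchanged
  perm <- c(1, sample(2:n))
  fit2 <- trainMultimodalClock(ms[, perm], target[perm],
                               alphaGrid = c(0.5), nFolds = 5)
  expect_equal(fit$evaluation$predictions["s01"],
               fit2$evaluation$predictions["s01"], tolerance = 1e-6)
  expect_error(trainMultimodalClock(ms[, 1:5], target[1:5]), ">= 10")
})

test_that("multimodal clock on an unrelated target finds nothing", {
  rs <- vapply(1:5, function(s) {
    set.seed(500 + s)
    n <- 20
    beta <- matrix(runif(30 * n), 30, n,
                   dimnames = list(sprintf("cg%02d", 1:30),
                                   sprintf("s%02d", 1:n)))
    target <- setNames(rnorm(n, 50, 10), colnames(beta))
    fit <- trainMultimodalClock(tinyMethylSet(beta), target,
                                alphaGrid = c(0.5), nFolds = 5)
    r <- fit$evaluation$r
    if (is.na(r)) 0 else r
  }, numeric(1))
  expect_lt(mean(rs), 0.5)
})

test_that("clock JSON serialization round-trips to identical predictions", {
  fx <- linearClockCohort(n = 60, p = 30, seed = 99)
  sp <- list(train = colnames(fx$ms)[1:40],
             validation = colnames(fx$ms)[41:60])
  m <- trainClock(fx$ms, fx$ages, sp, alphaGrid = c(0.5), seed = 7)
  path <- tempfile(fileext = ".json")
  writeClockModel(m, path)
  m2 <- readClockModel(path)
  expect_identical(clockWeights(m2), clockWeights(m))
  expect_identical(m2@intercept, m@intercept)
  expect_identical(predictAge(m2, fx$ms), predictAge(m, fx$ms))
})

test_that("published-clock coefficient import builds a working model", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(probe = c("(Intercept)", "cg1", "cg2"),
                       coefficient = c(10, 5, -2),
                       mean_beta = c(NA, 0.5, 0.4)),
            path, row.names = FALSE)
  m <- importClockCoefficients(path, name = "pub", transform = "identity")
  b <- matrix(c(0.6, 0.2), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
  expect_equal(unname(predictAge(m, b)), 10 + 5 * 0.6 - 2 * 0.2)
})
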