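#' Piecewise age transform for clock training
#'
#' Chronological age is mapped through the piecewise function used by
#' Horvath-style clocks: linear above the adult-age knot, logarithmic below
#' it, continuous (and equal to 0) at the knot:
#' \deqn{f(age) = (age + 1)/(A + 1) - 1 \quad (age \ge A); \qquad
#'       f(age) = \log((age + 1)/(A + 1)) \quad (age < A)}
#' with `A = adultAge` (20 by default). The log branch compresses the fast
#' epigenetic drift of childhood so a single linear model can fit the whole
#' age range.
#'
#' @param age ages in years, all > -1.
#' @param adultAge knot in years.
#' @return transformed values.
#' @examples
#' transformAge(c(20, 41))   # 0, 1
#' @export
transformAge <- function(age, adultAge = 20) {
  if (any(age <= -1)) stop("age must be > -1")
  ifelse(age >= adultAge,
         (age + 1) / (adultAge + 1) - 1,
         log((age + 1) / (adultAge + 1)))
}

#' Inverse of the piecewise age transform
#'
#' Maps a model score back to years: `t >= 0 -> (A + 1) * t + A`;
#' `t < 0 -> exp(t + log(A + 1)) - 1`. Exact inverse of [transformAge()]
#' on both branches.
#'
#' @param t transformed values (finite).
#' @param adultAge knot in years.
#' @return ages in years.
#' @examples
#' inverseTransformAge(c(0, 1))  # 20, 41
#' @export
inverseTransformAge <- function(t, adultAge = 20) {
  if (any(!is.finite(t))) stop("t must be finite")
  ifelse(t >= 0,
         (adultAge + 1) * t + adultAge,
         exp(t + log(adultAge + 1)) - 1)
}

#' Stratified train/validation split
#'
#' Splits samples 50/50 (or by `fracTrain`) within strata formed by sex and
#' age decile, so both halves cover the age range and sex balance of the
#' cohort.
#'
#' @param ms a [MethylSet-class] with `age` (and optionally `sex`) columns.
#' @param fracTrain fraction assigned to training.
#' @param seed RNG seed.
#' @return list with character vectors `train` and `validation`.
#' @export
stratifiedSplit <- function(ms, fracTrain = 0.5, seed = 1L) {
  sd <- sampleData(ms)
  set.seed(as.integer(seed))
  decile <- cut(sd$age, breaks = unique(stats::quantile(sd$age, 0:10 / 10)),
                include.lowest = TRUE)
  strata <- if (!is.null(sd$sex)) interaction(sd$sex, decile) else decile
  ids <- colnames(ms)
  train <- unlist(lapply(split(ids, strata), function(g) {
    if (!length(g)) return(character())
    sample(g, round(fracTrain * length(g)))
  }), use.names = FALSE)
  # balance rounding so the split hits fracTrain of the whole cohort
  target <- round(fracTrain * length(ids))
  pool <- setdiff(ids, train)
  if (length(train) > target) train <- sample(train, target)
  if (length(train) < target)
    train <- c(train, sample(pool, target - length(train)))
  list(train = sort(train), validation = sort(setdiff(ids, train)))
}

#' Train a transformed-age elastic-net clock
#'
#' For each alpha on the grid, an elastic-net path is fit on the training
#' samples with lambda chosen by internal 10-fold cross-validation
#' (fold assignment seeded); each candidate is then scored by mean absolute
#' error on the held-out validation samples, in years (predictions are
#' inverse-transformed before scoring when the target is chronological
#' age). The alpha/lambda pair with the lowest validation MAE becomes the
#' final model, returned with its nonzero CpG weights and the training-set
#' mean beta of each model probe (used for imputation at prediction time).
#'
#' @param ms a [MethylSet-class].
#' @param targets named numeric vector of per-sample targets (years); when
#'   `transform = "horvath_piecewise"` they are transformed before fitting.
#' @param split list with `train` and `validation` sample-id vectors
#'   (disjoint), e.g. from [stratifiedSplit()].
#' @param alphaGrid elastic-net mixing values (default 0.1..0.9).
#' @param nFolds internal CV folds for lambda (default 10).
#' @param transform `"horvath_piecewise"` (chronological age) or
#'   `"identity"` (targets used as-is).
#' @param adultAge knot of the piecewise transform.
#' @param seed RNG seed (CV fold assignment).
#' @param name model name stored in the result.
#' @return a [ClockModel-class]; `@meta` records alpha, lambda, validation
#'   MAE and r.
#' @export
trainClock <- function(ms, targets, split, alphaGrid = seq(0.1, 0.9, 0.1),
                       nFolds = 10, transform = "horvath_piecewise",
                       adultAge = 20, seed = 1L, name = "DNAmAge") {
  if (length(intersect(split$train, split$validation)))
    stop("train and validation sets must be disjoint")
  if (!length(split$validation)) stop("validation set is empty")
  if (any(!is.finite(targets[c(split$train, split$validation)])))
    stop("targets must be finite for all split samples")
  b <- betaValues(ms)
  xTrain <- t(b[, split$train, drop = FALSE])
  xVal <- t(b[, split$validation, drop = FALSE])
  yTrain <- targets[split$train]
  yValYears <- targets[split$validation]
  fTrain <- if (transform == "horvath_piecewise")
    transformAge(yTrain, adultAge) else yTrain

  set.seed(as.integer(seed))
  foldid <- sample(rep(seq_len(nFolds), length.out = nrow(xTrain)))
  best <- NULL
  for (alpha in alphaGrid) {
    cvfit <- glmnet::cv.glmnet(xTrain, fTrain, alpha = alpha,
                               foldid = foldid, family = "gaussian")
    predT <- as.numeric(stats::predict(cvfit, newx = xVal, s = "lambda.min"))
    predYears <- if (transform == "horvath_piecewise")
      inverseTransformAge(predT, adultAge) else predT
    mae <- mean(abs(predYears - yValYears))
    if (is.null(best) || mae < best$mae)
      best <- list(alpha = alpha, cvfit = cvfit, mae = mae,
                   pred = predYears)
  }
  cf <- as.matrix(stats::coef(best$cvfit, s = "lambda.min"))
  w <- cf[-1, 1]
  w <- w[w != 0]
  r <- if (stats::sd(best$pred) > 0)
    stats::cor(best$pred, yValYears) else NA_real_
  ClockModel(name = name, intercept = cf[1, 1], weights = w,
             transform = transform, adultAge = adultAge,
             trainingMeans = colMeans(xTrain)[names(w)],
             meta = list(alpha = best$alpha,
                         lambda = best$cvfit$lambda.min,
                         validationMAE = best$mae, validationR = r,
                         target = name, nTrain = nrow(xTrain),
                         nValidation = nrow(xVal)))
}

#' Predict age from a clock model
#'
#' Computes the linear score `intercept + sum(w * beta)` per sample and,
#' for piecewise-transform models, maps it back to years with
#' [inverseTransformAge()]. Model probes absent from the matrix are imputed
#' with their training-set mean beta (count reported in a message); if no
#' model probe is present, prediction is refused.
#'
#' @param model a [ClockModel-class].
#' @param ms a [MethylSet-class] or plain beta matrix (probes x samples).
#' @return named numeric vector of predicted ages (years for
#'   piecewise-transform models).
#' @export
predictAge <- function(model, ms) {
  b <- if (is(ms, "SummarizedExperiment")) betaValues(ms) else as.matrix(ms)
  probes <- names(model@weights)
  if (!length(probes)) {
    # intercept-only model (e.g. a null fit that selected no CpGs)
    score <- stats::setNames(rep(model@intercept, ncol(b)), colnames(b))
    return(if (model@transform == "horvath_piecewise")
      inverseTransformAge(score, model@adultAge) else score)
  }
  present <- probes %in% rownames(b)
  if (!any(present)) stop("no model probes present in the beta matrix")
  if (any(!present)) {
    missingIds <- probes[!present]
    fillers <- model@trainingMeans[missingIds]
    if (anyNA(fillers))
      stop("missing model probes without stored training means: ",
           paste(missingIds[is.na(fillers)], collapse = ", "))
    message(sprintf("predictAge: %d/%d model probes missing; imputed with training means",
                    sum(!present), length(probes)))
    fill <- matrix(fillers, length(missingIds), ncol(b),
                   dimnames = list(missingIds, colnames(b)))
    b <- rbind(b[probes[present], , drop = FALSE], fill)
  }
  score <- model@intercept +
    as.numeric(crossprod(model@weights[probes], b[probes, , drop = FALSE]))
  names(score) <- colnames(b)
  if (model@transform == "horvath_piecewise")
    inverseTransformAge(score, model@adultAge)
  else score
}

#' Evaluate clock predictions against a target
#'
#' @param predictions named/plain numeric vector of predicted ages.
#' @param truth matching numeric vector of true ages.
#' @return list with `r` (Pearson; `NA` with a warning for constant
#'   predictions), `mae` (years), `n`, and the per-sample `predictions`.
#' @export
evaluateClock <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  if (length(truth) < 3) stop("need >= 3 paired values")
  r <- if (stats::sd(predictions) == 0) {
    warning("constant predictions: correlation undefined")
    NA_real_
  } else stats::cor(predictions, truth)
  list(r = r, mae = mean(abs(predictions - truth)), n = length(truth),
       predictions = predictions)
}

#' Backward stepwise reduction to a compact CpG panel
#'
#' Starting from an OLS fit of the (untransformed) target on a probe set,
#' the probe whose single deletion least degrades the selection criterion
#' (AIC by default) is removed, repeatedly, until `stopK` probes remain.
#' Every step is an exhaustive search over single deletions, so the
#' elimination order is reproducible by brute force.
#'
#' @param ms a [MethylSet-class].
#' @param targets named numeric target vector (years).
#' @param startProbes initial probe set (present in `ms`, length > `stopK`).
#' @param stopK panel size to stop at (default 5).
#' @param criterion `"AIC"` or `"BIC"`.
#' @return a [ClockModel-class] with identity transform; `@meta$eliminated`
#'   records the deletion order.
#' @export
stepwiseReduce <- function(ms, targets, startProbes, stopK = 5,
                           criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (length(startProbes) < stopK)
    stop("startProbes must contain at least stopK probes")
  b <- betaValues(ms)
  if (!all(startProbes %in% rownames(b)))
    stop("startProbes absent from the beta matrix")
  ids <- intersect(colnames(b), names(targets))
  X <- t(b[startProbes, ids, drop = FALSE])
  y <- targets[ids]
  n <- length(y)
  crit <- function(cols) {
    Xs <- cbind(1, X[, cols, drop = FALSE])
    qrX <- qr(Xs)
    if (qrX$rank < ncol(Xs)) return(Inf)
    rss <- sum(qr.resid(qrX, y)^2)
    k <- ncol(Xs) + 1  # + sigma
    n * log(rss / n) + if (criterion == "AIC") 2 * k else log(n) * k
  }
  current <- startProbes
  if (!is.finite(crit(current))) stop("collinear start probe set")
  eliminated <- character()
  while (length(current) > stopK) {
    scores <- vapply(seq_along(current),
                     function(i) crit(current[-i]), numeric(1))
    drop <- which.min(scores)
    eliminated <- c(eliminated, current[drop])
    current <- current[-drop]
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1,
                             X[, current, drop = FALSE]), y)
  w <- fit$coefficients[-1]
  names(w) <- current
  ClockModel(name = sprintf("%dCpG-panel", stopK),
             intercept = fit$coefficients[1], weights = w,
             transform = "identity",
             trainingMeans = colMeans(X[, current, drop = FALSE]),
             meta = list(criterion = criterion, eliminated = eliminated,
                         nTrain = n))
}

#' Train a DNAm surrogate clock for a multi-modal age
#'
#' Multi-modal biological ages (composite, facial, transcriptomic, ...) are
#' regressed on methylation with the same elastic-net protocol as the
#' chronological clock, but evaluated by leave-one-out cross-validation:
#' for each alpha, every sample is predicted by a model trained on all
#' others (lambda by internal CV), the LOO predictions are scored against
#' the target, and the best alpha's final model is refit on all samples.
#' Targets are used on their own scale (identity transform).
#'
#' @param ms a [MethylSet-class].
#' @param targets named numeric vector of multi-modal ages; samples with
#'   `NA` are dropped.
#' @param alphaGrid elastic-net mixing values.
#' @param nFolds internal CV folds for lambda.
#' @param seed RNG seed.
#' @param name target name (stored in meta as `multimodal:<name>`).
#' @param loo compute leave-one-out predictions (required for evaluation;
#'   `FALSE` skips straight to the full-data fit at the first alpha).
#' @return list with `model` ([ClockModel-class]) and `evaluation`
#'   (list r / mae / n / predictions from the LOO pass).
#' @export
trainMultimodalClock <- function(ms, targets, alphaGrid = seq(0.1, 0.9, 0.2),
                                 nFolds = 10, seed = 1L, name = "multimodal",
                                 loo = TRUE) {
  targets <- targets[!is.na(targets)]
  ids <- intersect(colnames(ms), names(targets))
  if (loo && length(ids) < 10) stop("need >= 10 samples for leave-one-out")
  b <- betaValues(ms)[, ids, drop = FALSE]
  X <- t(b)
  y <- targets[ids]
  n <- length(ids)
  # fold assignment is a deterministic function of the sample-id SET, so a
  # LOO prediction is invariant to the ordering of the other samples
  foldOf <- function(idSet) {
    s <- sort(idSet)
    stats::setNames((seq_along(s) - 1L) %% nFolds + 1L, s)[idSet]
  }
  best <- NULL
  evaluation <- NULL
  if (loo) {
    for (alpha in alphaGrid) {
      preds <- vapply(seq_len(n), function(i) {
        idRest <- ids[-i]
        cvfit <- glmnet::cv.glmnet(X[idRest, , drop = FALSE], y[idRest],
                                   alpha = alpha, foldid = foldOf(idRest))
        as.numeric(stats::predict(cvfit, newx = X[ids[i], , drop = FALSE],
                                  s = "lambda.min"))
      }, numeric(1))
      mae <- mean(abs(preds - y))
      if (is.null(best) || mae < best$mae)
        best <- list(alpha = alpha, mae = mae, preds = preds)
    }
    evaluation <- list(
      r = if (stats::sd(best$preds) > 0) stats::cor(best$preds, y) else NA_real_,
      mae = best$mae, n = n,
      predictions = stats::setNames(best$preds, ids))
  } else {
    best <- list(alpha = alphaGrid[1], mae = NA_real_)
  }
  set.seed(as.integer(seed))
  finalFit <- glmnet::cv.glmnet(X, y, alpha = best$alpha,
                                foldid = unname(foldOf(ids)))
  cf <- as.matrix(stats::coef(finalFit, s = "lambda.min"))
  w <- cf[-1, 1]
  w <- w[w != 0]
  model <- ClockModel(name = paste0(name, "-DNAmAge"), intercept = cf[1, 1],
                      weights = w, transform = "identity",
                      trainingMeans = colMeans(X)[names(w)],
                      meta = list(alpha = best$alpha,
                                  lambda = finalFit$lambda.min,
                                  validationMAE = best$mae,
                                  target = paste0("multimodal:", name),
                                  nTrain = n))
  list(model = model, evaluation = evaluation)
}

#' Write / read a clock model as JSON
#'
#' The schema is `{name, transform, adult_age, intercept, weights:
#' [{probe, coef, training_mean}], meta}`; numeric values are serialized at
#' full precision so a round trip reproduces bit-identical predictions.
#'
#' @param model a [ClockModel-class].
#' @param path JSON file path.
#' @return `writeClockModel` returns `path` invisibly; `readClockModel`
#'   returns the [ClockModel-class].
#' @export
writeClockModel <- function(model, path) {
  tm <- model@trainingMeans[names(model@weights)]
  obj <- list(name = model@name, transform = model@transform,
              adult_age = model@adultAge, intercept = model@intercept,
              weights = data.frame(probe = names(model@weights),
                                   coef = unname(model@weights),
                                   training_mean = unname(tm)),
              meta = model@meta)
  # 17 significant digits: lossless decimal round trip for doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeClockModel
#' @export
readClockModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- stats::setNames(obj$weights$coef, obj$weights$probe)
  tm <- if (!is.null(obj$weights$training_mean))
    stats::setNames(obj$weights$training_mean, obj$weights$probe)
  else numeric()
  meta <- obj$meta
  if (is.null(meta)) meta <- list()
  ClockModel(name = obj$name, intercept = obj$intercept, weights = w,
             transform = obj$transform, adultAge = obj$adult_age,
             trainingMeans = tm, meta = as.list(meta))
}

#' Import a published clock from a coefficient CSV
#'
#' Reads user-supplied coefficient tables for published clocks (columns
#' `probe` and `coefficient`; the intercept is the row whose probe id is
#' `"(Intercept)"` or `"Intercept"`). Missing-probe imputation values may be
#' given in a `mean_beta` column.
#'
#' @param path CSV path.
#' @param name model name.
#' @param transform `"horvath_piecewise"` (e.g. Horvath) or `"identity"`
#'   (e.g. Hannum, PhenoAge).
#' @param adultAge transform knot.
#' @return a [ClockModel-class].
#' @export
importClockCoefficients <- function(path, name = "imported",
                                    transform = "identity", adultAge = 20) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("probe", "coefficient") %in% colnames(tab)))
    stop("coefficient CSV needs 'probe' and 'coefficient' columns")
  isInt <- tab$probe %in% c("(Intercept)", "Intercept")
  intercept <- if (any(isInt)) sum(tab$coefficient[isInt]) else 0
  body <- tab[!isInt, , drop = FALSE]
  w <- stats::setNames(body$coefficient, body$probe)
  tm <- if ("mean_beta" %in% colnames(body))
    stats::setNames(body$mean_beta, body$probe) else numeric()
  ClockModel(name = name, intercept = intercept, weights = w,
             transform = transform, adultAge = adultAge,
             trainingMeans = tm, meta = list(source = basename(path)))
}
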