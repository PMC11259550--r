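# Small in-code fixtures shared across test files.

# MethylSet with explicit beta values and optional ages.
tinyMethylSet <- function(beta, ages = NULL, ...) {
  sd <- if (!is.null(ages)) data.frame(age = ages, ...) else NULL
  MethylSet(beta, sampleData = sd)
}

# Deterministic cohort where one target is an exact linear function of a
# few probes on the transformed-age scale; used for clock recovery tests.
linearClockCohort <- function(n = 200, p = 120, nSignal = 5,
                              noiseSd = 0.02, seed = 1) {
  set.seed(seed)
  beta <- matrix(runif(p * n), p, n,
                 dimnames = list(sprintf("cg%05d", 1:p),
                                 sprintf("S%04d", 1:n)))
  signal <- rownames(beta)[seq_len(nSignal)]
  w <- runif(nSignal, 0.3, 0.6)
  score <- -0.5 + as.numeric(crossprod(w, beta[signal, , drop = FALSE]))
  score <- score + rnorm(n, 0, noiseSd)
  ages <- inverseTransformAge(score)
  list(ms = MethylSet(beta, sampleData = data.frame(age = ages,
                                                    sex = rep(0:1, length.out = n))),
       ages = setNames(ages, colnames(beta)), signal = signal, weights = w)
}

# Independent OLS oracle via explicit normal equations (solve(), not qr),
# for checking fitSiteModels.
olsOracle <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  bhat <- XtXi %*% t(X) %*% y
  res <- y - X %*% bhat
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(XtXi) * s2)
  t <- bhat / se
  list(coef = as.numeric(bhat), se = as.numeric(se), t = as.numeric(t),
       p = as.numeric(2 * pt(-abs(t), df)))
}
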