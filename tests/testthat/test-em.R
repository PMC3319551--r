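test_that("the block E-step equals brute-force enumeration of the indicator", {
  # w = 0 makes all assignments equidistant: uniform posterior
  b <- randomBlock(R = 2, D = 5, seed = 11)
  expect_equal(eStepBlock(b, rep(0, 5), 1), rep(1 / 6, 6), tolerance = 1e-12)

  # analytic case: R = 1, projections (1,-1,...,-1): SSE gap 8 -> exp(-4)
  f <- array(0, c(1, 6, 2))
  f[1, , 1] <- c(1, -1, -1, -1, -1, -1)
  f[1, , 2] <- 1
  b1 <- PseudoSymbolBlock(0L, "row", f)
  w <- c(1, 0)
  p <- eStepBlock(b1, w, 1)
  expect_equal(p[1], 1 / (1 + 5 * exp(-4)), tolerance = 1e-12)
  expect_equal(p, bruteForcePosterior(b1, w, 1), tolerance = 1e-12)

  # exact inference on random instances, R <= 3, D <= 10
  for (seed in 1:8) {
    set.seed(seed)
    R <- sample(1:3, 1); D <- sample(3:10, 1)
    b <- randomBlock(R, D, seed = 100 + seed)
    w <- rnorm(D) / sqrt(D)
    beta <- runif(1, 0.2, 2)
    expect_equal(eStepBlock(b, w, beta), bruteForcePosterior(b, w, beta),
                 tolerance = 1e-12)
  }
})

test_that("more repetitions of a clear pattern sharpen the posterior at the truth", {
  mk <- function(R) {
    f <- array(0, c(R, 6, 2))
    f[, 1, 1] <- 1; f[, 2:6, 1] <- -1; f[, , 2] <- 1
    PseudoSymbolBlock(0L, "row", f)
  }
  p1 <- eStepBlock(mk(1), c(1, 0), 1)
  p2 <- eStepBlock(mk(2), c(1, 0), 1)
  expect_gt(p2[1], p1[1])
  expect_equal(p2, bruteForcePosterior(mk(2), c(1, 0), 1), tolerance = 1e-12)
})

test_that("expected labels marginalize the indicator: 2p - 1 per flash", {
  b <- randomBlock(R = 3, D = 4, seed = 21)
  expect_equal(expectedLabels(rep(1 / 6, 6), b),
               matrix(-2 / 3, 3, 6), tolerance = 1e-12)
  oneHot <- c(0, 0, 1, 0, 0, 0)
  expect_equal(expectedLabels(oneHot, b),
               matrix(rep(c(-1, -1, 1, -1, -1, -1), each = 3), 3, 6))
  set.seed(5)
  post <- prop.table(runif(6))
  acc <- matrix(0, 3, 6)
  for (cand in 0:5)
    acc <- acc + post[cand + 1] * labelsForAssignment(cand, b)
  expect_equal(expectedLabels(post, b), acc, tolerance = 1e-12)
})

test_that("the weight M-step equals the posterior-weighted sum of ridge solutions", {
  sess <- randomOneCharSession(R = 3, D = 8, seed = 31)
  set.seed(32)
  postRow <- prop.table(runif(6)); postCol <- prop.table(runif(6))
  beta <- 0.8; alpha <- 2
  w <- mStepW(sess, rbind(postRow, postCol), beta, alpha)
  wbf <- bruteForceJointRidge(sess, postRow, postCol, beta, alpha)
  expect_lt(max(abs(w - wbf)) / max(abs(wbf)), 1e-10)

  # one-hot posteriors at the truth give supervised ridge regression
  g <- generateFeatureSession(featureGenConfig(K = 4, R = 3, D = 10,
                                               mu = 1, seed = 33))
  post <- oneHotPosteriors(g)
  wsup <- mStepW(g, post, 1, 1)
  expect_equal(wsup, ridgeMap(g@X, trueLabels(g), 1), tolerance = 1e-10)

  # uniform posteriors pull toward the nontarget mean via E[y] = -2/3
  wunif <- mStepW(g, matrix(1 / 6, nrow(g@blockInfo), 6), 1, 1)
  expect_equal(wunif, ridgeMap(g@X, rep(-2 / 3, nrow(g@X)), 1),
               tolerance = 1e-12)
})

test_that("the noise M-step is the posterior-weighted mean squared error", {
  sess <- randomOneCharSession(R = 2, D = 6, seed = 41)
  unif <- matrix(1 / 6, 2, 6)
  # w = 0: residual to every +/-1 label is 1
  expect_equal(mStepBeta(sess, unif, rep(0, 6)), 1, tolerance = 1e-12)
  set.seed(42)
  postRow <- prop.table(runif(6)); postCol <- prop.table(runif(6))
  w <- rnorm(6) / 3
  expect_lt(abs(mStepBeta(sess, rbind(postRow, postCol), w) -
                  bruteForceJointBeta(sess, postRow, postCol, w)), 1e-12)
  # perfect projections under one-hot posteriors floor beta
  g <- generateFeatureSession(featureGenConfig(K = 2, R = 2, D = 5,
                                               mu = 1, seed = 43))
  y <- trueLabels(g)
  gPerfect <- g
  gPerfect@X <- cbind(y, g@X[, -1])
  expect_equal(mStepBeta(gPerfect, oneHotPosteriors(g), c(1, rep(0, 4))),
               1e-8)
})

test_that("the prior-precision M-step is D over the squared norm, capped when asked", {
  expect_equal(mStepAlpha(w = c(rep(1, 5), rep(0, 5)), D = 10), 2)
  expect_equal(mStepAlpha(c(1, 1)), 1)
  expect_warning(a <- mStepAlpha(c(1e-6, 0), D = 2, alphaCap = 1e4),
                 "capped")
  expect_equal(a, 1e4)
  expect_error(mStepAlpha(c(0, 0)), "degenerate")
})

test_that("the MAP objective collapses correctly and improves along the beta update", {
  # w = 0, beta = 1, alpha = 2pi, K = 1, R = 1, D = 2:
  # every assignment ties, the mixture collapses, the prior term vanishes
  sess <- randomOneCharSession(R = 1, D = 2, seed = 51)
  params <- classifierParams(c(0, 0), beta = 1, alpha = 2 * pi)
  expect_equal(mapObjective(sess, params),
               12 * (-0.5 * log(2 * pi) - 0.5), tolerance = 1e-10)

  # moving beta toward the M-step value increases the objective (1-D scan)
  sess2 <- generateFeatureSession(featureGenConfig(K = 3, R = 2, D = 8,
                                                   mu = 0.8, seed = 52))
  w <- attr(sess2, "trueDirection") * 0.4
  objAt <- function(b) mapObjective(sess2, classifierParams(w, beta = b))
  for (b0 in c(0.3, 0.6, 2, 4)) {
    post0 <- eStepSession(sess2, classifierParams(w, beta = b0))
    bstar <- mStepBeta(sess2, post0, w)
    bmid <- b0 + 0.5 * (bstar - b0)
    expect_gt(objAt(bmid), objAt(b0) - 1e-9)
  }

  # the data term is invariant to relabeling the axes of the same blocks
  flipped <- sessionBlocks(sess2)
  flipped <- lapply(flipped, function(b)
    PseudoSymbolBlock(b@charIndex,
                      if (b@axis == "row") "column" else "row", b@features))
  ord <- order(vapply(flipped, function(b) b@charIndex, integer(1)),
               match(vapply(flipped, function(b) b@axis, character(1)),
                     c("row", "column")))
  sessF <- SessionFeatures(flipped[ord], grid = sessionGrid(sess2))
  p2 <- classifierParams(w, beta = 1)
  expect_equal(dataLogLik(sessF, p2), dataLogLik(sess2, p2),
               tolerance = 1e-10)
})

test_that("EM ascends the MAP objective and nails separable sessions", {
  # monotone trace over 50 forced iterations on 10 seeded sessions
  for (s in 1:10) {
    sess <- generateFeatureSession(featureGenConfig(K = 8, R = 3, D = 10,
                                                    mu = 0.5, seed = 200 + s))
    fit <- emFit(sess, initCouples(10, 1, seed = s)[[1]][[1]],
                 emConfig(maxIter = 50, relTol = 0))
    obj <- traceTable(fit$trace)$objective
    expect_true(all(diff(obj) >= -1e-9 * abs(obj[-1])))
  }
  # high separability: couple + selection converges fast to certainty
  sess <- generateFeatureSession(featureGenConfig(K = 10, R = 8, D = 20,
                                                  mu = 2, seed = 5))
  fits <- lapply(initCouples(20, 1, seed = 2)[[1]],
                 function(p) emFit(sess, p))
  best <- fits[[selectBest(lapply(fits, `[[`, "params"), sess)]]
  expect_lte(nrow(traceTable(best$trace)), 20)
  post <- eStepSession(sess, best$params)
  expect_gte(min(posteriorAtTruth(sess, post)), 0.99)
})

test_that("with ground-truth posteriors one EM iteration is supervised ridge plus closed-form beta", {
  sess <- generateFeatureSession(featureGenConfig(K = 6, R = 4, D = 12,
                                                  mu = 1, seed = 61))
  post <- oneHotPosteriors(sess)
  beta0 <- 1; alpha0 <- 1
  w <- mStepW(sess, post, beta0, alpha0)
  y <- trueLabels(sess)
  expect_equal(w, ridgeMap(sess@X, y, beta0 * alpha0), tolerance = 1e-10)
  p <- drop(sess@X %*% w)
  expect_equal(mStepBeta(sess, post, w), mean((p - y)^2), tolerance = 1e-12)
})

test_that("starved sessions reach the degenerate optimum and the trace flags it", {
  flagged <- 0L
  for (s in 1:10) {
    sess <- generateFeatureSession(featureGenConfig(K = 2, R = 1, D = 10,
                                                    mu = 0.3, seed = 900 + s))
    fit <- suppressWarnings(
      emFit(sess, initCouples(10, 1, seed = s)[[1]][[1]],
            emConfig(maxIter = 200)))
    tb <- traceTable(fit$trace)
    if (any(tb$degenerate)) {
      flagged <- flagged + 1L
      expect_true(max(tb$alpha) > 1e6 || min(tb$beta) <= 1e-8)
    }
  }
  expect_gt(flagged, 0L)
  # a capped config on the same data never lets alpha explode
  sessd <- generateFeatureSession(featureGenConfig(K = 2, R = 1, D = 10,
                                                   mu = 0.3, seed = 901))
  fitc <- emFit(sessd, initCouples(10, 1, seed = 1)[[1]][[1]],
                emConfig(maxIter = 200, alphaCap = 1e4))
  expect_lte(max(traceTable(fitc$trace)$alpha), 1e4)
})

test_that("unconstrained EM keeps valid per-flash posteriors and admits the w = 0 fixed point", {
  sess <- generateFeatureSession(featureGenConfig(K = 5, R = 3, D = 8,
                                                  mu = 0.8, seed = 71))
  fit <- emFitUnconstrained(sess, initCouples(8, 1, seed = 7)[[1]][[1]],
                            emConfig(maxIter = 30))
  p <- labelPosterior(drop(sess@X %*% fit$params@w), fit$params,
                      projection = TRUE)
  expect_true(all(p >= 0 & p <= 1))
  # pi1 = 1/2: starting at w = 0, expected labels vanish and w stays 0
  init0 <- classifierParams(rep(0, 8), beta = 1, alpha = 1, pi1 = 0.5)
  fit0 <- emFitUnconstrained(sess, init0, emConfig(maxIter = 5,
                                                   updateAlpha = FALSE))
  expect_equal(sum(fit0$params@w^2), 0, tolerance = 1e-20)
})

test_that("the paradigm constraint beats unconstrained EM on paired sessions", {
  accC <- accU <- numeric(10)
  for (s in 1:10) {
    sess <- generateFeatureSession(featureGenConfig(K = 20, R = 5, D = 30,
                                                    mu = 0.7, seed = 700 + s))
    inits <- unlist(initCouples(30, 3, seed = s), recursive = FALSE)
    fc <- lapply(inits, function(p) emFit(sess, p)$params)
    fu <- lapply(inits, function(p) emFitUnconstrained(sess, p)$params)
    accC[s] <- spellSession(sess, fc[[selectBest(fc, sess)]])$accuracy
    accU[s] <- spellSession(sess, fu[[selectBest(fu, sess)]])$accuracy
  }
  expect_gt(mean(accC), mean(accU))  # strictly better at moderate separability
})

test_that("initialization couples are mirrored, reproducible and unit-scaled", {
  cps <- initCouples(40, 3, seed = 123)
  for (cp in cps) expect_equal(cp[[2]]@w, -cp[[1]]@w)
  cps2 <- initCouples(40, 3, seed = 123)
  expect_equal(cps[[2]][[1]]@w, cps2[[2]][[1]]@w)
  set.seed(1)
  nrm <- replicate(1000, sum(rnorm(40, sd = 1 / sqrt(40))^2))
  expect_lt(abs(mean(nrm) - 1), 0.1)
})

test_that("likelihood selection separates a classifier from its sign-flip", {
  expect_identical(selectBest(list(classifierParams(c(1, 0))),
                              randomOneCharSession(2, 2, seed = 81)), 1L)
  for (s in 1:5) {
    sess <- generateFeatureSession(featureGenConfig(K = 12, R = 6, D = 15,
                                                    mu = 1, seed = 800 + s))
    fits <- lapply(initCouples(15, 1, seed = s)[[1]],
                   function(p) emFit(sess, p)$params)
    sel <- selectBest(fits, sess)
    y <- trueLabels(sess)
    aucs <- vapply(fits, function(p)
      aucScore(drop(sess@X %*% p@w), y), numeric(1))
    expect_gt(aucs[sel], 0.5)   # the correctly-signed member wins
  }
})
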