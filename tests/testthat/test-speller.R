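test_that("character prediction takes the maximum-posterior grid cell with low-index ties", {
  sess <- generateFeatureSession(featureGenConfig(K = 2, R = 3, D = 8,
                                                  mu = 2, seed = 91))
  blocks <- sessionBlocks(sess)
  # w = 0: uniform posteriors on both axes, tie-break to (0, 0) = 'A'
  pr <- predictCharacter(blocks[[1]], blocks[[2]],
                         classifierParams(rep(0, 8)))
  expect_identical(pr@predictedChar, "A")
  expect_equal(pr@rowPosterior, rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(sum(pr@joint), 1, tolerance = 1e-12)
  expect_error(predictCharacter(blocks[[1]], blocks[[4]],
                                classifierParams(rep(0, 8))), "same character")
  # one-hot posteriors at row 2, column 4 spell 'Q' (row-major lookup)
  expect_identical(gridLookup(defaultGrid(), 2, 4), "Q")
})

test_that("row and column inference are independent", {
  sess <- generateFeatureSession(featureGenConfig(K = 3, R = 2, D = 10,
                                                  mu = 0.8, seed = 92))
  params <- classifierParams(attr(sess, "trueDirection"), beta = 0.7)
  post <- eStepSession(sess, params)
  # swap the column blocks of characters 0 and 1
  blocks <- sessionBlocks(sess)
  tmp <- blocks[[2]]@features
  blocks[[2]] <- PseudoSymbolBlock(0L, "column", blocks[[4]]@features)
  blocks[[4]] <- PseudoSymbolBlock(1L, "column", tmp)
  swapped <- SessionFeatures(blocks, grid = sessionGrid(sess))
  postSw <- eStepSession(swapped, params)
  rowBlocks <- which(sess@blockInfo$axis == "row")
  expect_equal(postSw[rowBlocks, ], post[rowBlocks, ], tolerance = 1e-12)
})

test_that("OFF-US reports are deterministic and nail separable sessions", {
  sess <- generateFeatureSession(featureGenConfig(K = 15, R = 6, D = 25,
                                                  mu = 1.5, seed = 93))
  rep1 <- runOffUS(sess, groups = 2, couplesPerGroup = 3, seed = 7)
  expect_gte(rep1$meanAccuracy, 95)
  expect_lte(rep1$sdAccuracy, 5)
  rep2 <- runOffUS(sess, groups = 2, couplesPerGroup = 3, seed = 7)
  expect_identical(rep1$texts, rep2$texts)
  expect_equal(rep1$groupAccuracies, rep2$groupAccuracies)
  # degenerate protocol: one group, one couple still works
  rep3 <- runOffUS(sess, groups = 1, couplesPerGroup = 1, seed = 7)
  expect_length(rep3$groupAccuracies, 1L)
})

test_that("OFF-US-T with an empty train session degenerates to OFF-US", {
  sess <- generateFeatureSession(featureGenConfig(K = 10, R = 5, D = 20,
                                                  mu = 1.2, seed = 94))
  a <- runOffUS(sess, groups = 2, couplesPerGroup = 2, seed = 3)
  b <- runOffUST(NULL, sess, groups = 2, couplesPerGroup = 2, seed = 3)
  expect_identical(b$mode, "OFF-US-T")
  expect_identical(a$texts, b$texts)
})

test_that("ON-US-T never touches the test set during training", {
  tr <- generateFeatureSession(featureGenConfig(K = 12, R = 5, D = 20,
                                                mu = 1.2, seed = 95))
  te <- generateFeatureSession(featureGenConfig(
    K = 8, R = 5, D = 20, mu = 1.2,
    wDir = attr(tr, "trueDirection")[1:19], seed = 96))
  rep <- runOnUST(tr, te, groups = 2, couplesPerGroup = 3, seed = 5)
  # the fitted classifiers are a pure function of the train session:
  # replacing the test session leaves them identical
  te2 <- generateFeatureSession(featureGenConfig(
    K = 8, R = 5, D = 20, mu = 1.2,
    wDir = attr(tr, "trueDirection")[1:19], seed = 97))
  rep2 <- runOnUST(tr, te2, groups = 2, couplesPerGroup = 3, seed = 5)
  for (g in 1:2)
    expect_equal(rep$classifiers[[g]]@w, rep2$classifiers[[g]]@w)
  # and spelling the test set does not mutate them (fixed-classifier contract)
  again <- spellSession(te, rep$classifiers[[1]])
  expect_identical(again$text, rep$texts[[1]])
})

test_that("online adaptation helps and hindsight re-evaluation helps further", {
  don <- doa <- dre <- numeric(4)
  for (s in 1:4) {
    tr <- generateFeatureSession(featureGenConfig(K = 20, R = 6, D = 50,
                                                  mu = 0.55, seed = 500 + s))
    te <- generateFeatureSession(featureGenConfig(
      K = 40, R = 6, D = 50, mu = 0.55,
      wDir = attr(tr, "trueDirection")[1:49], seed = 600 + s))
    oa <- runOAUST(tr, te, groups = 3, couplesPerGroup = 5, seed = s)
    don[s] <- oa$onReport$meanAccuracy
    doa[s] <- oa$meanAccuracy
    dre[s] <- oa$meanReAccuracy
  }
  expect_gte(mean(doa), mean(don))
  expect_gte(mean(dre), mean(doa))
})

test_that("adapted classifiers improve on a held-out probe across the stream", {
  tr <- generateFeatureSession(featureGenConfig(K = 15, R = 6, D = 50,
                                                mu = 0.5, seed = 511))
  wd <- attr(tr, "trueDirection")[1:49]
  te <- generateFeatureSession(featureGenConfig(K = 30, R = 6, D = 50,
                                                mu = 0.5, wDir = wd,
                                                seed = 512))
  probe <- generateFeatureSession(featureGenConfig(K = 30, R = 6, D = 50,
                                                   mu = 0.5, wDir = wd,
                                                   seed = 513))
  oa <- runOAUST(tr, te, groups = 1, couplesPerGroup = 5, seed = 2,
                 keepHistory = TRUE)
  y <- trueLabels(probe)
  aucs <- vapply(oa$history[[1]], function(p)
    aucScore(drop(probe@X %*% p@w), y), numeric(1))
  slope <- stats::coef(stats::lm(aucs ~ seq_along(aucs)))[2]
  expect_gt(slope, 0)                       # upward adaptation trend
  expect_gt(mean(utils::tail(aucs, 5)), mean(utils::head(aucs, 5)))
})

test_that("online predictions depend only on already-seen characters", {
  sess <- generateFeatureSession(featureGenConfig(K = 16, R = 8, D = 30,
                                                  mu = 1, seed = 98))
  full <- runOAUS(sess, couples = 3, seed = 11)
  # truncating the stream after m characters reproduces the first m
  # predictions exactly -- including when the removed tail is poisoned
  m <- 9L
  idx <- sort(unique(sess@blockInfo$charIndex))
  prefix <- subsetCharacters(sess, idx[seq_len(m)])
  part <- runOAUS(prefix, couples = 3, seed = 11)
  expect_identical(part$predictionLog$predicted,
                   full$predictionLog$predicted[seq_len(m)])
  expect_equal(part$predictionLog$bestLogLik,
               full$predictionLog$bestLogLik[seq_len(m)])
})

test_that("cold-start spelling works end to end and logs a consistent trace", {
  sess <- generateFeatureSession(featureGenConfig(K = 25, R = 10, D = 40,
                                                  mu = 1.2, seed = 99))
  rep <- runOAUS(sess, couples = 4, seed = 3)
  lg <- rep$predictionLog
  expect_identical(nrow(lg), 25L)
  expect_true(all(lg$cumCorrect == cumsum(lg$correct)))
  expect_true(all(lg$retestCorrect <= seq_len(25)))
  # after warm-up the stream is spelled essentially perfectly
  expect_gte(100 * mean(lg$correct[11:25]), 90)
  tr <- onlineTrace(lg)
  expect_identical(tr$bound, seq_len(25))
  expect_true(all(tr$cumulativeCorrect <= tr$bound))
})

test_that("larger selection pools never hurt expected accuracy", {
  acc1 <- acc5 <- numeric(6)
  for (s in 1:6) {
    sess <- generateFeatureSession(featureGenConfig(K = 12, R = 4, D = 20,
                                                    mu = 0.6, seed = 300 + s))
    r1 <- runOffUS(sess, groups = 1, couplesPerGroup = 1, seed = s)
    r5 <- runOffUS(sess, groups = 1, couplesPerGroup = 5, seed = s)
    acc1[s] <- r1$meanAccuracy
    acc5[s] <- r5$meanAccuracy
  }
  expect_gte(mean(acc5), mean(acc1))
})
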