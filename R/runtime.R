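#' @include em.R
NULL

# rows of blockInfo for one character, ordered (row, column)
.charBlockRows <- function(session, charIndex) {
  i <- which(session@blockInfo$charIndex == charIndex)
  i[match(c("row", "column"), session@blockInfo$axis[i])]
}

# Batched EM iterations for a pool of M classifiers on the same data.
# One symmetric eigendecomposition of XtX per call turns every ridge solve
# into two D x M transforms, and projections/expected labels run as N x M
# BLAS-3 products -- the classifier pools of the online protocols advance in
# lockstep. Returns updated parameters plus the final per-classifier data
# log-likelihood and block posteriors. Numerically equivalent to running
# .emLoop per classifier (same updates, same order).
.emIterateBatch <- function(pool, W, beta, alpha, nIter, alphaCap,
                            betaFloor, updateAlpha, XtX,
                            skipAlpha = FALSE, eig = NULL) {
  M <- ncol(W); D <- pool$D
  J <- pool$J; B <- pool$B
  nbJ <- rep(pool$nb, each = J)  # J x B flattened
  if (is.null(eig)) eig <- eigen(XtX, symmetric = TRUE)
  V <- eig$vectors; ev <- eig$values
  blockLoglik <- function(P, beta) {
    # -> array J x B x M of per-candidate block log-likelihoods
    S <- rowsum(P, pool$grp)                 # (B*J) x M, j fast within b
    Q <- rowsum(P * P, pool$blockId)         # B x M
    Tbm <- Q + 2 * colSums(array(S, c(J, B, M))) + pool$nb
    sse <- array(rep(Tbm, each = J), c(J, B, M)) - 4 * array(S, c(J, B, M))
    bArr <- array(rep(beta, each = J * B), c(J, B, M))
    -(array(nbJ, c(J, B, M)) / 2) * log(2 * pi * bArr) - sse / (2 * bArr)
  }
  posteriorFromL <- function(L) {
    Lm <- matrix(L, J, B * M)
    mx <- apply(Lm, 2L, max)
    pw <- exp(sweep(Lm, 2L, mx, "-"))
    array(sweep(pw, 2L, colSums(pw), "/"), c(J, B, M))
  }
  EY <- matrix(0, pool$N, M)
  idx <- cbind(pool$flashIdx1, pool$blockId)
  P <- pool$X %*% W
  if (!all(is.finite(P)))
    stop("non-finite projection in block(s) ",
         paste(unique(pool$blockId[!is.finite(rowSums(P))]), collapse = ", "))
  for (it in seq_len(nIter)) {
    post <- posteriorFromL(blockLoglik(P, beta))
    for (m in seq_len(M)) EY[, m] <- 2 * post[, , m][idx] - 1
    Bmat <- crossprod(pool$X, EY)
    lam <- beta * alpha
    W <- V %*% (crossprod(V, Bmat) / outer(ev, lam, "+"))
    P <- pool$X %*% W
    beta <- pmax(colMeans(P * P - 2 * P * EY + 1), betaFloor)
    if (updateAlpha && !skipAlpha) {
      wtw <- colSums(W * W)
      alpha <- ifelse(wtw > 0, pmin(D / wtw, alphaCap), min(1e12, alphaCap))
    }
  }
  L <- blockLoglik(P, beta) - log(J)
  Lm <- matrix(L, J, B * M)
  mx <- apply(Lm, 2L, max)
  ll <- colSums(matrix(mx + log(colSums(exp(sweep(Lm, 2L, mx, "-")))), B, M))
  list(W = W, beta = beta, alpha = alpha, loglik = ll,
       posteriors = posteriorFromL(L),
       degenerate = alpha > 1e6 | beta <= betaFloor)
}

# prefix of a pooled session covering the first B blocks
.poolPrefix <- function(pf, B) {
  n <- sum(pf$nb[seq_len(B)])
  list(X = pf$X[seq_len(n), , drop = FALSE],
       grp = pf$grp[seq_len(n)],
       blockId = pf$blockId[seq_len(n)],
       flashIdx1 = pf$flashIdx1[seq_len(n)],
       B = B, J = pf$J, nb = pf$nb[seq_len(B)], N = n, D = pf$D)
}

#' Predict one character from its two pseudo-symbol blocks
#'
#' Runs the exact E-step on the row-axis and column-axis blocks and takes
#' the maximum-posterior row and column (lowest index on ties); the grid
#' cell at that coordinate is the predicted character.
#'
#' @param rowBlock,colBlock [PseudoSymbolBlock-class] of the same character
#' @param params a [ClassifierParams-class]
#' @param grid a [SpellerGrid-class]
#' @return a [CharacterPrediction-class]
#' @export
predictCharacter <- function(rowBlock, colBlock, params,
                             grid = defaultGrid()) {
  if (rowBlock@charIndex != colBlock@charIndex)
    stop("row and column blocks must belong to the same character")
  if (rowBlock@axis != "row" || colBlock@axis != "column")
    stop("expected a row-axis and a column-axis block, in that order")
  rp <- eStepBlock(rowBlock, params@w, params@beta)
  cp <- eStepBlock(colBlock, params@w, params@beta)
  r <- which.max(rp) - 1L
  cc <- which.max(cp) - 1L
  new("CharacterPrediction", charIndex = rowBlock@charIndex,
      rowPosterior = rp, colPosterior = cp,
      predictedChar = gridLookup(grid, r, cc),
      joint = outer(rp, cp))
}

setMethod("show", "CharacterPrediction", function(object) {
  cat(sprintf("CharacterPrediction: char %d -> '%s' (row p=%.3f, col p=%.3f)\n",
              object@charIndex, object@predictedChar,
              max(object@rowPosterior), max(object@colPosterior)))
})

# spell every character of a pooled session from a B x J posterior matrix
.spellFromPosteriors <- function(session, post) {
  chars <- sort(unique(session@blockInfo$charIndex))
  grid <- session@grid
  txt <- character(length(chars))
  rowmax <- integer(length(chars)); colmax <- integer(length(chars))
  for (i in seq_along(chars)) {
    rc <- .charBlockRows(session, chars[i])
    rowmax[i] <- which.max(post[rc[1], ]) - 1L
    colmax[i] <- which.max(post[rc[2], ]) - 1L
    txt[i] <- gridLookup(grid, rowmax[i], colmax[i])
  }
  list(chars = chars, text = txt, rowmax = rowmax, colmax = colmax)
}

#' Spell a whole session with a fixed classifier
#'
#' @param session a [SessionFeatures-class]
#' @param params a [ClassifierParams-class]
#' @return list with `text` (predicted characters), `predictions` (list of
#'   [CharacterPrediction-class]) and `accuracy` (percentage, `NA` when the
#'   session is unlabeled)
#' @export
spellSession <- function(session, params) {
  post <- eStepSession(session, params)
  sp <- .spellFromPosteriors(session, post)
  preds <- lapply(seq_along(sp$chars), function(i) {
    rc <- .charBlockRows(session, sp$chars[i])
    new("CharacterPrediction", charIndex = as.integer(sp$chars[i]),
        rowPosterior = post[rc[1], ], colPosterior = post[rc[2], ],
        predictedChar = sp$text[i],
        joint = outer(post[rc[1], ], post[rc[2], ]))
  })
  truth <- sessionTruth(session)
  acc <- if (is.null(truth)) NA_real_ else spellingAccuracy(sp$text, truth)
  list(text = sp$text, predictions = preds, accuracy = acc)
}

# fit one group: couples -> 2*cpg classifiers -> fit -> select
.fitGroup <- function(session, couplesPerGroup, config, groupSeed, XtX,
                      selectSession = NULL, selectXtXunused = NULL) {
  couples <- initCouples(featureDim(session), couplesPerGroup,
                         seed = groupSeed)
  inits <- unlist(couples, recursive = FALSE)
  fits <- lapply(inits, function(p) emFit(session, p, config, XtX = XtX))
  fitted <- lapply(fits, `[[`, "params")
  sel <- selectBest(fitted, if (is.null(selectSession)) session
                            else selectSession)
  list(params = fitted[[sel]], selected = sel, fitted = fitted,
       traces = lapply(fits, `[[`, "trace"))
}

.spellerReport <- function(mode, groupResults, spellTexts, accuracies,
                           predictions, extra = list()) {
  structure(c(list(
    mode = mode,
    groupAccuracies = accuracies,
    meanAccuracy = mean(accuracies, na.rm = TRUE),
    sdAccuracy = stats::sd(accuracies),
    texts = spellTexts,
    classifiers = lapply(groupResults, `[[`, "params"),
    predictions = predictions), extra),
    class = "spellerReport")
}

#' @export
print.spellerReport <- function(x, ...) {
  cat(sprintf("%s speller report: %d group(s)\n", x$mode,
              length(x$groupAccuracies)))
  if (all(is.na(x$groupAccuracies))) {
    cat("  unlabeled session: no accuracy available\n")
  } else {
    cat(sprintf("  spelling accuracy: mean %.1f%%, sd %.1f (groups: %s)\n",
                x$meanAccuracy, x$sdAccuracy,
                paste(sprintf("%.1f", x$groupAccuracies), collapse = ", ")))
  }
  cat(sprintf("  first group spelled: %s\n",
              paste(x$texts[[1]], collapse = "")))
  invisible(x)
}

#' OFF-US: offline unsupervised training on the test session
#'
#' Per group, draws `couplesPerGroup` initialization couples (twice as many
#' classifiers), fits each by EM on the session, selects the one with the
#' highest data log-likelihood, and spells the whole session with it.
#' Repeating over `groups` independent initializations averages out
#' initialization variance; the report carries mean and sd accuracy.
#'
#' @param session a [SessionFeatures-class] (the unlabeled test session)
#' @param groups number of independent groups (default 10)
#' @param couplesPerGroup couples per group (default 10, i.e. 20 classifiers)
#' @param config an [EMConfig-class]
#' @param seed master seed; all group initializations derive from it
#' @return a `spellerReport`
#' @export
runOffUS <- function(session, groups = 10L, couplesPerGroup = 10L,
                     config = emConfig(), seed = 1L) {
  set.seed(seed)
  groupSeeds <- sample.int(2^31 - 2, groups)
  XtX <- crossprod(session@X)
  truth <- sessionTruth(session)
  gr <- vector("list", groups); texts <- vector("list", groups)
  acc <- rep(NA_real_, groups); preds <- vector("list", groups)
  for (g in seq_len(groups)) {
    gr[[g]] <- tryCatch(
      .fitGroup(session, couplesPerGroup, config, groupSeeds[g], XtX),
      error = function(e) e)
    if (inherits(gr[[g]], "error")) next
    sp <- spellSession(session, gr[[g]]$params)
    texts[[g]] <- sp$text; acc[g] <- sp$accuracy; preds[[g]] <- sp$predictions
  }
  failed <- vapply(gr, inherits, logical(1), "error")
  if (any(failed))
    warning(sum(failed), " group(s) failed to fit and were recorded as NA")
  .spellerReport("OFF-US", gr[!failed], texts, acc, preds,
                 extra = list(failedGroups = which(failed), seed = seed))
}

#' OFF-US-T: offline unsupervised training on train + test
#'
#' As [runOffUS()] but EM runs on the concatenation of the (unlabeled)
#' train and test sessions; spelling is evaluated on the test part only.
#' More unlabeled data stabilizes both convergence and selection.
#'
#' @param trainSession a [SessionFeatures-class] or NULL (degenerates to
#'   [runOffUS()])
#' @param testSession a [SessionFeatures-class]
#' @inheritParams runOffUS
#' @return a `spellerReport`
#' @export
runOffUST <- function(trainSession, testSession, groups = 10L,
                      couplesPerGroup = 10L, config = emConfig(),
                      seed = 1L) {
  if (is.null(trainSession) || nCharacters(trainSession) == 0) {
    rep <- runOffUS(testSession, groups, couplesPerGroup, config, seed)
    rep$mode <- "OFF-US-T"
    return(rep)
  }
  combined <- concatSessions(trainSession, testSession)
  set.seed(seed)
  groupSeeds <- sample.int(2^31 - 2, groups)
  XtX <- crossprod(combined@X)
  gr <- vector("list", groups); texts <- vector("list", groups)
  acc <- rep(NA_real_, groups); preds <- vector("list", groups)
  for (g in seq_len(groups)) {
    gr[[g]] <- .fitGroup(combined, couplesPerGroup, config, groupSeeds[g], XtX)
    sp <- spellSession(testSession, gr[[g]]$params)
    texts[[g]] <- sp$text; acc[g] <- sp$accuracy; preds[[g]] <- sp$predictions
  }
  .spellerReport("OFF-US-T", gr, texts, acc, preds, extra = list(seed = seed))
}

#' ON-US-T: unsupervised training on the train session, fixed online use
#'
#' Fits and selects classifiers on the train session only (selection
#' likelihood evaluated on train); the selected classifier per group is then
#' applied, unchanged, to the test session. No test data enters training.
#'
#' @inheritParams runOffUST
#' @return a `spellerReport`; `$classifiers` holds the per-group selected
#'   classifiers (the initialization the adaptive protocol reuses)
#' @export
runOnUST <- function(trainSession, testSession, groups = 10L,
                     couplesPerGroup = 10L, config = emConfig(),
                     seed = 1L) {
  set.seed(seed)
  groupSeeds <- sample.int(2^31 - 2, groups)
  XtX <- crossprod(trainSession@X)
  gr <- vector("list", groups); texts <- vector("list", groups)
  acc <- rep(NA_real_, groups); preds <- vector("list", groups)
  for (g in seq_len(groups)) {
    gr[[g]] <- .fitGroup(trainSession, couplesPerGroup, config, groupSeeds[g],
                         XtX)
    sp <- spellSession(testSession, gr[[g]]$params)
    texts[[g]] <- sp$text; acc[g] <- sp$accuracy; preds[[g]] <- sp$predictions
  }
  .spellerReport("ON-US-T", gr, texts, acc, preds, extra = list(seed = seed))
}

# adaptive pass of one classifier over the test stream, pool = train + seen
.adaptStream <- function(trainSession, testSession, params, config,
                         keepHistory = FALSE) {
  combined <- concatSessions(trainSession, testSession)
  pf <- .poolInfo(combined)
  Btrain <- nrow(trainSession@blockInfo)
  testChars <- sort(unique(testSession@blockInfo$charIndex))
  K <- length(testChars)
  grid <- testSession@grid
  XtX <- crossprod(trainSession@X)
  predicted <- character(K)
  history <- if (keepHistory) vector("list", K) else NULL
  testBlocks <- sessionBlocks(testSession)
  nPrev <- nrow(trainSession@X)
  for (k in seq_len(K)) {
    B <- Btrain + 2L * k
    pool <- .poolPrefix(pf, B)
    XtX <- XtX + crossprod(pf$X[(nPrev + 1L):pool$N, , drop = FALSE])
    nPrev <- pool$N
    res <- .emLoop(pool, params, nIter = config@nEmAdaptive, relTol = 0,
                   updateAlpha = config@updateAlpha,
                   alphaCap = config@alphaCap,
                   betaFloor = config@betaFloor, XtX = XtX)
    params <- res$params
    rc <- .charBlockRows(testSession, testChars[k])
    predicted[k] <- predictCharacter(testBlocks[[rc[1]]], testBlocks[[rc[2]]],
                                     params, grid)@predictedChar
    if (keepHistory) history[[k]] <- params
  }
  list(params = params, predicted = predicted, history = history)
}

#' OA-US-T: online adaptation starting from the ON-US-T classifiers
#'
#' Reuses the classifier selected per group on the train session. For each
#' incoming test character its (unlabeled) blocks are appended to the pool
#' and exactly `nEmAdaptive` (default 3) EM iterations are run before the
#' character is predicted. The report also carries the hindsight
#' re-evaluation of the final classifier on the whole test session
#' (RE-OA-US-T).
#'
#' @inheritParams runOffUST
#' @param onReport optionally, a precomputed [runOnUST()] report to reuse
#'   (saves refitting when both protocols are compared on the same streams)
#' @param keepHistory record per-character classifier snapshots (for AUC
#'   trace analyses)
#' @return a `spellerReport` with extra fields `reAccuracies`
#'   (RE-OA-US-T per group), `onReport` and optional `history`
#' @export
runOAUST <- function(trainSession, testSession, groups = 10L,
                     couplesPerGroup = 10L, config = emConfig(),
                     seed = 1L, onReport = NULL, keepHistory = FALSE) {
  if (is.null(onReport))
    onReport <- runOnUST(trainSession, testSession, groups, couplesPerGroup,
                         config, seed)
  truth <- sessionTruth(testSession)
  G <- length(onReport$classifiers)
  texts <- vector("list", G); acc <- rep(NA_real_, G)
  reAcc <- rep(NA_real_, G); finals <- vector("list", G)
  hist <- vector("list", G)
  for (g in seq_len(G)) {
    ad <- .adaptStream(trainSession, testSession, onReport$classifiers[[g]],
                       config, keepHistory = keepHistory)
    texts[[g]] <- ad$predicted
    finals[[g]] <- ad$params
    hist[[g]] <- ad$history
    if (!is.null(truth)) {
      acc[g] <- spellingAccuracy(ad$predicted, truth)
      reAcc[g] <- spellSession(testSession, ad$params)$accuracy
    }
  }
  out <- .spellerReport("OA-US-T",
                        lapply(finals, function(p) list(params = p)),
                        texts, acc, list(),
                        extra = list(reAccuracies = reAcc,
                                     meanReAccuracy = mean(reAcc),
                                     onReport = onReport, seed = seed))
  if (keepHistory) out$history <- hist
  out
}

#' OA-US: cold-start online spelling without any prior data
#'
#' The most demanding protocol: the classifier pool starts untrained with
#' no data at all. A single group of `couples` initialization couples is
#' maintained. Per incoming character, every classifier runs `nEmAdaptive`
#' EM iterations on all data seen so far; the character is predicted by the
#' classifier with the highest data log-likelihood. After the prediction,
#' within each couple the member with the higher data log-likelihood is
#' kept, its beta and alpha are copied to the partner, and the partner's
#' weight vector is reset to the negation of the kept one -- so the two
#' members keep attacking the data with opposite label hypotheses. Alpha is
#' capped throughout (default 1e4), and alpha updates are skipped while
#' fewer than `warmupChars` characters have been seen, because with almost
#' no data the degenerate optimum is otherwise reached instantly. Early
#' characters are near chance by construction; once enough unlabeled data
#' has accumulated the classifier snaps into place (the "eureka"
#' transition).
#'
#' @param testSession a [SessionFeatures-class] processed as a stream
#' @param couples initialization couples in the group (default 10)
#' @param config an [EMConfig-class]; the default here caps alpha at 1e4
#' @param seed master seed
#' @param warmupChars characters before alpha updates start (default 3)
#' @return a `spellerReport` whose `predictionLog` data.frame holds, per
#'   character: the prediction, correctness (when truth is available), the
#'   cumulative number of correct online predictions, and the retest count
#'   (characters among those seen that the current classifier spells
#'   correctly)
#' @export
runOAUS <- function(testSession, couples = 10L,
                    config = emConfig(alphaCap = 1e4), seed = 1L,
                    warmupChars = 3L) {
  set.seed(seed)
  pf <- .poolInfo(testSession)
  D <- pf$D
  cps <- initCouples(D, couples)
  nc <- 2L * couples
  W <- do.call(cbind, lapply(unlist(cps, recursive = FALSE), slot, "w"))
  betaV <- rep(1, nc); alphaV <- rep(1, nc)
  testChars <- sort(unique(testSession@blockInfo$charIndex))
  K <- length(testChars)
  grid <- testSession@grid
  truth <- sessionTruth(testSession)
  predicted <- character(K)
  correct <- rep(NA, K); cumCorrect <- rep(NA_integer_, K)
  retest <- rep(NA_integer_, K); bestLL <- numeric(K)
  XtX <- matrix(0, D, D)
  nPrev <- 0L
  for (k in seq_len(K)) {
    pool <- .poolPrefix(pf, 2L * k)
    XtX <- XtX + crossprod(pf$X[(nPrev + 1L):pool$N, , drop = FALSE])
    nPrev <- pool$N
    st <- .emIterateBatch(pool, W, betaV, alphaV,
                          nIter = config@nEmAdaptive,
                          alphaCap = config@alphaCap,
                          betaFloor = config@betaFloor,
                          updateAlpha = config@updateAlpha, XtX = XtX,
                          skipAlpha = k < warmupChars)
    W <- st$W; betaV <- st$beta; alphaV <- st$alpha
    ll <- st$loglik
    best <- which.max(ll)
    bestLL[k] <- ll[best]
    post <- t(st$posteriors[, , best])  # B x J, blocks of the first k chars
    rc <- .charBlockRows(testSession, testChars[k])  # block ids = row ids here
    predicted[k] <- gridLookup(grid, which.max(post[rc[1], ]) - 1L,
                               which.max(post[rc[2], ]) - 1L)
    if (!is.null(truth)) {
      correct[k] <- predicted[k] == truth[k]
      cumCorrect[k] <- sum(correct[seq_len(k)])
      re <- vapply(seq_len(k), function(i) {
        rci <- .charBlockRows(testSession, testChars[i])
        gridLookup(grid, which.max(post[rci[1], ]) - 1L,
                   which.max(post[rci[2], ]) - 1L)
      }, character(1))
      retest[k] <- sum(re == truth[seq_len(k)])
    }
    # couple reinitialization: keep the better member, mirror the other
    for (ci in seq_len(couples)) {
      i1 <- 2L * ci - 1L; i2 <- 2L * ci
      keep <- if (ll[i1] >= ll[i2]) i1 else i2
      drop_ <- if (keep == i1) i2 else i1
      W[, drop_] <- -W[, keep]
      betaV[drop_] <- betaV[keep]
      alphaV[drop_] <- alphaV[keep]
    }
  }
  classifiers <- lapply(seq_len(nc), function(i)
    classifierParams(W[, i], beta = betaV[i], alpha = alphaV[i]))
  logdf <- data.frame(charIndex = testChars, predicted = predicted,
                      correct = correct, cumCorrect = cumCorrect,
                      retestCorrect = retest, bestLogLik = bestLL)
  acc <- if (is.null(truth)) NA_real_ else 100 * mean(correct)
  structure(list(
    mode = "OA-US", predictionLog = logdf,
    accuracy = acc,
    text = predicted,
    classifiers = classifiers,
    groupAccuracies = acc, meanAccuracy = acc, sdAccuracy = NA_real_,
    texts = list(predicted),
    seed = seed), class = "spellerReport")
}

#' Export a speller report to JSON
#'
#' Per-character predictions, accuracies and (for online runs) the
#' prediction log, written as a JSON report.
#'
#' @param report a `spellerReport`
#' @param path file path
#' @return `path`, invisibly
#' @export
exportReport <- function(report, path) {
  keep <- list(mode = report$mode,
               meanAccuracy = report$meanAccuracy,
               sdAccuracy = report$sdAccuracy,
               groupAccuracies = report$groupAccuracies,
               texts = lapply(report$texts, paste, collapse = ""))
  if (!is.null(report$predictionLog))
    keep$predictionLog <- report$predictionLog
  if (!is.null(report$reAccuracies))
    keep$reAccuracies <- report$reAccuracies
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
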