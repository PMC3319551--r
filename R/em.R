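#' @include model.R
NULL

#' Construct an EM configuration
#'
#' @param maxIter maximum EM iterations (default 100)
#' @param relTol relative change of the MAP objective at which the loop
#'   stops (default 1e-5; 0 disables the check and forces `maxIter`
#'   iterations)
#' @param nEmAdaptive EM iterations per incoming character in the online
#'   adaptive protocols (default 3)
#' @param updateAlpha re-estimate the prior precision (default TRUE)
#' @param alphaCap upper bound on alpha; `Inf` disables capping. Offline
#'   fits default to no cap; the cold-start online protocol bounds alpha
#'   (default there 1e4) because the degenerate optimum `w -> 0,
#'   alpha -> Inf` is easily reached on very little data.
#' @param betaFloor lower bound on beta (default 1e-8)
#' @param seed integer seed used by initialization helpers
#' @return an [EMConfig-class]
#' @export
emConfig <- function(maxIter = 100L, relTol = 1e-5, nEmAdaptive = 3L,
                     updateAlpha = TRUE, alphaCap = Inf, betaFloor = 1e-8,
                     seed = 1L) {
  new("EMConfig", maxIter = as.integer(maxIter), relTol = relTol,
      nEmAdaptive = as.integer(nEmAdaptive), updateAlpha = updateAlpha,
      alphaCap = alphaCap, betaFloor = betaFloor, seed = as.integer(seed))
}

#' @describeIn traceTable trace table accessor
#' @export
setMethod("traceTable", "FitTrace", function(x) x@table)

setMethod("show", "FitTrace", function(object) {
  tb <- object@table
  n <- nrow(tb)
  cat(sprintf("FitTrace: %d iterations, final objective %.6g, beta %.4g, alpha %.4g%s\n",
              n, tb$objective[n], tb$beta[n], tb$alpha[n],
              if (any(tb$degenerate)) " [degeneracy flagged]" else ""))
})

#' Export a fit trace as CSV
#' @param trace a [FitTrace-class]
#' @param path file path
#' @return `path`, invisibly
#' @export
exportTrace <- function(trace, path) {
  data.table::fwrite(traceTable(trace), path)
  invisible(path)
}

# ---- internal pooled-session machinery -------------------------------------

# Precomputed index structure for fast whole-session E/M steps.
.poolInfo <- function(session) {
  J <- gridSize(session)
  B <- nrow(session@blockInfo)
  list(X = session@X,
       grp = (session@blockId - 1L) * J + session@flashIndex + 1L,
       blockId = session@blockId,
       flashIdx1 = session@flashIndex + 1L,
       B = B, J = J,
       nb = session@blockInfo$R * J,
       N = nrow(session@X), D = ncol(session@X))
}

# Per-block candidate log-likelihoods L[b, c] = log p(block b | indicator c-1)
# from projections p. Uses sum((p - y)^2) = Q_b + n_b + 2 S_b - 4 S_bc.
.blockCandLoglik <- function(pool, p, beta) {
  S <- matrix(rowsum(p, pool$grp), pool$B, pool$J, byrow = TRUE)
  Qb <- drop(rowsum(p^2, pool$blockId))
  sse <- Qb + pool$nb + 2 * rowSums(S) - 4 * S
  -(pool$nb / 2) * log(2 * pi * beta) - sse / (2 * beta)
}

# E-step over all blocks: posterior matrix B x J.
.eStepPooled <- function(pool, w, beta) {
  p <- drop(pool$X %*% w)
  if (!all(is.finite(p)))
    stop("non-finite projection in block(s) ",
         paste(unique(pool$blockId[!is.finite(p)]), collapse = ", "))
  L <- .blockCandLoglik(pool, p, beta) - log(pool$J)
  post <- exp(L - .logsumexpRows(L))
  post / rowSums(post)
}

# Data log-likelihood (MAP objective without the weight prior).
.dataTerm <- function(pool, w, beta) {
  p <- drop(pool$X %*% w)
  L <- .blockCandLoglik(pool, p, beta) - log(pool$J)
  sum(.logsumexpRows(L))
}

.asPosteriorMatrix <- function(posteriors, B, J) {
  if (is.list(posteriors)) posteriors <- do.call(rbind, posteriors)
  if (is.null(dim(posteriors))) posteriors <- matrix(posteriors, 1L)
  stopifnot(nrow(posteriors) == B, ncol(posteriors) == J)
  posteriors
}

# ---- spec-level operations -------------------------------------------------

#' E-step for one pseudo-symbol block
#'
#' Exact posterior over the J possible indicator values: under indicator c,
#' the block's R*J intensifications carry labels +1 at flash position c and
#' -1 elsewhere, identically across repetitions. With the uniform indicator
#' prior, `probs[c]` is proportional to the product of projection
#' likelihoods under that labeling; computed with log-sum-exp.
#'
#' @param block a [PseudoSymbolBlock-class]
#' @param w weight vector
#' @param beta noise variance
#' @return numeric J-vector of posterior probabilities (sums to 1)
#' @export
eStepBlock <- function(block, w, beta) {
  f <- block@features
  R <- dim(f)[1]; J <- dim(f)[2]; D <- dim(f)[3]
  p <- matrix(f, R * J, D) %*% w  # rows: flash-major? no -- see below
  # matrix(f, R*J, D) flattens (r, j) with r fast; track flash index per row
  flash <- rep(seq_len(J), each = R)
  if (!all(is.finite(p)))
    stop("non-finite projection in block (char ", block@charIndex, ", ",
         block@axis, ")")
  ll <- vapply(seq_len(J), function(c1) {
    y <- ifelse(flash == c1, 1, -1)
    sum(-0.5 * log(2 * pi * beta) - (p - y)^2 / (2 * beta))
  }, numeric(1))
  lg <- ll - log(J)
  post <- exp(lg - max(lg) - log(sum(exp(lg - max(lg)))))
  post / sum(post)
}

#' Expected labels of a block under an indicator posterior
#'
#' Marginalizing the +/-1 labels over the indicator gives
#' `E[y at flash j] = 2 probs[j] - 1`, identical across repetitions --
#' the quantity the posterior-weighted ridge update consumes.
#'
#' @param posterior numeric J-vector (normalized)
#' @param block a [PseudoSymbolBlock-class]
#' @return numeric matrix R x J of expected labels
#' @export
expectedLabels <- function(posterior, block) {
  R <- dim(block@features)[1]; J <- dim(block@features)[2]
  stopifnot(length(posterior) == J, abs(sum(posterior) - 1) < 1e-9)
  matrix(rep(2 * posterior - 1, each = R), R, J)
}

#' M-step for the weight vector
#'
#' The update is the posterior-weighted sum of the ridge solutions over all
#' indicator assignments; by linearity of the solve in the response this
#' collapses to a single ridge solve against the expected labels:
#' `w = solve(X^T X + beta alpha I, X^T E[y])` over all intensifications.
#'
#' @param session a [SessionFeatures-class]
#' @param posteriors B x J matrix (or list of J-vectors) of indicator
#'   posteriors, rows in session block order
#' @param beta,alpha current noise variance and prior precision
#' @param XtX optional precomputed `crossprod` of the pooled design
#' @return updated weight vector
#' @export
mStepW <- function(session, posteriors, beta, alpha, XtX = NULL) {
  pool <- .poolInfo(session)
  post <- .asPosteriorMatrix(posteriors, pool$B, pool$J)
  ey <- 2 * post[cbind(pool$blockId, pool$flashIdx1)] - 1
  ridgeMap(pool$X, ey, beta * alpha, XtX = XtX)
}

#' M-step for the noise variance
#'
#' The posterior-weighted mean squared error between the projection and the
#' target labels, via the per-intensification simplification
#' `(w^T x)^2 - 2 (w^T x) E[y] + 1`, floored at `betaFloor`.
#'
#' @param session a [SessionFeatures-class]
#' @param posteriors B x J posterior matrix (or list)
#' @param w weight vector
#' @param betaFloor lower bound (default 1e-8)
#' @return updated beta
#' @export
mStepBeta <- function(session, posteriors, w, betaFloor = 1e-8) {
  pool <- .poolInfo(session)
  post <- .asPosteriorMatrix(posteriors, pool$B, pool$J)
  ey <- 2 * post[cbind(pool$blockId, pool$flashIdx1)] - 1
  p <- drop(pool$X %*% w)
  max(mean(p^2 - 2 * p * ey + 1), betaFloor)
}

#' M-step for the prior precision
#'
#' `alpha = D / (w^T w)`, optionally capped. The uncapped update admits the
#' degenerate global optimum `w -> 0, alpha -> Inf`; a finite cap is the
#' guard used by the cold-start online protocol.
#'
#' @param w weight vector
#' @param D dimensionality (default `length(w)`)
#' @param alphaCap upper bound (default `Inf`)
#' @return updated alpha
#' @export
mStepAlpha <- function(w, D = length(w), alphaCap = Inf) {
  wtw <- sum(w^2)
  if (wtw == 0)
    stop("degenerate update: w = 0 reaches the pathological global optimum")
  a <- D / wtw
  if (a > alphaCap) {
    warning(sprintf("alpha update %.3g capped at %.3g", a, alphaCap))
    a <- alphaCap
  }
  a
}

#' MAP objective of the constrained model
#'
#' Sum over pseudo-symbol blocks of the log marginal likelihood
#' (log-sum-exp over the J indicator values with uniform prior) plus the
#' log weight prior. The quantity EM ascends.
#'
#' @param session a [SessionFeatures-class]
#' @param params a [ClassifierParams-class]
#' @return scalar objective
#' @export
mapObjective <- function(session, params) {
  pool <- .poolInfo(session)
  val <- .dataTerm(pool, params@w, params@beta) +
    logPriorW(params@w, params@alpha)
  if (!is.finite(val)) stop("non-finite MAP objective")
  val
}

#' Data log-likelihood of a session under a classifier
#'
#' The MAP objective without the weight prior term: the criterion used to
#' select among randomly initialized classifiers.
#'
#' @param session a [SessionFeatures-class]
#' @param params a [ClassifierParams-class]
#' @return scalar log-likelihood
#' @export
dataLogLik <- function(session, params) {
  .dataTerm(.poolInfo(session), params@w, params@beta)
}

# ---- the EM loop -----------------------------------------------------------

# Core loop shared by offline fits and online 3-iteration updates.
# relTol = 0 forces exactly nIter iterations. skipAlpha overrides
# updateAlpha (online warm-up). Returns params + trace data.frame.
.emLoop <- function(pool, params, nIter, relTol, updateAlpha, alphaCap,
                    betaFloor, XtX = NULL, skipAlpha = FALSE) {
  if (is.null(XtX)) XtX <- crossprod(pool$X)
  w <- params@w; beta <- params@beta; alpha <- params@alpha
  tr <- vector("list", nIter)
  prevObj <- NA_real_
  it <- 0L
  repeat {
    it <- it + 1L
    post <- .eStepPooled(pool, w, beta)
    ey <- 2 * post[cbind(pool$blockId, pool$flashIdx1)] - 1
    w <- ridgeMap(pool$X, ey, beta * alpha, XtX = XtX)
    p <- drop(pool$X %*% w)
    beta <- max(mean(p^2 - 2 * p * ey + 1), betaFloor)
    wtw <- sum(w^2)
    if (updateAlpha && !skipAlpha) {
      if (wtw == 0) {
        alpha <- min(1e12, alphaCap)  # degenerate; flagged below
      } else {
        alpha <- min(pool$D / wtw, alphaCap)
      }
    }
    obj <- .dataTerm(pool, w, beta) + logPriorW(w, alpha)
    degen <- (alpha > 1e6) || (beta <= betaFloor) || wtw == 0 ||
      !is.finite(obj)
    tr[[it]] <- data.frame(
      iteration = it, objective = obj, beta = beta, alpha = alpha,
      wnorm2 = wtw, degenerate = degen)
    if (!is.finite(obj)) break  # degenerate optimum reached; surfaced via trace
    if (it >= nIter) break
    if (relTol > 0 && !is.na(prevObj) &&
        abs(obj - prevObj) < relTol * abs(obj)) break
    prevObj <- obj
  }
  list(params = classifierParams(w, beta = beta, alpha = alpha,
                                 pi1 = params@pi1),
       trace = do.call(rbind, tr[seq_len(it)]))
}

#' Fit the constrained classifier by EM
#'
#' Iterates the exact E-step over the per-block indicator posteriors and the
#' closed-form M-steps for w, beta and (optionally) alpha, in that order,
#' each using the freshest values, until the relative change of the MAP
#' objective falls below `relTol` or `maxIter` is reached. The objective is
#' non-decreasing across iterations; a run approaching the degenerate
#' optimum (`w -> 0`, `alpha -> Inf`) is flagged in the trace.
#'
#' @param session a [SessionFeatures-class]
#' @param init a [ClassifierParams-class] initial setting (see
#'   [initCouples()])
#' @param config an [EMConfig-class]
#' @param XtX optional precomputed crossprod of the pooled design matrix
#'   (shared across a classifier pool)
#' @return list with elements `params` ([ClassifierParams-class]) and
#'   `trace` ([FitTrace-class])
#' @export
emFit <- function(session, init, config = emConfig(), XtX = NULL) {
  stopifnot(is(session, "SessionFeatures"), is(init, "ClassifierParams"))
  if (nrow(session@X) == 0) stop("session is empty")
  pool <- .poolInfo(session)
  res <- .emLoop(pool, init, nIter = config@maxIter, relTol = config@relTol,
                 updateAlpha = config@updateAlpha, alphaCap = config@alphaCap,
                 betaFloor = config@betaFloor, XtX = XtX)
  if (any(res$trace$degenerate) && is.infinite(config@alphaCap))
    warning("EM approached the degenerate optimum (w -> 0); see the trace")
  list(params = res$params, trace = new("FitTrace", table = res$trace))
}

#' Fit the unconstrained classifier by EM (ablation)
#'
#' The same loop but without the paradigm constraint: every
#' intensification's label is an independent latent with prior `pi1`, so the
#' E-step reduces to [labelPosterior()] per intensification. Expected to
#' perform clearly worse than the constrained model -- the structured
#' indicator is what makes unsupervised training work.
#'
#' @inheritParams emFit
#' @return list with `params` and `trace` as in [emFit()]
#' @export
emFitUnconstrained <- function(session, init, config = emConfig(),
                               XtX = NULL) {
  pool <- .poolInfo(session)
  if (is.null(XtX)) XtX <- crossprod(pool$X)
  w <- init@w; beta <- init@beta; alpha <- init@alpha; pi1 <- init@pi1
  tr <- vector("list", config@maxIter)
  prevObj <- NA_real_; it <- 0L
  repeat {
    it <- it + 1L
    p <- drop(pool$X %*% w)
    lp <- log(pi1) - 0.5 * log(2 * pi * beta) - (p - 1)^2 / (2 * beta)
    lm <- log1p(-pi1) - 0.5 * log(2 * pi * beta) - (p + 1)^2 / (2 * beta)
    prob <- 1 / (1 + exp(lm - lp))
    ey <- 2 * prob - 1
    w <- ridgeMap(pool$X, ey, beta * alpha, XtX = XtX)
    p <- drop(pool$X %*% w)
    beta <- max(mean(p^2 - 2 * p * ey + 1), config@betaFloor)
    wtw <- sum(w^2)
    if (config@updateAlpha && wtw > 0)
      alpha <- min(pool$D / wtw, config@alphaCap)
    lp <- log(pi1) - 0.5 * log(2 * pi * beta) - (p - 1)^2 / (2 * beta)
    lm <- log1p(-pi1) - 0.5 * log(2 * pi * beta) - (p + 1)^2 / (2 * beta)
    mx <- pmax(lp, lm)
    obj <- sum(mx + log(exp(lp - mx) + exp(lm - mx))) + logPriorW(w, alpha)
    tr[[it]] <- data.frame(
      iteration = it, objective = obj, beta = beta, alpha = alpha,
      wnorm2 = wtw,
      degenerate = (alpha > 1e6) || (beta <= config@betaFloor) || wtw == 0)
    if (it >= config@maxIter) break
    if (config@relTol > 0 && !is.na(prevObj) &&
        abs(obj - prevObj) < config@relTol * abs(obj)) break
    prevObj <- obj
  }
  list(params = classifierParams(w, beta = beta, alpha = alpha, pi1 = pi1),
       trace = new("FitTrace", table = do.call(rbind, tr[seq_len(it)])))
}

#' Draw initialization couples
#'
#' Each couple is a pair of classifiers with opposite initial weight
#' vectors `(w, -w)`, `w ~ N(0, I/D)` so initial projections are O(1);
#' beta and alpha start at 1. One member of a couple starts with labels
#' effectively flipped relative to the other, so the chance that one of
#' them converges to a correctly-signed classifier is high.
#'
#' @param D feature dimensionality
#' @param nCouples number of couples
#' @param seed integer seed (NULL leaves the RNG state alone)
#' @return list of length `nCouples`; each element a list of two
#'   [ClassifierParams-class] with `w` and `-w`
#' @export
initCouples <- function(D, nCouples, seed = NULL) {
  stopifnot(nCouples >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nCouples), function(i) {
    w <- stats::rnorm(D, sd = 1 / sqrt(D))
    list(classifierParams(w), classifierParams(-w))
  })
}

#' Select the best classifier from a pool by data log-likelihood
#'
#' Returns the (1-based) index of the classifier whose data log-likelihood
#' on the session is highest; ties break to the lowest index. The weight
#' prior is excluded by default so classifiers with different alpha are
#' compared on the data alone; `includePrior = TRUE` switches to the full
#' MAP objective.
#'
#' @param classifiers list of [ClassifierParams-class]
#' @param session a [SessionFeatures-class]
#' @param includePrior include the weight prior term (default FALSE)
#' @return integer index into `classifiers`
#' @export
selectBest <- function(classifiers, session, includePrior = FALSE) {
  if (!length(classifiers)) stop("empty classifier list")
  pool <- .poolInfo(session)
  ll <- vapply(classifiers, function(p) {
    v <- .dataTerm(pool, p@w, p@beta)
    if (includePrior) v <- v + logPriorW(p@w, p@alpha)
    v
  }, numeric(1))
  which.max(ll)  # which.max takes the lowest index on ties
}

#' Indicator posteriors for every block of a session
#'
#' @param session a [SessionFeatures-class]
#' @param params a [ClassifierParams-class]
#' @return numeric matrix B x J, rows in session block order
#' @export
eStepSession <- function(session, params) {
  .eStepPooled(.poolInfo(session), params@w, params@beta)
}
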