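#' @include paradigm.R
NULL

#' Construct classifier parameters
#'
#' @param w numeric weight vector (length D, bias coefficient last)
#' @param beta projection noise variance, > 0 (default 1: the natural scale
#'   for targets at +/-1)
#' @param alpha prior precision of w, > 0 (default 1)
#' @param pi1 prior target probability in (0,1); defaults to 1/6, one target
#'   among six flashes. Used only by the unconstrained variant and
#'   diagnostics -- the constrained model carries the paradigm prior itself.
#' @return a [ClassifierParams-class]
#' @export
classifierParams <- function(w, beta = 1, alpha = 1, pi1 = 1 / 6) {
  new("ClassifierParams", w = as.numeric(w), beta = beta, alpha = alpha,
      pi1 = pi1)
}

#' @describeIn weights weight vector of the classifier
#' @export
setMethod("weights", "ClassifierParams", function(x) x@w)

#' @describeIn noiseVariance noise variance beta
#' @export
setMethod("noiseVariance", "ClassifierParams", function(x) x@beta)

#' @describeIn priorPrecision prior precision alpha
#' @export
setMethod("priorPrecision", "ClassifierParams", function(x) x@alpha)

#' @describeIn featureDim length of the weight vector
#' @export
setMethod("featureDim", "ClassifierParams", function(x) length(x@w))

setMethod("show", "ClassifierParams", function(object) {
  cat(sprintf(
    "ClassifierParams: D=%d, |w|^2=%.4g, beta=%.4g, alpha=%.4g, pi1=%.4g\n",
    length(object@w), sum(object@w^2), object@beta, object@alpha, object@pi1))
})

#' Log-likelihood of a projection given its label
#'
#' The model treats the one-dimensional projection `w^T x` as Gaussian around
#' the label: `log N(w^T x; y, beta)`. (This is not a normalized density on
#' x itself; the functional form is what the EM updates and predictions use.)
#'
#' @param x feature vector, or a precomputed projection when `projection=TRUE`
#' @param w weight vector
#' @param label +1 or -1
#' @param beta noise variance > 0
#' @param projection if TRUE, `x` is already the scalar projection
#' @return log density (vectorized over projections)
#' @export
projectionLoglik <- function(x, w, label, beta, projection = FALSE) {
  if (beta <= 0) stop("beta must be positive")
  p <- if (projection) x else sum(w * x)
  -0.5 * log(2 * pi * beta) - (p - label)^2 / (2 * beta)
}

#' Log density of the isotropic Gaussian weight prior
#'
#' `log N(w; 0, alpha^{-1} I) = (D/2) log(alpha / 2 pi) - (alpha/2) w^T w`.
#'
#' @param w weight vector
#' @param alpha prior precision > 0
#' @return log density
#' @export
logPriorW <- function(w, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  D <- length(w)
  (D / 2) * log(alpha / (2 * pi)) - (alpha / 2) * sum(w^2)
}

#' MAP / ridge-regression weight estimate
#'
#' Solves `(X^T X + lam I) w = X^T y` by a linear solve (never an explicit
#' inverse). With the Gaussian prior this is the posterior mode; `lam`
#' equals `beta * alpha`.
#'
#' @param X design matrix N x D
#' @param y numeric response (labels or expected labels)
#' @param lam ridge constant >= 0
#' @param XtX optional precomputed `crossprod(X)` (reused across EM
#'   iterations and classifier pools)
#' @return weight vector of length D
#' @export
ridgeMap <- function(X, y, lam, XtX = NULL) {
  if (lam < 0) stop("lam must be >= 0")
  if (is.null(XtX)) XtX <- crossprod(X)
  D <- ncol(XtX)
  A <- XtX
  diag(A) <- diag(A) + lam
  out <- tryCatch(solve(A, crossprod(X, y)),
                  error = function(e) stop("ridge system is singular: ",
                                           conditionMessage(e)))
  drop(out)
}

#' Posterior probability of a target label for one intensification
#'
#' `p(y = +1 | x, w, beta, pi1)` -- a sigmoid in the projection, computed in
#' log-space. With `pi1 = 1/2` the point of equal probability sits at
#' projection 0; the prior shifts it toward the mean of the less likely
#' class.
#'
#' @param x feature vector, or projections when `projection=TRUE`
#' @param params a [ClassifierParams-class]
#' @param projection if TRUE, `x` holds precomputed projections
#' @return probability (vectorized over projections)
#' @export
labelPosterior <- function(x, params, projection = FALSE) {
  p <- if (projection) x else sum(params@w * x)
  lp <- log(params@pi1) +
    projectionLoglik(p, NULL, 1, params@beta, projection = TRUE)
  lm <- log(1 - params@pi1) +
    projectionLoglik(p, NULL, -1, params@beta, projection = TRUE)
  1 / (1 + exp(lm - lp))
}

# numerically stable log(sum(exp(v))) along rows of a matrix
.logsumexpRows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Serialize classifier parameters to JSON
#' @param params a [ClassifierParams-class]
#' @param path file path
#' @return `path`, invisibly
#' @export
writeClassifier <- function(params, path) {
  jsonlite::write_json(
    list(w = params@w, beta = params@beta, alpha = params@alpha,
         pi1 = params@pi1),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read classifier parameters from JSON
#' @param path file path
#' @return a [ClassifierParams-class]
#' @export
readClassifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  classifierParams(j$w, beta = j$beta, alpha = j$alpha, pi1 = j$pi1)
}
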