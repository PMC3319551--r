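#' @include synthetic.R
NULL

#' Area under the ROC curve (rank statistic)
#'
#' Mann--Whitney form: the probability that a random positive scores above
#' a random negative, with ties counting one half. 1 is perfect, 0.5 is
#' chance, below 0.5 the classifier has its labels swapped.
#'
#' @param scores numeric classifier outputs
#' @param labels +1/-1 (or logical/0-1) class labels; both classes required
#' @return AUC in `[0, 1]`
#' @export
aucScore <- function(scores, labels) {
  pos <- labels == 1 | labels == TRUE
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks: ties contribute 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spelling accuracy in percent
#'
#' @param predictions character vector of predicted characters
#' @param truth character vector of true characters, same length
#' @return `100 * #correct / #characters`
#' @export
spellingAccuracy <- function(predictions, truth) {
  if (!length(truth)) stop("truth must be non-empty")
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  100 * mean(predictions == truth)
}

#' Online performance curves from a prediction log
#'
#' From an ordered per-character prediction log (as produced by
#' [runOAUS()]), assembles the cumulative-correct curve, the retest curve
#' (characters among those already seen that the then-current classifier
#' spells correctly) and the upper bound, which is simply the number of
#' characters seen -- the identity line.
#'
#' @param predictionLog data.frame with columns `charIndex`, `correct` and
#'   optionally `retestCorrect`, ordered by `charIndex`
#' @return data.frame with columns `charsSeen`, `cumulativeCorrect`,
#'   `retestCorrect`, `bound`
#' @export
onlineTrace <- function(predictionLog) {
  if (is.unsorted(predictionLog$charIndex))
    stop("prediction log must be ordered by charIndex")
  n <- nrow(predictionLog)
  data.frame(
    charsSeen = seq_len(n),
    cumulativeCorrect = cumsum(as.logical(predictionLog$correct)),
    retestCorrect = if ("retestCorrect" %in% names(predictionLog))
      predictionLog$retestCorrect else rep(NA_integer_, n),
    bound = seq_len(n))
}

#' Cosine alignment between a fitted classifier and the true direction
#'
#' With a 1-in-J target rate the optimal classifier carries a genuine
#' negative bias coefficient (the regression intercept toward the majority
#' class), so recovery of the discriminative direction is measured on the
#' signal coordinates with the bias excluded (the default). `excludeBias =
#' FALSE` compares the full vectors.
#'
#' @param params a [ClassifierParams-class]
#' @param trueDirection length-D reference vector (e.g.
#'   `attr(session, "trueDirection")`)
#' @param excludeBias drop the last (bias) coordinate before comparing
#' @return `|cos|` in `[0, 1]`
#' @export
directionCosine <- function(params, trueDirection, excludeBias = TRUE) {
  w <- params@w
  stopifnot(length(w) == length(trueDirection))
  if (excludeBias) {
    w <- w[-length(w)]
    trueDirection <- trueDirection[-length(trueDirection)]
  }
  abs(sum(w * trueDirection)) /
    sqrt(sum(w^2) * sum(trueDirection^2))
}

#' Supervised ridge baseline on true labels
#'
#' Plain ridge regression on the true +/-1 intensification labels -- the
#' supervised oracle the unsupervised fits are compared against in tests.
#'
#' @param session a labeled [SessionFeatures-class]
#' @param lam ridge constant (default 1e-6, effectively unregularized)
#' @return a [ClassifierParams-class] with beta set to the training MSE
#' @export
supervisedRidge <- function(session, lam = 1e-6) {
  y <- trueLabels(session)
  w <- ridgeMap(session@X, y, lam)
  p <- drop(session@X %*% w)
  classifierParams(w, beta = max(mean((p - y)^2), 1e-8))
}
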