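#' @import methods
NULL

#' SpellerGrid: the character matrix of the row/column speller
#'
#' A square grid of distinct single characters. The subject focuses on one
#' cell; rows and columns are intensified in random order and the attended
#' row/column elicits the P300 response. The standard matrix is 6 by 6
#' (letters A-Z, digits 1-9 and an underscore, row-major).
#'
#' @slot symbols character matrix, J x J, all entries distinct single
#'   characters.
#' @seealso [defaultGrid()], [gridLookup()]
#' @export
setClass("SpellerGrid", representation(symbols = "matrix"))

setValidity("SpellerGrid", function(object) {
  s <- object@symbols
  if (!is.character(s)) return("symbols must be a character matrix")
  if (nrow(s) != ncol(s)) return("grid must be square")
  if (nrow(s) < 2) return("grid must be at least 2 x 2")
  if (any(nchar(s) != 1)) return("all grid entries must be single characters")
  if (anyDuplicated(c(s))) return("grid entries must be distinct")
  TRUE
})

#' PseudoSymbolBlock: one character's intensifications along one axis
#'
#' The row-axis (or column-axis) flashes of a single character form an
#' independent 6-way latent classification problem: exactly one of the J
#' flash positions is the target, and which one is shared across all
#' repetitions. Features are stored indexed by flash position, not by
#' presentation order.
#'
#' @slot charIndex integer, 0-based position of the character in the session.
#' @slot axis `"row"` or `"column"`.
#' @slot features numeric array R x J x D; `features[r, j, ]` is the feature
#'   vector of the intensification of row/column `j-1` in repetition `r-1`.
#'   The last feature is the bias and equals 1.
#' @export
setClass("PseudoSymbolBlock", representation(
  charIndex = "integer", axis = "character", features = "array"))

setValidity("PseudoSymbolBlock", function(object) {
  f <- object@features
  if (length(dim(f)) != 3) return("features must be an R x J x D array")
  if (dim(f)[1] < 1) return("at least one repetition required")
  if (dim(f)[3] < 2) return("D must be >= 2 (signal features plus bias)")
  if (!isTRUE(all(abs(f[, , dim(f)[3]] - 1) < 1e-12)))
    return("last feature of every vector must be the bias term 1")
  if (!object@axis %in% c("row", "column")) return("axis must be 'row' or 'column'")
  if (object@charIndex < 0L) return("charIndex must be >= 0")
  TRUE
})

#' SessionFeatures: a preprocessed speller session
#'
#' All per-intensification feature vectors of a spelling session, grouped in
#' pseudo-symbol blocks (one row-axis and one column-axis block per
#' character). Internally the features are pooled into a single design matrix
#' for efficient inference; [sessionBlocks()] reconstructs the per-block
#' arrays. The optional ground truth is carried for evaluation only -- no
#' training code path reads it.
#'
#' @slot X numeric matrix N x D, all intensification features pooled
#'   (rows ordered block by block, repetition-major within a block).
#' @slot blockId integer N, 1-based block membership of each row of `X`.
#' @slot flashIndex integer N, 0-based flash position of each row of `X`.
#' @slot blockInfo data.frame with one row per block: `charIndex` (0-based),
#'   `axis`, `R` (repetitions).
#' @slot grid a [SpellerGrid-class].
#' @slot truth character vector of true characters (length = number of
#'   characters) or `character(0)` when unlabeled.
#' @export
setClass("SessionFeatures", representation(
  X = "matrix", blockId = "integer", flashIndex = "integer",
  blockInfo = "data.frame", grid = "SpellerGrid", truth = "character"))

setValidity("SessionFeatures", function(object) {
  J <- nrow(object@grid@symbols)
  if (nrow(object@X) != length(object@blockId)) return("blockId length mismatch")
  if (nrow(object@X) != length(object@flashIndex)) return("flashIndex length mismatch")
  if (nrow(object@blockInfo) > 0) {
    n_expect <- sum(object@blockInfo$R) * J
    if (nrow(object@X) != n_expect)
      return("X rows inconsistent with blockInfo repetitions")
    cc <- object@blockInfo$charIndex
    for (ci in unique(cc)) {
      ax <- object@blockInfo$axis[cc == ci]
      if (!setequal(ax, c("row", "column")))
        return(sprintf("character %d must have one row and one column block", ci))
    }
    if (length(object@truth) &&
        length(object@truth) != length(unique(cc)))
      return("truth length must equal the number of characters")
  }
  TRUE
})

#' ClassifierParams: the Bayesian linear speller classifier
#'
#' The model is `w^T x ~ N(y, beta)` with labels `y = +/-1`, a zero-mean
#' isotropic Gaussian prior `w ~ N(0, alpha^{-1} I)`, and a target prior
#' `pi1` (used only by the unconstrained variant -- the paradigm-constrained
#' model replaces it by the uniform indicator prior `1/J`).
#'
#' @slot w numeric weight vector of length D (last entry multiplies the bias).
#' @slot beta numeric, noise variance of the one-dimensional projection, > 0.
#' @slot alpha numeric, prior precision of `w`, > 0.
#' @slot pi1 numeric in (0,1), prior probability of a target intensification.
#' @seealso [initCouples()], [emFit()]
#' @export
setClass("ClassifierParams", representation(
  w = "numeric", beta = "numeric", alpha = "numeric", pi1 = "numeric"))

setValidity("ClassifierParams", function(object) {
  if (length(object@beta) != 1 || object@beta <= 0) return("beta must be a positive scalar")
  if (length(object@alpha) != 1 || object@alpha <= 0) return("alpha must be a positive scalar")
  if (length(object@pi1) != 1 || object@pi1 <= 0 || object@pi1 >= 1)
    return("pi1 must lie in (0,1)")
  if (!length(object@w)) return("w must be non-empty")
  TRUE
})

#' FitTrace: per-iteration EM diagnostics
#'
#' Records, for each EM iteration, the MAP objective, the noise variance
#' beta, the prior precision alpha and the squared weight norm, plus a
#' degeneracy flag (the global optimum at `w = 0`, `alpha -> Inf` is a known
#' pathology of the model and must be detectable).
#'
#' @slot table data.frame with columns `iteration`, `objective`, `beta`,
#'   `alpha`, `wnorm2`, `degenerate`.
#' @export
setClass("FitTrace", representation(table = "data.frame"))

setValidity("FitTrace", function(object) {
  need <- c("iteration", "objective", "beta", "alpha", "wnorm2", "degenerate")
  if (!all(need %in% names(object@table)))
    return(paste("trace table must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' CharacterPrediction: spelled character with its posterior evidence
#'
#' @slot charIndex integer, 0-based character position.
#' @slot rowPosterior numeric J-vector, posterior over the target row.
#' @slot colPosterior numeric J-vector, posterior over the target column.
#' @slot predictedChar single character, the grid cell at the argmax
#'   row/column (lowest index on ties).
#' @slot joint numeric J x J matrix, outer product of the two posteriors.
#' @export
setClass("CharacterPrediction", representation(
  charIndex = "integer", rowPosterior = "numeric", colPosterior = "numeric",
  predictedChar = "character", joint = "matrix"))

setValidity("CharacterPrediction", function(object) {
  if (abs(sum(object@rowPosterior) - 1) > 1e-9) return("rowPosterior must sum to 1")
  if (abs(sum(object@colPosterior) - 1) > 1e-9) return("colPosterior must sum to 1")
  if (any(object@rowPosterior < 0) || any(object@colPosterior < 0))
    return("posteriors must be non-negative")
  TRUE
})

#' EMConfig: settings of the EM fitting loop
#'
#' @slot maxIter integer, maximum number of EM iterations.
#' @slot relTol numeric, relative change of the MAP objective below which the
#'   loop stops.
#' @slot nEmAdaptive integer, EM iterations per incoming character in the
#'   online-adaptive protocols.
#' @slot updateAlpha logical, whether the prior precision is re-estimated.
#' @slot alphaCap numeric, upper bound on alpha (`Inf` disables capping;
#'   a finite bound is the documented guard for the online cold start).
#' @slot betaFloor numeric, lower bound on beta preventing log-density
#'   overflow at the degenerate optimum.
#' @slot seed integer seed for initial weight draws.
#' @seealso [emConfig()]
#' @export
setClass("EMConfig", representation(
  maxIter = "integer", relTol = "numeric", nEmAdaptive = "integer",
  updateAlpha = "logical", alphaCap = "numeric", betaFloor = "numeric",
  seed = "integer"))

setValidity("EMConfig", function(object) {
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (object@relTol < 0) return("relTol must be >= 0 (0 disables the check)")
  if (object@nEmAdaptive < 1L) return("nEmAdaptive must be >= 1")
  if (object@alphaCap <= 0) return("alphaCap must be positive (Inf to disable)")
  if (object@betaFloor <= 0) return("betaFloor must be positive")
  TRUE
})

#' PreprocessConfig: settings of the five-step EEG preprocessing chain
#'
#' Defaults follow the standard speller pipeline: 0.5--15 Hz band-pass,
#' decimation by 6, 10 retained samples per intensification centered on the
#' expected P300 latency of 300 ms, plus a bias feature.
#'
#' @slot bandLowHz,bandHighHz numeric band edges in Hz.
#' @slot decimationFactor integer subsampling factor.
#' @slot samplesPerIntensification integer retained samples per flash.
#' @slot p300CenterMs numeric, expected P300 latency in ms after flash onset.
#' @slot filterOrder integer Butterworth order (applied forward-backward).
#' @seealso [preprocessConfig()]
#' @export
setClass("PreprocessConfig", representation(
  bandLowHz = "numeric", bandHighHz = "numeric", decimationFactor = "integer",
  samplesPerIntensification = "integer", p300CenterMs = "numeric",
  filterOrder = "integer"))

setValidity("PreprocessConfig", function(object) {
  if (object@bandLowHz <= 0) return("bandLowHz must be > 0")
  if (object@bandHighHz <= object@bandLowHz) return("bandHighHz must exceed bandLowHz")
  if (object@decimationFactor < 1L) return("decimationFactor must be >= 1")
  if (object@samplesPerIntensification < 1L)
    return("samplesPerIntensification must be >= 1")
  if (object@filterOrder < 1L) return("filterOrder must be >= 1")
  TRUE
})

#' RawSignalBlock: multichannel EEG with flash events
#'
#' @slot signals numeric matrix C x T (channels by samples, microvolt-scale
#'   arbitrary units).
#' @slot fs numeric sampling rate in Hz.
#' @slot events data.frame of flash events with columns `char_index`,
#'   `repetition`, `axis`, `flash_index` (all 0-based except axis) and
#'   `onset_sample` (0-based sample index).
#' @export
setClass("RawSignalBlock", representation(
  signals = "matrix", fs = "numeric", events = "data.frame"))

setValidity("RawSignalBlock", function(object) {
  if (nrow(object@signals) < 1) return("at least one channel required")
  if (object@fs <= 0) return("fs must be positive")
  need <- c("char_index", "repetition", "axis", "flash_index", "onset_sample")
  if (!all(need %in% names(object@events)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (nrow(object@events)) {
    if (any(object@events$onset_sample < 0) ||
        any(object@events$onset_sample >= ncol(object@signals)))
      return("event onsets must lie inside the signal")
    if (!all(object@events$axis %in% c("row", "column")))
      return("event axis must be 'row' or 'column'")
  }
  TRUE
})
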