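#' @include AllGenerics.R
NULL

#' Construct a speller grid
#'
#' @param symbols a J x J character matrix of distinct single characters, or
#'   a character vector of J strings of length J (one per row), or a single
#'   string of length J*J filled row-major.
#' @return a [SpellerGrid-class]
#' @examples
#' defaultGrid()
#' gridLookup(defaultGrid(), 2, 4)  # "Q"
#' @export
SpellerGrid <- function(symbols) {
  if (is.character(symbols) && !is.matrix(symbols)) {
    if (length(symbols) == 1L) {
      ch <- strsplit(symbols, "")[[1]]
      J <- as.integer(round(sqrt(length(ch))))
      if (J * J != length(ch))
        stop("grid string length must be a perfect square")
      symbols <- matrix(ch, J, J, byrow = TRUE)
    } else {
      symbols <- do.call(rbind, lapply(symbols, function(s) strsplit(s, "")[[1]]))
    }
  }
  new("SpellerGrid", symbols = symbols)
}

#' The standard 6 x 6 Farwell--Donchin speller matrix
#'
#' Letters A-Z, digits 1-9 and an underscore, filled row-major.
#' @return a [SpellerGrid-class]
#' @export
defaultGrid <- function() {
  SpellerGrid("ABCDEFGHIJKLMNOPQRSTUVWXYZ123456789_")
}

#' @describeIn gridSize number of rows (= columns) of the grid
#' @export
setMethod("gridSize", "SpellerGrid", function(x) nrow(x@symbols))

setMethod("show", "SpellerGrid", function(object) {
  cat(sprintf("SpellerGrid %d x %d\n", gridSize(object), gridSize(object)))
  for (r in seq_len(nrow(object@symbols)))
    cat(" ", paste(object@symbols[r, ], collapse = " "), "\n")
})

#' Look up the character at a grid coordinate
#'
#' @param grid a [SpellerGrid-class]
#' @param row,col 0-based row and column indices in `0..J-1`
#' @return single character at `(row, col)`
#' @export
gridLookup <- function(grid, row, col) {
  J <- gridSize(grid)
  if (length(row) != 1L || length(col) != 1L || is.na(row) || is.na(col) ||
      row < 0 || row >= J || col < 0 || col >= J)
    stop(sprintf("row and col must lie in 0..%d", J - 1L))
  grid@symbols[row + 1L, col + 1L]
}

#' Target/non-target labels of the paradigm
#'
#' The latent indicator of a pseudo-symbol names which of the J flash
#' positions is the target; the intensification at that position carries
#' label +1, all others -1.
#'
#' @param indicator 0-based target position, in `0..J-1`
#' @param flashIndex 0-based flash position(s), in `0..J-1`; may be a vector
#' @param J grid size (default 6)
#' @return integer label(s) in `{+1, -1}`
#' @examples
#' labelAssignment(2, 2)  # +1
#' labelAssignment(2, 5)  # -1
#' @export
labelAssignment <- function(indicator, flashIndex, J = 6L) {
  if (length(indicator) != 1L || is.na(indicator) ||
      indicator < 0 || indicator >= J)
    stop(sprintf("indicator must lie in 0..%d", J - 1L))
  if (any(is.na(flashIndex)) || any(flashIndex < 0) || any(flashIndex >= J))
    stop(sprintf("flashIndex must lie in 0..%d", J - 1L))
  ifelse(flashIndex == indicator, 1L, -1L)
}

#' Label matrix of a block under one indicator assignment
#'
#' The indicator is shared across repetitions, so every repetition receives
#' the same row of labels: one +1 at the indicator position, -1 elsewhere.
#'
#' @param indicator 0-based target position
#' @param block a [PseudoSymbolBlock-class]
#' @return integer matrix R x J of labels
#' @export
labelsForAssignment <- function(indicator, block) {
  stopifnot(is(block, "PseudoSymbolBlock"))
  R <- dim(block@features)[1]
  J <- dim(block@features)[2]
  matrix(rep(labelAssignment(indicator, 0:(J - 1L), J = J), each = R), R, J)
}

#' Construct a pseudo-symbol block
#'
#' @param charIndex 0-based character position in the session
#' @param axis `"row"` or `"column"`
#' @param features numeric array R x J x D, indexed by flash position; the
#'   last feature of every vector must be the bias 1
#' @return a [PseudoSymbolBlock-class]
#' @export
PseudoSymbolBlock <- function(charIndex, axis, features) {
  new("PseudoSymbolBlock", charIndex = as.integer(charIndex),
      axis = axis, features = features)
}

#' @describeIn featureDim feature dimensionality of a block
#' @export
setMethod("featureDim", "PseudoSymbolBlock", function(x) dim(x@features)[3])

setMethod("show", "PseudoSymbolBlock", function(object) {
  d <- dim(object@features)
  cat(sprintf("PseudoSymbolBlock char %d, %s axis: R=%d, J=%d, D=%d\n",
              object@charIndex, object@axis, d[1], d[2], d[3]))
})

#' Assemble a session from pseudo-symbol blocks
#'
#' Blocks must come in (row, column) pairs per character and share the same
#' feature dimensionality. Features are pooled internally into one design
#' matrix; [sessionBlocks()] gives them back per block.
#'
#' @param blocks list of [PseudoSymbolBlock-class], two per character
#' @param grid a [SpellerGrid-class] (default [defaultGrid()])
#' @param truth optional character vector of true characters, one per
#'   character, for evaluation only
#' @return a [SessionFeatures-class]
#' @export
SessionFeatures <- function(blocks, grid = defaultGrid(), truth = NULL) {
  stopifnot(length(blocks) >= 1L)
  D <- featureDim(blocks[[1]])
  J <- gridSize(grid)
  for (b in blocks) {
    if (featureDim(b) != D) stop("all blocks must share the feature dimension D")
    if (dim(b@features)[2] != J) stop("block flash dimension must match the grid size")
  }
  Xs <- vector("list", length(blocks))
  info <- data.frame(
    charIndex = vapply(blocks, function(b) b@charIndex, integer(1)),
    axis = vapply(blocks, function(b) b@axis, character(1)),
    R = vapply(blocks, function(b) dim(b@features)[1], integer(1)))
  blockId <- integer(0); flashIndex <- integer(0)
  for (i in seq_along(blocks)) {
    f <- blocks[[i]]@features
    R <- dim(f)[1]
    # rows: repetition-major, flash fast
    Xs[[i]] <- matrix(aperm(f, c(2, 1, 3)), R * J, D)
    blockId <- c(blockId, rep.int(i, R * J))
    flashIndex <- c(flashIndex, rep.int(0:(J - 1L), R))
  }
  new("SessionFeatures", X = do.call(rbind, Xs), blockId = blockId,
      flashIndex = as.integer(flashIndex), blockInfo = info, grid = grid,
      truth = if (is.null(truth)) character(0) else as.character(truth))
}

#' @describeIn featureDim feature dimensionality of a session
#' @export
setMethod("featureDim", "SessionFeatures", function(x) ncol(x@X))

#' @describeIn nCharacters characters in the session
#' @export
setMethod("nCharacters", "SessionFeatures",
          function(x) length(unique(x@blockInfo$charIndex)))

#' @describeIn gridSize grid size of a session
#' @export
setMethod("gridSize", "SessionFeatures", function(x) gridSize(x@grid))

#' @describeIn sessionTruth truth of a session, NULL when unlabeled
#' @export
setMethod("sessionTruth", "SessionFeatures",
          function(x) if (length(x@truth)) x@truth else NULL)

#' @describeIn sessionGrid grid of a session
#' @export
setMethod("sessionGrid", "SessionFeatures", function(x) x@grid)

#' @describeIn sessionBlocks reconstruct the per-block feature arrays
#' @export
setMethod("sessionBlocks", "SessionFeatures", function(x) {
  J <- gridSize(x)
  D <- featureDim(x)
  lapply(seq_len(nrow(x@blockInfo)), function(i) {
    rows <- x@blockId == i
    R <- x@blockInfo$R[i]
    f <- aperm(array(x@X[rows, , drop = FALSE], c(J, R, D)), c(2, 1, 3))
    PseudoSymbolBlock(x@blockInfo$charIndex[i], x@blockInfo$axis[i], f)
  })
})

setMethod("show", "SessionFeatures", function(object) {
  cat(sprintf(
    "SessionFeatures: %d characters, %d blocks, D=%d, %s\n",
    nCharacters(object), nrow(object@blockInfo), featureDim(object),
    if (length(object@truth)) "labeled (truth attached)" else "unlabeled"))
})

#' Concatenate two sessions
#'
#' Character indices of the second session are shifted past the first.
#' Both sessions must share grid size and feature dimension. Truth is kept
#' only when both sessions carry it.
#'
#' @param a,b [SessionFeatures-class] objects
#' @return a [SessionFeatures-class]
#' @export
concatSessions <- function(a, b) {
  if (nCharacters(b) == 0) return(a)
  stopifnot(featureDim(a) == featureDim(b), gridSize(a) == gridSize(b))
  shift <- max(a@blockInfo$charIndex) + 1L
  infoB <- b@blockInfo
  infoB$charIndex <- infoB$charIndex + shift
  truth <- if (length(a@truth) && length(b@truth)) c(a@truth, b@truth)
           else character(0)
  new("SessionFeatures",
      X = rbind(a@X, b@X),
      blockId = c(a@blockId, b@blockId + nrow(a@blockInfo)),
      flashIndex = c(a@flashIndex, b@flashIndex),
      blockInfo = rbind(a@blockInfo, infoB),
      grid = a@grid, truth = truth)
}

#' Keep only the first R repetitions of every character
#'
#' Reduced-repetition analyses use the first R repetitions of each block
#' (the presentation-earliest data an online system would have).
#'
#' @param session a [SessionFeatures-class]
#' @param R repetitions to keep
#' @return a [SessionFeatures-class]
#' @export
truncateRepetitions <- function(session, R) {
  stopifnot(R >= 1L)
  blocks <- lapply(sessionBlocks(session), function(b) {
    Rb <- min(R, dim(b@features)[1])
    PseudoSymbolBlock(b@charIndex, b@axis,
                      b@features[seq_len(Rb), , , drop = FALSE])
  })
  SessionFeatures(blocks, grid = session@grid,
                  truth = sessionTruth(session))
}

#' Select a contiguous range of characters from a session
#'
#' @param session a [SessionFeatures-class]
#' @param charIndices 0-based character indices to keep (re-indexed from 0)
#' @return a [SessionFeatures-class]
#' @export
subsetCharacters <- function(session, charIndices) {
  blocks <- sessionBlocks(session)
  keep <- vapply(blocks, function(b) b@charIndex %in% charIndices, logical(1))
  sel <- blocks[keep]
  remap <- stats::setNames(seq_along(sort(unique(charIndices))) - 1L,
                           sort(unique(charIndices)))
  sel <- lapply(sel, function(b)
    PseudoSymbolBlock(remap[[as.character(b@charIndex)]], b@axis, b@features))
  truth <- sessionTruth(session)
  if (!is.null(truth)) truth <- truth[sort(unique(charIndices)) + 1L]
  SessionFeatures(sel, grid = session@grid, truth = truth)
}

#' Split a session into train and test parts
#'
#' Order-preserving, disjoint split after `nTrainChars` characters. An empty
#' train split is allowed (yields a 0-character session placeholder `NULL`).
#'
#' @param session a [SessionFeatures-class]
#' @param nTrainChars number of leading characters in the train part
#' @return list with elements `train` (possibly NULL) and `test`
#' @export
sessionSplit <- function(session, nTrainChars) {
  K <- nCharacters(session)
  if (nTrainChars < 0 || nTrainChars > K)
    stop("nTrainChars must lie in 0..K")
  idx <- sort(unique(session@blockInfo$charIndex))
  train <- if (nTrainChars > 0)
    subsetCharacters(session, idx[seq_len(nTrainChars)]) else NULL
  test <- if (nTrainChars < K)
    subsetCharacters(session, idx[(nTrainChars + 1L):K]) else NULL
  list(train = train, test = test)
}
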