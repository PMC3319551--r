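# Independent brute-force oracles and small fixture builders.
# The oracles enumerate the discrete latent space directly and never touch
# the package's pooled E/M-step implementations.

# posterior over the J indicator values by direct enumeration
bruteForcePosterior <- function(block, w, beta) {
  f <- block@features
  R <- dim(f)[1]; J <- dim(f)[2]; D <- dim(f)[3]
  ll <- vapply(0:(J - 1L), function(cand) {
    lab <- labelsForAssignment(cand, block)
    s <- 0
    for (r in seq_len(R)) for (j in seq_len(J))
      s <- s + projectionLoglik(f[r, j, ], w, lab[r, j], beta)
    s
  }, numeric(1))
  p <- exp(ll - max(ll))
  p / sum(p)
}

# pooled labels of a single-character session under one (row, col) assignment
.jointLabels <- function(session, cr, cc) {
  lab <- integer(nrow(session@X))
  for (i in seq_len(nrow(session@blockInfo))) {
    target <- if (session@blockInfo$axis[i] == "row") cr else cc
    rows <- session@blockId == i
    lab[rows] <- ifelse(session@flashIndex[rows] == target, 1L, -1L)
  }
  lab
}

# posterior-weighted sum of per-assignment ridge solutions (K = 1 session)
bruteForceJointRidge <- function(session, postRow, postCol, beta, alpha) {
  w <- numeric(ncol(session@X))
  for (cr in 0:5) for (cc in 0:5) {
    y <- .jointLabels(session, cr, cc)
    w <- w + postRow[cr + 1] * postCol[cc + 1] *
      ridgeMap(session@X, y, beta * alpha)
  }
  w
}

# posterior-weighted mean squared error (K = 1 session)
bruteForceJointBeta <- function(session, postRow, postCol, w) {
  p <- drop(session@X %*% w)
  v <- 0
  for (cr in 0:5) for (cc in 0:5) {
    y <- .jointLabels(session, cr, cc)
    v <- v + postRow[cr + 1] * postCol[cc + 1] * mean((p - y)^2)
  }
  v
}

# all-pairs AUC, ties count one half
bruteForceAUC <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels != 1]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# a small random pseudo-symbol block (features standard normal + bias)
randomBlock <- function(R, D, charIndex = 0L, axis = "row", seed = 1) {
  set.seed(seed)
  f <- array(rnorm(R * 6 * D), c(R, 6, D))
  f[, , D] <- 1
  PseudoSymbolBlock(charIndex, axis, f)
}

# a one-character session with random features
randomOneCharSession <- function(R, D, seed = 1) {
  set.seed(seed)
  mk <- function(axis) {
    f <- array(rnorm(R * 6 * D), c(R, 6, D))
    f[, , D] <- 1
    PseudoSymbolBlock(0L, axis, f)
  }
  SessionFeatures(list(mk("row"), mk("column")))
}

# posterior matrix with one-hot rows at the true indicators
oneHotPosteriors <- function(session) {
  ind <- attr(session, "trueIndicators")
  info <- session@blockInfo
  post <- matrix(0, nrow(info), gridSize(session))
  for (i in seq_len(nrow(info))) {
    k <- info$charIndex[i] + 1L
    target <- if (info$axis[i] == "row") ind[k, 1] else ind[k, 2]
    post[i, target + 1L] <- 1
  }
  post
}

# posterior at the true indicator for every block
posteriorAtTruth <- function(session, post) {
  ind <- attr(session, "trueIndicators")
  info <- session@blockInfo
  vapply(seq_len(nrow(info)), function(i) {
    k <- info$charIndex[i] + 1L
    target <- if (info$axis[i] == "row") ind[k, 1] else ind[k, 2]
    post[i, target + 1L]
  }, numeric(1))
}
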