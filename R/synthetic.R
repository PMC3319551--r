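#' @include runtime.R
NULL

#' Feature-level generator configuration
#'
#' Emulates the model's own generative assumptions: a latent direction along
#' which target projections are N(+mu, 1) and non-target projections
#' N(-mu, 1), with independent standard-normal structure orthogonal to the
#' direction and a bias feature appended. At mu = 1 the intensification AUC
#' of the true direction is Phi(sqrt(2)) ~ 0.92, a realistic single-trial
#' separability for a responsive subject.
#'
#' @param K characters (default 30)
#' @param R repetitions per character (default 10)
#' @param D feature dimensionality including the bias (default 50)
#' @param mu class separation of the latent projection in projection units
#'   (default 1)
#' @param wDir optional unit direction of length D-1 (random when NULL)
#' @param seed integer seed
#' @return a list of class `featureGenConfig`
#' @export
featureGenConfig <- function(K = 30L, R = 10L, D = 50L, mu = 1,
                             wDir = NULL, seed = 1L) {
  stopifnot(mu >= 0, D >= 2, K >= 1, R >= 1)
  structure(list(K = as.integer(K), R = as.integer(R), D = as.integer(D),
                 mu = mu, wDir = wDir, seed = as.integer(seed)),
            class = "featureGenConfig")
}

#' Generate a feature-level synthetic speller session
#'
#' True characters are chosen uniformly from the grid. For every
#' intensification a feature vector is drawn such that its projection on the
#' latent direction is N(+mu, 1) for targets and N(-mu, 1) for non-targets;
#' coordinates orthogonal to the direction are standard normal, and the bias
#' 1 is appended. Exactly 1 in J intensifications is a target, by paradigm
#' structure. The ground truth travels in the session's `truth` slot (and in
#' the returned `trueDirection`), which no training code path reads.
#'
#' @param config a [featureGenConfig()]
#' @param grid a [SpellerGrid-class]
#' @return a [SessionFeatures-class] with attributes accessible via
#'   `attr(., "trueDirection")` (length-D vector: direction plus 0 bias
#'   coefficient) and `attr(., "trueIndicators")` (K x 2 matrix of true
#'   row/column indices)
#' @export
generateFeatureSession <- function(config = featureGenConfig(),
                                   grid = defaultGrid()) {
  set.seed(config$seed)
  J <- gridSize(grid)
  K <- config$K; R <- config$R; D <- config$D; mu <- config$mu
  d <- D - 1L
  wDir <- config$wDir
  if (is.null(wDir)) {
    wDir <- stats::rnorm(d)
    wDir <- wDir / sqrt(sum(wDir^2))
  }
  stopifnot(length(wDir) == d)
  rows <- sample.int(J, K, replace = TRUE) - 1L
  cols <- sample.int(J, K, replace = TRUE) - 1L
  truth <- vapply(seq_len(K), function(k) gridLookup(grid, rows[k], cols[k]),
                  character(1))
  blocks <- vector("list", 2L * K)
  for (k in seq_len(K)) {
    for (a in 1:2) {
      axis <- c("row", "column")[a]
      ind <- if (a == 1) rows[k] else cols[k]
      n <- R * J
      G <- matrix(stats::rnorm(n * d), n, d)
      targ <- rep(rep(0:(J - 1L), each = 1L), R) == ind  # flash j in each rep
      t <- stats::rnorm(n, mean = ifelse(targ, mu, -mu))
      Xs <- G + outer(t - drop(G %*% wDir), wDir)
      # fold rows (rep-major, flash fast) back into R x J x D-1, add bias
      f <- array(NA_real_, c(R, J, D))
      f[, , seq_len(d)] <- aperm(array(t(Xs), c(d, J, R)), c(3, 2, 1))
      f[, , D] <- 1
      blocks[[2L * (k - 1L) + a]] <- PseudoSymbolBlock(k - 1L, axis, f)
    }
  }
  sess <- SessionFeatures(blocks, grid = grid, truth = truth)
  attr(sess, "trueDirection") <- c(wDir, 0)
  attr(sess, "trueIndicators") <- cbind(row = rows, col = cols)
  sess
}

#' True intensification labels of a generated session
#'
#' +1 for target flashes, -1 otherwise, aligned with the rows of the pooled
#' design matrix. Evaluation-only helper for AUC oracles and the supervised
#' ridge baseline.
#'
#' @param session a session from [generateFeatureSession()] (needs the
#'   `trueIndicators` attribute) or any labeled session with a default grid
#' @return integer vector of +/-1, length = total intensifications
#' @export
trueLabels <- function(session) {
  ind <- attr(session, "trueIndicators")
  if (is.null(ind)) {
    truth <- sessionTruth(session)
    if (is.null(truth)) stop("session carries no ground truth")
    sym <- session@grid@symbols
    pos <- t(vapply(truth, function(ch) {
      w <- which(sym == ch, arr.ind = TRUE)[1, ]
      c(w[1], w[2]) - 1L
    }, integer(2)))
    ind <- pos
  }
  info <- session@blockInfo
  lab <- integer(nrow(session@X))
  for (i in seq_len(nrow(info))) {
    k <- info$charIndex[i] - min(info$charIndex) + 1L
    target <- if (info$axis[i] == "row") ind[k, 1] else ind[k, 2]
    lab[session@blockId == i] <-
      ifelse(session@flashIndex[session@blockId == i] == target, 1L, -1L)
  }
  lab
}

#' Raw-signal generator configuration
#'
#' Paradigm timing defaults follow the classic matrix-speller protocol:
#' 100 ms intensifications with 75 ms inter-stimulus interval (one epoch of
#' 12 flashes = 2.1 s); the alternative 62.5/125 ms timing gives 2.25 s.
#' The background is 1/f-shaped Gaussian noise so the band-pass has real
#' work to do; every target flash adds a Gaussian deflection peaking 300 ms
#' after onset on the target channels.
#'
#' @param C channels (default 8)
#' @param fs sampling rate in Hz (default 240)
#' @param stimulusMs intensification duration (default 100)
#' @param isiMs inter-stimulus interval (default 75)
#' @param preMatrixMs pause before each character's flashing (default 2500)
#' @param p300Amplitude deflection amplitude in background-sd units
#'   (default 1)
#' @param p300LatencyMs deflection peak latency (default 300)
#' @param p300WidthMs Gaussian width (sd) of the deflection (default 60)
#' @param oneOverFExponent spectral exponent of the background (default 1)
#' @param backgroundScale background standard deviation (default 1)
#' @param targetChannels channel subset carrying the deflection
#'   (default first half)
#' @param K characters (default 4)
#' @param R repetitions (default 5)
#' @param seed integer seed
#' @return a list of class `rawGenConfig`
#' @export
rawGenConfig <- function(C = 8L, fs = 240, stimulusMs = 100, isiMs = 75,
                         preMatrixMs = 2500, p300Amplitude = 1,
                         p300LatencyMs = 300, p300WidthMs = 60,
                         oneOverFExponent = 1, backgroundScale = 1,
                         targetChannels = NULL, K = 4L, R = 5L, seed = 1L) {
  stopifnot(fs > 30, C >= 1)
  if (is.null(targetChannels)) targetChannels <- seq_len(max(1L, C %/% 2L))
  structure(list(C = as.integer(C), fs = fs, stimulusMs = stimulusMs,
                 isiMs = isiMs, preMatrixMs = preMatrixMs,
                 p300Amplitude = p300Amplitude,
                 p300LatencyMs = p300LatencyMs, p300WidthMs = p300WidthMs,
                 oneOverFExponent = oneOverFExponent,
                 backgroundScale = backgroundScale,
                 targetChannels = as.integer(targetChannels),
                 K = as.integer(K), R = as.integer(R),
                 seed = as.integer(seed)),
            class = "rawGenConfig")
}

#' Duration of one epoch (12 flashes) in seconds
#'
#' @param config a [rawGenConfig()]
#' @param J grid size (default 6; an epoch is 2J flashes)
#' @return seconds of flashing per repetition
#' @export
epochDuration <- function(config, J = 6L) {
  2 * J * (config$stimulusMs + config$isiMs) / 1000
}

# 1/f-shaped Gaussian noise, unit sd
.pinkNoise <- function(n, exponent, fs) {
  wn <- stats::rnorm(n)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]  # fold to physical frequencies
  shape <- 1 / pmax(f, 0.1)^(exponent / 2)
  x <- Re(stats::fft(stats::fft(wn) * shape, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Generate a raw-signal synthetic speller session
#'
#' Builds a continuous multichannel recording: per character, a pre-matrix
#' pause followed by R repetitions of 12 flashes (6 rows + 6 columns in
#' fresh random order each repetition). Target flashes add a Gaussian
#' deflection at the configured latency on the target channels; overlapping
#' deflections sum. Returns the block plus the hidden truth.
#'
#' @param config a [rawGenConfig()]
#' @param grid a [SpellerGrid-class]
#' @return list with `block` (a [RawSignalBlock-class]) and `truth`
#'   (character vector of the true characters)
#' @export
generateRawSession <- function(config = rawGenConfig(),
                               grid = defaultGrid()) {
  set.seed(config$seed)
  J <- gridSize(grid)
  fs <- config$fs
  soa <- (config$stimulusMs + config$isiMs) / 1000 * fs   # stimulus onset asynchrony
  pre <- round(config$preMatrixMs / 1000 * fs)
  post <- round(0.8 * fs)
  perChar <- pre + ceiling(2 * J * config$R * soa) + post
  Tn <- config$K * perChar
  sig <- matrix(0, config$C, Tn)
  for (ch in seq_len(config$C))
    sig[ch, ] <- config$backgroundScale *
      .pinkNoise(Tn, config$oneOverFExponent, fs)
  rows <- sample.int(J, config$K, replace = TRUE) - 1L
  cols <- sample.int(J, config$K, replace = TRUE) - 1L
  truth <- vapply(seq_len(config$K),
                  function(k) gridLookup(grid, rows[k], cols[k]),
                  character(1))
  lat <- round(config$p300LatencyMs / 1000 * fs)
  wid <- config$p300WidthMs / 1000 * fs
  half <- ceiling(3 * wid)
  bumpT <- (-half):half
  bump <- config$p300Amplitude * exp(-bumpT^2 / (2 * wid^2))
  ev <- vector("list", config$K)
  for (k in seq_len(config$K)) {
    base <- (k - 1L) * perChar + pre
    flashes <- data.frame()
    slot <- 0L
    for (r in seq_len(config$R) - 1L) {
      order12 <- sample.int(2L * J) - 1L  # 0..5 rows, 6..11 columns
      for (f in order12) {
        axis <- if (f < J) "row" else "column"
        fi <- f %% J
        onset <- as.integer(round(base + slot * soa))
        slot <- slot + 1L
        isTarget <- (axis == "row" && fi == rows[k]) ||
          (axis == "column" && fi == cols[k])
        if (isTarget) {
          idx <- onset + lat + bumpT
          keep <- idx >= 0L & idx < Tn
          sig[config$targetChannels, idx[keep] + 1L] <-
            sig[config$targetChannels, idx[keep] + 1L, drop = FALSE] +
            rep(bump[keep], each = length(config$targetChannels))
        }
        flashes <- rbind(flashes, data.frame(
          char_index = k - 1L, repetition = r, axis = axis,
          flash_index = fi, onset_sample = onset))
      }
    }
    ev[[k]] <- flashes
  }
  events <- do.call(rbind, ev)
  list(block = RawSignalBlock(sig, fs, events), truth = truth)
}
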