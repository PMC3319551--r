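#' @include paradigm.R
NULL

#' Construct a preprocessing configuration
#'
#' @param bandLowHz,bandHighHz band-pass edges in Hz (defaults 0.5 and 15)
#' @param decimationFactor subsampling factor (default 6)
#' @param samplesPerIntensification retained samples per flash (default 10)
#' @param p300CenterMs expected P300 latency after flash onset in ms
#'   (default 300)
#' @param filterOrder Butterworth order, applied forward-backward (default 4)
#' @return a [PreprocessConfig-class]
#' @export
preprocessConfig <- function(bandLowHz = 0.5, bandHighHz = 15,
                             decimationFactor = 6L,
                             samplesPerIntensification = 10L,
                             p300CenterMs = 300, filterOrder = 4L) {
  new("PreprocessConfig", bandLowHz = bandLowHz, bandHighHz = bandHighHz,
      decimationFactor = as.integer(decimationFactor),
      samplesPerIntensification = as.integer(samplesPerIntensification),
      p300CenterMs = p300CenterMs, filterOrder = as.integer(filterOrder))
}

#' Construct a raw signal block
#'
#' @param signals numeric matrix C x T (channels by samples)
#' @param fs sampling rate in Hz
#' @param events data.frame of flash events (`char_index`, `repetition`,
#'   `axis`, `flash_index`, `onset_sample`; indices 0-based)
#' @return a [RawSignalBlock-class]
#' @export
RawSignalBlock <- function(signals, fs, events) {
  new("RawSignalBlock", signals = signals, fs = fs,
      events = as.data.frame(events))
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across channels. The across-channel
#' mean of the output is exactly zero.
#'
#' @param signals numeric matrix C x T
#' @return numeric matrix C x T
#' @export
commonAverageReference <- function(signals) {
  if (!is.matrix(signals) || nrow(signals) < 1 || ncol(signals) < 1)
    stop("signals must be a non-empty C x T matrix")
  sweep(signals, 2L, colMeans(signals), "-")
}

#' Zero-phase Butterworth band-pass
#'
#' A Butterworth band-pass of the configured order applied forward-backward
#' (`signal::filtfilt`), so the phase response is zero and the P300 peak
#' latency is not shifted -- the centered extraction window relies on this.
#'
#' @param signals numeric matrix C x T
#' @param fs sampling rate in Hz
#' @param config a [PreprocessConfig-class]
#' @return filtered matrix C x T
#' @export
bandpassFilter <- function(signals, fs, config = preprocessConfig()) {
  nyq <- fs / 2
  if (config@bandHighHz >= nyq)
    stop("upper cutoff must lie below the Nyquist frequency")
  bf <- signal::butter(config@filterOrder,
                       c(config@bandLowHz, config@bandHighHz) / nyq,
                       type = "pass")
  t(apply(signals, 1L, function(ch) signal::filtfilt(bf, ch)))
}

#' Frequency response magnitude of the configured band-pass
#'
#' Gain of the forward-backward filter (squared magnitude of the one-pass
#' Butterworth response) at the requested frequencies; the oracle for
#' band-pass attenuation checks.
#'
#' @param freqHz frequencies in Hz
#' @param fs sampling rate in Hz
#' @param config a [PreprocessConfig-class]
#' @return numeric gains in `[0, 1]`
#' @export
bandpassGain <- function(freqHz, fs, config = preprocessConfig()) {
  bf <- signal::butter(config@filterOrder,
                       c(config@bandLowHz, config@bandHighHz) / (fs / 2),
                       type = "pass")
  zinv <- exp(-1i * 2 * pi * freqHz / fs)
  evalPoly <- function(coef, zi) {
    acc <- 0 + 0i
    for (k in seq_along(coef)) acc <- acc + coef[k] * zi^(k - 1)
    acc
  }
  h <- evalPoly(bf$b, zinv) / evalPoly(bf$a, zinv)
  Mod(h)^2  # filtfilt applies the filter twice
}

#' Normalize each channel to zero mean and unit variance
#'
#' @param signals numeric matrix C x T
#' @return normalized matrix C x T
#' @export
normalizeChannels <- function(signals) {
  mu <- rowMeans(signals)
  sdv <- apply(signals, 1L, stats::sd)
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad))
    stop("zero-variance channel(s): ", paste(bad, collapse = ", "))
  (signals - mu) / sdv
}

#' Extract decimated per-intensification features
#'
#' For every flash event, takes a raw window of
#' `samplesPerIntensification * decimationFactor` consecutive samples whose
#' center sample is the one nearest `onset + p300CenterMs`, keeps every
#' `decimationFactor`-th sample per channel, concatenates channels and
#' appends the bias 1. Feature length is
#' `C * samplesPerIntensification + 1`. Features are grouped into
#' pseudo-symbol blocks by (character, axis). The signals are used as given
#' (call [commonAverageReference()], [bandpassFilter()] and
#' [normalizeChannels()] first, or use [preprocessCharacter()]).
#'
#' @param block a [RawSignalBlock-class] (signals already filtered/normalized)
#' @param config a [PreprocessConfig-class]
#' @param grid a [SpellerGrid-class]
#' @param truth optional character vector for evaluation
#' @return a [SessionFeatures-class]
#' @export
extractFeatures <- function(block, config = preprocessConfig(),
                            grid = defaultGrid(), truth = NULL) {
  sig <- block@signals
  C <- nrow(sig); Tn <- ncol(sig)
  J <- gridSize(grid)
  S <- config@samplesPerIntensification
  L <- S * config@decimationFactor
  offs <- seq.int(0L, by = config@decimationFactor, length.out = S)
  ev <- block@events
  center <- as.integer(round(ev$onset_sample + config@p300CenterMs / 1000 * block@fs))
  start <- center - L %/% 2L
  bad <- which(start < 0L | start + L - 1L >= Tn)
  if (length(bad))
    stop("extraction window out of bounds for event(s) ",
         paste(bad, collapse = ", "),
         " (char ", paste(unique(ev$char_index[bad]), collapse = ","), ")")
  D <- C * S + 1L
  key <- interaction(ev$char_index, ev$axis, drop = TRUE)
  blocks <- list()
  for (k in levels(key)) {
    rows <- which(key == k)
    R <- length(unique(ev$repetition[rows]))
    reps <- sort(unique(ev$repetition[rows]))
    f <- array(NA_real_, c(R, J, D))
    for (i in rows) {
      r <- match(ev$repetition[i], reps)
      j <- ev$flash_index[i] + 1L
      win <- sig[, start[i] + 1L + offs, drop = FALSE]  # C x S
      f[r, j, ] <- c(t(win), 1)  # channel-major, bias last
    }
    if (anyNA(f))
      stop("incomplete flash set for block ", k,
           ": flash indices must cover 0..", J - 1L, " in every repetition")
    blocks[[length(blocks) + 1L]] <-
      PseudoSymbolBlock(ev$char_index[rows[1]], as.character(ev$axis[rows[1]]), f)
  }
  ord <- order(vapply(blocks, function(b) b@charIndex, integer(1)),
               match(vapply(blocks, function(b) b@axis, character(1)),
                     c("row", "column")))
  SessionFeatures(blocks[ord], grid = grid, truth = truth)
}

#' Preprocess one character's raw EEG
#'
#' The five-step chain applied character by character (online-capable):
#' common average reference, zero-phase band-pass, per-channel normalization
#' over this character's samples, decimated window extraction, bias term.
#'
#' @param block a [RawSignalBlock-class] holding exactly one character's
#'   samples and its `R * 2J` flash events
#' @param config a [PreprocessConfig-class]
#' @param grid a [SpellerGrid-class]
#' @return a [SessionFeatures-class] with the character's two blocks
#' @export
preprocessCharacter <- function(block, config = preprocessConfig(),
                                grid = defaultGrid()) {
  if (length(unique(block@events$char_index)) != 1L)
    stop("block must contain events of exactly one character")
  sig <- commonAverageReference(block@signals)
  sig <- bandpassFilter(sig, block@fs, config)
  sig <- normalizeChannels(sig)
  extractFeatures(RawSignalBlock(sig, block@fs, block@events),
                  config, grid)
}

#' Preprocess a multi-character raw session character by character
#'
#' Splits the events per character, applies [preprocessCharacter()] on each
#' character's own sample range (padded so extraction windows and filter
#' transients fall inside), and concatenates the resulting blocks.
#'
#' @param block a [RawSignalBlock-class] with events of K characters
#' @param config a [PreprocessConfig-class]
#' @param grid a [SpellerGrid-class]
#' @param truth optional character vector for evaluation
#' @param padMs margin in ms kept around each character's events (default 800)
#' @return a [SessionFeatures-class]
#' @export
preprocessSession <- function(block, config = preprocessConfig(),
                              grid = defaultGrid(), truth = NULL,
                              padMs = 800) {
  ev <- block@events
  pad <- as.integer(round(padMs / 1000 * block@fs))
  chars <- sort(unique(ev$char_index))
  blocks <- list()
  for (ci in chars) {
    sub <- ev[ev$char_index == ci, , drop = FALSE]
    lo <- max(0L, min(sub$onset_sample) - pad)
    hi <- min(ncol(block@signals) - 1L, max(sub$onset_sample) + pad)
    sub$onset_sample <- sub$onset_sample - lo
    sess <- preprocessCharacter(
      RawSignalBlock(block@signals[, (lo + 1L):(hi + 1L), drop = FALSE],
                     block@fs, sub), config, grid)
    blocks <- c(blocks, sessionBlocks(sess))
  }
  SessionFeatures(blocks, grid = grid, truth = truth)
}
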