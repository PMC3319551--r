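#' @include evaluation.R
NULL

#' Write a session bundle
#'
#' A bundle is a directory holding `metadata.json` (sampling rate, channel
#' count, grid rows, timing, seed provenance), `signals.csv` (C rows by T
#' columns, 9 significant digits), `events.csv` (one flash per row,
#' 0-based indices) and optionally `truth.csv`. Ground truth lives in its
#' own file so unsupervised code paths physically cannot read it by
#' accident.
#'
#' @param block a [RawSignalBlock-class]
#' @param path directory to create/fill
#' @param grid a [SpellerGrid-class]
#' @param truth optional character vector of true characters
#' @param meta optional named list merged into the metadata (e.g. seed)
#' @return `path`, invisibly
#' @export
writeBundle <- function(block, path, grid = defaultGrid(), truth = NULL,
                        meta = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  md <- c(list(
    fs = block@fs,
    channels = nrow(block@signals),
    samples = ncol(block@signals),
    grid = apply(grid@symbols, 1L, paste, collapse = ""),
    index_base = 0L), meta)
  jsonlite::write_json(md, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(data.table::as.data.table(signif(block@signals, 9)),
                     file.path(path, "signals.csv"), col.names = FALSE)
  data.table::fwrite(block@events, file.path(path, "events.csv"))
  if (!is.null(truth))
    data.table::fwrite(
      data.frame(char_index = seq_along(truth) - 1L, character = truth),
      file.path(path, "truth.csv"))
  invisible(path)
}

#' Read a session bundle
#'
#' @param path bundle directory (see [writeBundle()])
#' @return list with `block` (a [RawSignalBlock-class]), `grid`
#'   (a [SpellerGrid-class]), `truth` (character vector or NULL) and
#'   `meta` (the metadata list)
#' @export
readBundle <- function(path) {
  mdPath <- file.path(path, "metadata.json")
  evPath <- file.path(path, "events.csv")
  sigPath <- file.path(path, "signals.csv")
  for (p in c(mdPath, evPath, sigPath))
    if (!file.exists(p))
      stop("not a session bundle: missing ", basename(p), " in ", path)
  md <- jsonlite::read_json(mdPath, simplifyVector = TRUE)
  sig <- as.matrix(data.table::fread(sigPath, header = FALSE))
  dimnames(sig) <- NULL
  if (nrow(sig) != md$channels || ncol(sig) != md$samples)
    stop(sprintf("signals.csv is %d x %d but metadata declares %d x %d",
                 nrow(sig), ncol(sig), md$channels, md$samples))
  ev <- as.data.frame(data.table::fread(evPath))
  need <- c("char_index", "repetition", "axis", "flash_index", "onset_sample")
  if (!all(need %in% names(ev)))
    stop("events.csv must have columns ", paste(need, collapse = ", "))
  truth <- NULL
  if (file.exists(file.path(path, "truth.csv")))
    truth <- as.data.frame(
      data.table::fread(file.path(path, "truth.csv")))$character
  list(block = RawSignalBlock(sig, md$fs, ev),
       grid = SpellerGrid(md$grid), truth = truth, meta = md)
}
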