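#' @name tracks
#' @title Per-residue prediction tracks
#'
#' @description
#' A prediction track is one predictor's per-residue call string for one
#' local sequence feature, aligned position-for-position to the query.
#' Feature alphabets:
#' \describe{
#'   \item{SS3}{H (helix), E (strand), C (coil), plus '.' = no call, used by
#'     predictors that only ever vote for one state (e.g. a coil-only caller).}
#'   \item{DISORDER}{'*' disordered, '.' ordered.}
#'   \item{TM}{'H' transmembrane helix, '.' elsewhere.}
#'   \item{SIGNAL}{'S' signal peptide, '.' elsewhere.}
#'   \item{COIL}{'x' coiled coil, '.' elsewhere.}
#'   \item{LOWCOMPLEX}{'x' low-complexity, '.' elsewhere.}
#'   \item{CONSERVATION}{digits 0-9, least to most conserved.}
#' }
NULL

FEATURES <- c("SS3", "DISORDER", "TM", "SIGNAL", "COIL", "LOWCOMPLEX",
              "CONSERVATION")

FEATURE_ALPHABET <- list(
  SS3          = c("H", "E", "C", "."),
  DISORDER     = c("*", "."),
  TM           = c("H", "."),
  SIGNAL       = c("S", "."),
  COIL         = c("x", "."),
  LOWCOMPLEX   = c("x", "."),
  CONSERVATION = as.character(0:9)
)

# display letter marking a positive call in a binary feature track
POSITIVE_SYMBOL <- c(DISORDER = "*", TM = "H", SIGNAL = "S",
                     COIL = "x", LOWCOMPLEX = "x")

#' Construct a prediction track
#'
#' @param predictor Name of the predictor that produced the track.
#' @param feature One of \code{SS3}, \code{DISORDER}, \code{TM},
#'   \code{SIGNAL}, \code{COIL}, \code{LOWCOMPLEX}, \code{CONSERVATION}.
#' @param symbols One character per query residue, drawn from the feature's
#'   alphabet (see \link{tracks}).
#' @param query_length Optional; when given, \code{nchar(symbols)} must equal it.
#' @return A list of class \code{prediction_track}.
#' @export
prediction_track <- function(predictor, feature, symbols, query_length = NULL) {
  feature <- match.arg(feature, FEATURES)
  if (!is.character(predictor) || !nzchar(predictor))
    stop("predictor name must be a non-empty string")
  if (!is.null(query_length) && nchar(symbols) != query_length)
    stop("track from ", predictor, " has ", nchar(symbols),
         " symbols but the query has ", query_length, " residues")
  chars <- strsplit(symbols, "")[[1]]
  bad <- setdiff(unique(chars), FEATURE_ALPHABET[[feature]])
  if (length(bad))
    stop("track from ", predictor, " contains symbols outside the ",
         feature, " alphabet: ", paste(bad, collapse = " "))
  structure(list(predictor = predictor, feature = feature, symbols = symbols),
            class = "prediction_track")
}

#' Read predictor tracks from a tracks.tsv file
#'
#' The file is tab-separated with a header line and columns
#' \code{predictor}, \code{feature}, \code{symbols}.
#'
#' @param path Path to the tracks file.
#' @param query The \code{\link{query_sequence}} the tracks belong to.
#' @return A list of \code{\link{prediction_track}} objects.
#' @export
read_tracks <- function(path, query) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("predictor", "feature", "symbols")
  if (!all(need %in% names(df)))
    stop("tracks file must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    prediction_track(df$predictor[i], df$feature[i], df$symbols[i],
                     query_length = query$length)
  })
}

#' Write tracks to a tracks.tsv file
#'
#' @param tracks List of \code{\link{prediction_track}} objects.
#' @param path Output path.
#' @export
write_tracks <- function(tracks, path) {
  df <- data.frame(
    predictor = vapply(tracks, `[[`, "", "predictor"),
    feature   = vapply(tracks, `[[`, "", "feature"),
    symbols   = vapply(tracks, `[[`, "", "symbols"),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.prediction_track <- function(x, ...) {
  cat(sprintf("<%s track from %s: %d aa>\n", x$feature, x$predictor,
              nchar(x$symbols)))
  invisible(x)
}

track_chars <- function(track) strsplit(track$symbols, "")[[1]]
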