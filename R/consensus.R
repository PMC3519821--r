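#' Voting configuration for consensus tracks
#'
#' Vote weights and binary-call thresholds used when predictor tracks are
#' combined. By default every predictor has one vote, except PSIPRED for
#' secondary structure and Phobius for signal peptides, which carry two
#' votes each on account of their accuracy. Binary features call a residue
#' positive when the weighted votes reach the feature's threshold:
#' disorder needs at least 2 votes, signal peptides at least 3 (of the 5
#' nominal votes: SignalP-HMM, SignalP-NN, MEMSATSVM each 1, Phobius 2),
#' single-predictor features need 1, and transmembrane helices need a
#' strict majority of the votes actually supplied (threshold \code{NA}).
#'
#' @param weights Named numeric vector keyed \code{"predictor/feature"};
#'   predictors not listed weigh 1.
#' @param min_votes Named integer vector of per-feature thresholds; an
#'   \code{NA} entry means strict majority of contributing votes.
#' @return A list of class \code{vote_config}.
#' @export
vote_config <- function(weights = c("PSIPRED/SS3" = 2, "Phobius/SIGNAL" = 2),
                        min_votes = c(DISORDER = 2, SIGNAL = 3, TM = NA,
                                      COIL = 1, LOWCOMPLEX = 1)) {
  if (any(weights <= 0)) stop("vote weights must be positive")
  ok <- is.na(min_votes) | min_votes >= 1
  if (!all(ok)) stop("binary vote thresholds must be at least 1")
  structure(list(weights = weights, min_votes = min_votes),
            class = "vote_config")
}

vote_weight <- function(config, predictor, feature) {
  key <- paste(predictor, feature, sep = "/")
  if (key %in% names(config$weights)) unname(config$weights[key]) else 1
}

SS3_STATES <- c("H", "E", "C")

#' Consensus secondary-structure track by weighted voting
#'
#' At each residue, each SS3 track casts its weight for the state it calls
#' (tracks may call '.' = abstain, as a coil-only caller does outside its
#' coil segments). The state with the largest tally wins. On a tie the
#' state called by a double-weighted predictor is preferred if it is among
#' the tied maxima; failing that, coil (C) if tied, else the first tied
#' state in H, E, C order.
#'
#' @param tracks List of \code{\link{prediction_track}} objects with
#'   feature \code{SS3}.
#' @param config A \code{\link{vote_config}}.
#' @return A list of class \code{consensus_track} with fields
#'   \code{feature}, \code{symbols} and \code{tallies} (a states-by-residue
#'   matrix of vote counts).
#' @export
consensus_ss3 <- function(tracks, config = vote_config()) {
  tracks <- Filter(function(t) t$feature == "SS3", tracks)
  if (!length(tracks)) stop("no SS3 tracks to combine")
  L <- nchar(tracks[[1]]$symbols)
  mats <- lapply(tracks, track_chars)
  weights <- vapply(tracks, function(t) vote_weight(config, t$predictor, "SS3"),
                    0)
  heavy <- which(weights > 1)

  tallies <- matrix(0, nrow = 3, ncol = L, dimnames = list(SS3_STATES, NULL))
  for (k in seq_along(tracks)) {
    for (s in SS3_STATES) {
      hit <- mats[[k]] == s
      tallies[s, hit] <- tallies[s, hit] + weights[k]
    }
  }

  symbols <- character(L)
  for (i in seq_len(L)) {
    tal <- tallies[, i]
    tied <- SS3_STATES[tal == max(tal)]
    if (length(tied) == 1L) {
      symbols[i] <- tied
    } else {
      pick <- NA_character_
      for (k in heavy) {
        st <- mats[[k]][i]
        if (st %in% tied) { pick <- st; break }
      }
      if (is.na(pick)) pick <- if ("C" %in% tied) "C" else tied[1]
      symbols[i] <- pick
    }
  }
  new_consensus_track("SS3", paste(symbols, collapse = ""), tallies)
}

#' Consensus binary-feature track by thresholded weighted voting
#'
#' A residue is called positive when the weighted votes for the positive
#' state reach the feature's threshold (\code{\link{vote_config}}); an
#' \code{NA} threshold means a strict majority of the votes supplied by the
#' tracks present. Absent predictors simply contribute no votes.
#'
#' @param tracks List of tracks, all of one binary feature.
#' @param feature The binary feature being combined.
#' @param config A \code{\link{vote_config}}.
#' @return A \code{consensus_track}; positives carry the feature's display
#'   letter, negatives '.'.
#' @export
consensus_binary <- function(tracks, feature = tracks[[1]]$feature,
                             config = vote_config()) {
  feature <- match.arg(feature, names(POSITIVE_SYMBOL))
  tracks <- Filter(function(t) t$feature == feature, tracks)
  if (!length(tracks)) stop("no ", feature, " tracks to combine")
  L <- nchar(tracks[[1]]$symbols)
  pos_sym <- POSITIVE_SYMBOL[[feature]]
  weights <- vapply(tracks,
                    function(t) vote_weight(config, t$predictor, feature), 0)
  total <- sum(weights)
  threshold <- config$min_votes[[feature]]
  if (is.na(threshold)) threshold <- floor(total / 2) + 1

  votes <- numeric(L)
  for (k in seq_along(tracks)) {
    hit <- track_chars(tracks[[k]]) == pos_sym
    votes[hit] <- votes[hit] + weights[k]
  }
  positive <- votes >= threshold
  tallies <- rbind(positive = votes, negative = total - votes)
  symbols <- ifelse(positive, pos_sym, ".")
  new_consensus_track(feature, paste(symbols, collapse = ""), tallies)
}

new_consensus_track <- function(feature, symbols, tallies) {
  structure(list(feature = feature, symbols = symbols, tallies = tallies),
            class = "consensus_track")
}

#' @export
print.consensus_track <- function(x, ...) {
  cat(sprintf("<consensus %s track: %d aa>\n", x$feature, nchar(x$symbols)))
  invisible(x)
}

#' Resolve signal-peptide / transmembrane-helix conflicts
#'
#' A cleavable N-terminal signal peptide and a first transmembrane helix
#' are easy to confuse: both are hydrophobic stretches near the N-terminus.
#' When the consensus signal-peptide track has a positive run starting at
#' residue 1, any consensus TM run overlapping that run is taken to be the
#' signal peptide seen twice, and is cleared from the TM track. Without a
#' consensus signal peptide both tracks are returned unchanged.
#'
#' @param sp Consensus \code{SIGNAL} track.
#' @param tm Consensus \code{TM} track.
#' @return List with elements \code{signal} and \code{tm}.
#' @export
resolve_sp_tm <- function(sp, tm) {
  if (nchar(sp$symbols) != nchar(tm$symbols))
    stop("signal and TM tracks differ in length")
  sp_chars <- strsplit(sp$symbols, "")[[1]]
  if (sp_chars[1] != "S") return(list(signal = sp, tm = tm))
  sp_end <- match(TRUE, sp_chars != "S", nomatch = length(sp_chars) + 1L) - 1L

  tm_chars <- strsplit(tm$symbols, "")[[1]]
  runs <- positive_runs(tm_chars == "H")
  for (r in seq_len(nrow(runs))) {
    if (runs$start[r] <= sp_end)  # run overlaps [1, sp_end]
      tm_chars[runs$start[r]:runs$end[r]] <- "."
  }
  tm$symbols <- paste(tm_chars, collapse = "")
  list(signal = sp, tm = tm)
}

positive_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}
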