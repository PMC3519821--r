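#' Parse an Enzyme Commission number
#'
#' EC numbers are four dotted levels, with trailing \code{-} marking
#' unspecified levels (a 2-level prediction is written \code{1.1.-.-}).
#' Unspecified levels are legal only as a suffix.
#'
#' @param ec EC string in dotted notation.
#' @return List of class \code{ec_number} with \code{levels} (character,
#'   length 4, \code{"-"} for unspecified), \code{specified_depth} and the
#'   normalized \code{string}.
#' @export
parse_ec <- function(ec) {
  parts <- strsplit(trimws(ec), ".", fixed = TRUE)[[1]]
  if (length(parts) != 4L)
    stop("EC number must have four dotted levels: '", ec, "'")
  spec <- parts != "-"
  if (any(!spec & c(spec[-1], FALSE)))
    stop("unspecified EC levels must form a suffix: '", ec, "'")
  if (any(spec & !grepl("^[0-9]+$", parts)))
    stop("EC levels must be positive integers or '-': '", ec, "'")
  structure(list(levels = parts, specified_depth = sum(spec),
                 string = paste(parts, collapse = ".")),
            class = "ec_number")
}

#' Do two EC numbers agree?
#'
#' Two EC numbers agree when they are equal on every level specified in
#' both. A full 4-level prediction therefore agrees with the 2-level
#' prediction it refines (\code{1.1.1.1} vs \code{1.1.-.-}); predictions
#' diverging on a mutually specified level do not. Symmetric and
#' reflexive.
#'
#' @param a,b \code{ec_number} objects or EC strings.
#' @return Logical.
#' @export
ec_agrees <- function(a, b) {
  if (!inherits(a, "ec_number")) a <- parse_ec(a)
  if (!inherits(b, "ec_number")) b <- parse_ec(b)
  both <- a$levels != "-" & b$levels != "-"
  all(a$levels[both] == b$levels[both])
}

ec_transfer_points <- function(best_score) {
  if (best_score >= 10) 3 else if (best_score >= 8) 2
  else if (best_score >= 6) 1 else 0
}

eficaz_points <- function(confidence) {
  if (identical(toupper(as.character(confidence)), "LOW")) return(2)
  conf <- suppressWarnings(as.numeric(confidence))
  if (is.na(conf) || conf < 0 || conf > 1)
    stop("EFICAz confidence must be in [0, 1] or 'LOW', got '",
         confidence, "'")
  if (conf >= 0.9) 4 else if (conf >= 0.8) 3.5 else if (conf >= 0.7) 3
  else if (conf >= 0.6) 2.5 else 2
}

#' Combine EC evidence from annotation transfer and de novo predictors
#'
#' Candidate EC numbers are pooled from three sources: transfer from
#' scored Swiss-Prot homologs, a 2-level de novo predictor (Ezypred-like,
#' no per-prediction confidence) and a 4-level de novo predictor
#' (EFICAz-like, with a confidence in [0, 1] or the label \code{LOW}).
#' When one candidate refines another (agrees and is more specific) only
#' the most specific representative is kept. Each candidate scores:
#' transfer points from the best agreeing homolog's rubric total (6-8
#' gives 1, 8-10 gives 2, 10 and above 3); +1 when at least three distinct
#' Swiss-Prot hits carry an agreeing EC; +2 when the 2-level predictor
#' agrees; and EFICAz confidence points when it agrees (LOW 2, then 2.5 /
#' 3 / 3.5 / 4 for confidence bands 0.6-0.7 / 0.7-0.8 / 0.8-0.9 /
#' 0.9-1). Tiers are assigned at 7/5/3.
#'
#' @param transfers Data frame with columns \code{ec}, \code{score}
#'   (homolog rubric total) and optionally \code{subject_id}; one row per
#'   transferring hit. May be empty or \code{NULL}.
#' @param ezypred EC string of the 2-level prediction, or \code{NULL}.
#' @param eficaz List with \code{ec} and \code{confidence}, or \code{NULL}.
#' @param scheme Tier scheme (default 7/5/3).
#' @return Data frame of EC predictions sorted by descending total, ties
#'   by EC string.
#' @export
combine_ec_evidence <- function(transfers = NULL, ezypred = NULL,
                                eficaz = NULL,
                                scheme = tier_scheme(7, 5, 3)) {
  if (is.null(transfers))
    transfers <- data.frame(ec = character(), score = numeric(),
                            stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(transfers))
    transfers$subject_id <- as.character(seq_len(nrow(transfers)))
  ez <- if (!is.null(ezypred)) parse_ec(ezypred)
  ef <- if (!is.null(eficaz)) parse_ec(eficaz$ec)

  cands <- lapply(unique(c(transfers$ec,
                           if (!is.null(ez)) ez$string,
                           if (!is.null(ef)) ef$string)), parse_ec)
  if (!length(cands))
    return(ec_prediction_table(list()))

  # keep only the most specific representative of each agreement class
  keep <- vapply(seq_along(cands), function(i) {
    !any(vapply(seq_along(cands), function(j) {
      i != j && ec_agrees(cands[[i]], cands[[j]]) &&
        (cands[[j]]$specified_depth > cands[[i]]$specified_depth ||
           (cands[[j]]$specified_depth == cands[[i]]$specified_depth &&
              j < i && cands[[j]]$string == cands[[i]]$string))
    }, NA))
  }, NA)
  cands <- cands[keep]

  preds <- lapply(cands, function(cand) {
    agreeing <- vapply(transfers$ec, function(e) ec_agrees(cand, e), NA)
    sources <- character()
    p_transfer <- 0
    p_consensus <- 0
    if (any(agreeing)) {
      p_transfer <- ec_transfer_points(max(transfers$score[agreeing]))
      if (p_transfer > 0) sources <- c(sources, "TRANSFER")
      ids <- transfers$subject_id[agreeing]
      ids[!nzchar(ids)] <- paste0(".row", which(agreeing)[!nzchar(ids)])
      if (length(unique(ids)) >= 3L) p_consensus <- 1
    }
    p_ezypred <- 0
    if (!is.null(ez) && ec_agrees(cand, ez)) {
      p_ezypred <- 2
      sources <- c(sources, "EZYPRED")
    }
    p_eficaz <- 0
    if (!is.null(ef) && ec_agrees(cand, ef)) {
      p_eficaz <- eficaz_points(eficaz$confidence)
      sources <- c(sources, "EFICAZ")
    }
    total <- p_transfer + p_consensus + p_ezypred + p_eficaz
    list(ec = cand$string, points_transfer = p_transfer,
         points_consensus = p_consensus, points_ezypred = p_ezypred,
         points_eficaz = p_eficaz, total = total,
         tier = assign_tier(total, scheme),
         sources = paste(sources, collapse = ";"))
  })
  tab <- ec_prediction_table(preds)
  tab[order(-tab$total, tab$ec), , drop = FALSE]
}

ec_prediction_table <- function(preds) {
  data.frame(
    ec = vapply(preds, `[[`, "", "ec"),
    points_transfer = vapply(preds, `[[`, 0, "points_transfer"),
    points_consensus = vapply(preds, `[[`, 0, "points_consensus"),
    points_ezypred = vapply(preds, `[[`, 0, "points_ezypred"),
    points_eficaz = vapply(preds, `[[`, 0, "points_eficaz"),
    total = vapply(preds, `[[`, 0, "total"),
    tier = vapply(preds, `[[`, "", "tier"),
    sources = vapply(preds, `[[`, "", "sources"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Is the query predicted to be an enzyme?
#'
#' True when any combined EC prediction reaches at least the probable tier
#' (total of 3 or more under the 7/5/3 scheme).
#'
#' @param predictions Result of \code{\link{combine_ec_evidence}}.
#' @param scheme Tier scheme.
#' @return Logical.
#' @export
is_enzyme <- function(predictions, scheme = tier_scheme(7, 5, 3)) {
  nrow(predictions) > 0 && any(predictions$total >= scheme$probable)
}
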