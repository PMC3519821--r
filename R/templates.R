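#' @name templates
#' @title Structure-template scoring and non-redundant selection
#'
#' @description
#' Structure templates for homology modeling come from three detection
#' routes: sequence search against the PDB (e-value cut 1e-3), profile
#' search against domain representatives (RPS-BLAST, cut 1e-2), and
#' profile-profile search (HHpred-like, probability cut 80). All hits to
#' one template are pooled into a single template score; ranked templates
#' are then scanned greedily, keeping each template only if it covers at
#' least 30 query residues not covered by higher-ranked accepted
#' templates.
NULL

TEMPLATE_DETECTION_CUTS <- list(BLAST = 1e-3, RPSBLAST = 1e-2, HHPRED = 80)

template_identity_points <- function(identity) {
  if (identity >= 90) 5L else if (identity >= 80) 4L
  else if (identity >= 60) 3L else if (identity >= 40) 2L
  else if (identity >= 20) 1L else 0L
}

template_probability_points <- function(prob) {
  if (is.na(prob)) 0L
  else if (prob >= 99.99) 5L else if (prob >= 99) 4L
  else if (prob >= 90) 3L else if (prob >= 85) 2L
  else if (prob >= 80) 1L else 0L
}

template_evalue_points <- function(e) {
  if (is.na(e)) 0L
  else if (e <= 1e-54) 4L else if (e <= 1e-18) 3L
  else if (e <= 1e-6) 2L else if (e <= 1e-2) 1L else 0L
}

#' Filter template hits by their method's detection cut
#'
#' @param hits Template hits data frame (PDB or SCOP collection).
#' @return Rows passing BLAST e-value <= 1e-3, RPS-BLAST e-value <= 1e-2,
#'   or HHpred probability >= 80, by method.
#' @export
template_detection_filter <- function(hits) {
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    m <- hits$method[i]
    if (m == "HHPRED")
      !is.na(hits$probability_pct[i]) &&
        hits$probability_pct[i] >= TEMPLATE_DETECTION_CUTS$HHPRED
    else
      !is.na(hits$evalue[i]) && hits$evalue[i] <= TEMPLATE_DETECTION_CUTS[[m]]
  }, NA)
  hits[keep, , drop = FALSE]
}

#' Score one structure template from all its hits
#'
#' Pools every hit sharing a template id: up to 5 points for the best
#' sequence identity (bins 20/40/60/80/90), up to 5 for the best
#' profile-profile probability (bins 80/85/90/99/99.99), up to 4 for the
#' best sequence/profile e-value (bins 1e-2/1e-6/1e-18/1e-54), and a
#' consensus bonus of 1 when two of the three methods detect the template
#' or 2 when all three do. The covered query range is the union of the
#' hits' alignment intervals.
#'
#' @param hits Data frame of hits that all share one \code{subject_id} and
#'   have passed \code{\link{template_detection_filter}}.
#' @return List of class \code{template_score} with component points,
#'   \code{total}, \code{method_set}, \code{q_ranges} (data frame of
#'   disjoint 1-based intervals), plus the best e-value and probability
#'   used for rank tie-breaking.
#' @export
score_template <- function(hits) {
  if (!nrow(hits)) stop("no hits supplied for template scoring")
  id <- unique(as.character(hits$subject_id))
  if (length(id) != 1L)
    stop("hits for one template must share a subject_id; got: ",
         paste(id, collapse = ", "))
  methods <- sort(unique(hits$method))
  hh <- hits[hits$method == "HHPRED", , drop = FALSE]
  seqs <- hits[hits$method != "HHPRED", , drop = FALSE]

  best_prob <- if (nrow(hh)) max(hh$probability_pct, na.rm = TRUE) else NA_real_
  best_evalue <- if (nrow(seqs) && any(!is.na(seqs$evalue)))
    min(seqs$evalue, na.rm = TRUE) else NA_real_

  p_id <- template_identity_points(max(hits$identity_pct))
  p_prob <- template_probability_points(best_prob)
  p_e <- template_evalue_points(best_evalue)
  p_cons <- if (length(methods) >= 3L) 2L else if (length(methods) == 2L) 1L
            else 0L
  total <- p_id + p_prob + p_e + p_cons

  mask <- interval_mask(hits$q_start, hits$q_end, max(hits$q_end))
  structure(list(
    template_id = id,
    method_set = methods,
    points_identity = p_id,
    points_probability = p_prob,
    points_evalue = p_e,
    points_consensus = p_cons,
    total = total,
    best_evalue = best_evalue,
    best_probability = best_prob,
    tier = template_tier(best_prob, best_evalue),
    q_ranges = mask_to_ranges(mask)
  ), class = "template_score")
}

# display tier for the summary page; thresholds mirror the confidence
# bands used for probability/e-value points
template_tier <- function(prob, evalue) {
  if ((!is.na(prob) && prob >= 99) || (!is.na(evalue) && evalue <= 1e-18))
    "VERY_CONFIDENT"
  else if ((!is.na(prob) && prob >= 90) || (!is.na(evalue) && evalue <= 1e-6))
    "CONFIDENT"
  else "PROBABLE"
}

interval_mask <- function(starts, ends, L) {
  mask <- logical(L)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  mask
}

mask_to_ranges <- function(mask) {
  runs <- positive_runs(mask)
  data.frame(start = as.integer(runs$start), end = as.integer(runs$end))
}

template_residues <- function(score) {
  unlist(lapply(seq_len(nrow(score$q_ranges)), function(i)
    score$q_ranges$start[i]:score$q_ranges$end[i]))
}

#' Rank template scores
#'
#' Descending total, then ascending best e-value, then descending best
#' probability, then template id — a deterministic order for the greedy
#' selection scan.
#'
#' @param scores List of \code{\link{score_template}} results.
#' @return The list, ranked.
#' @export
rank_templates <- function(scores) {
  if (!length(scores)) return(scores)
  ord <- order(-vapply(scores, `[[`, 0, "total"),
               vapply(scores, function(s)
                 if (is.na(s$best_evalue)) Inf else s$best_evalue, 0),
               -vapply(scores, function(s)
                 if (is.na(s$best_probability)) -1 else s$best_probability, 0),
               vapply(scores, `[[`, "", "template_id"))
  scores[ord]
}

#' Greedy non-redundant template selection
#'
#' Scans templates from the top of the ranking and accepts a template only
#' if it covers at least \code{min_new} query residues not yet covered by
#' previously accepted templates (the first template included: a template
#' under 30 residues is uninformative for modeling). Accepted templates
#' extend the coverage mask.
#'
#' @param ranked List of template scores, already ranked
#'   (\code{\link{rank_templates}}).
#' @param query_length Query length in residues.
#' @param min_new Minimum number of newly covered residues (default 30).
#' @return List of class \code{template_selection} with \code{selected}
#'   (the accepted scores, in order), \code{new_residues} (count each
#'   selection added), \code{mask} (logical per residue) and
#'   \code{fraction_covered}.
#' @export
select_nonredundant <- function(ranked, query_length, min_new = 30L) {
  if (min_new < 1) stop("min_new must be at least 1")
  mask <- logical(query_length)
  selected <- list()
  added <- integer()
  for (s in ranked) {
    res <- template_residues(s)
    res <- res[res <= query_length]
    new <- setdiff(res, which(mask))
    if (length(new) >= min_new) {
      mask[new] <- TRUE
      selected[[length(selected) + 1L]] <- s
      added <- c(added, length(new))
    }
  }
  structure(list(selected = selected, new_residues = added, mask = mask,
                 fraction_covered = mean(mask)),
            class = "template_selection")
}

#' Residue-coverage statistics for a template selection
#'
#' @param selection A \code{\link{select_nonredundant}} result.
#' @param disorder Optional consensus \code{DISORDER} track; disordered
#'   residues are counted as accounted-for even without a template, since
#'   they are not expected to adopt a modelable structure.
#' @return List with \code{fraction_covered},
#'   \code{fraction_covered_or_disordered} and \code{high_coverage}
#'   (whether the combined fraction exceeds 0.80).
#' @export
coverage_stats <- function(selection, disorder = NULL) {
  mask <- selection$mask
  combined <- mask
  if (!is.null(disorder)) {
    dis <- strsplit(disorder$symbols, "")[[1]] == POSITIVE_SYMBOL[["DISORDER"]]
    if (length(dis) != length(mask))
      stop("disorder track length differs from query length")
    combined <- mask | dis
  }
  list(fraction_covered = mean(mask),
       fraction_covered_or_disordered = mean(combined),
       high_coverage = mean(combined) > 0.80)
}
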