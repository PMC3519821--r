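#' Confidence-tier thresholds
#'
#' A tier scheme maps a rubric total to one of the labels
#' \code{VERY_CONFIDENT}, \code{CONFIDENT}, \code{PROBABLE},
#' \code{UNASSIGNED} by three descending thresholds. Homolog and GO rubrics
#' use 10/8/6; the EC rubric uses 7/5/3.
#'
#' @param very,confident,probable Descending thresholds.
#' @return A list of class \code{tier_scheme}.
#' @export
tier_scheme <- function(very = 10, confident = 8, probable = 6) {
  if (!(very > confident && confident > probable && probable >= 0))
    stop("tier thresholds must satisfy very > confident > probable >= 0")
  structure(list(very = very, confident = confident, probable = probable),
            class = "tier_scheme")
}

TIERS <- c("VERY_CONFIDENT", "CONFIDENT", "PROBABLE", "UNASSIGNED")

#' Assign a confidence tier to a rubric total
#'
#' @param total Rubric total (points).
#' @param scheme A \code{\link{tier_scheme}}.
#' @return One of \code{VERY_CONFIDENT}, \code{CONFIDENT}, \code{PROBABLE},
#'   \code{UNASSIGNED}.
#' @export
assign_tier <- function(total, scheme = tier_scheme()) {
  if (total >= scheme$very) "VERY_CONFIDENT"
  else if (total >= scheme$confident) "CONFIDENT"
  else if (total >= scheme$probable) "PROBABLE"
  else "UNASSIGNED"
}

#' Reciprocal-best-hit status for one search direction
#'
#' @param status One of \code{BEST}, \code{NOT_BEST}, \code{UNAVAILABLE}.
#' @return The validated status string.
#' @export
reciprocal_state <- function(status) {
  match.arg(status, c("BEST", "NOT_BEST", "UNAVAILABLE"))
}

#' Determine reciprocal-best-hit status in both directions
#'
#' The classic orthology proxy: the hit should be the query's top-ranked
#' hit against the hit's proteome (forward), and the query should be the
#' hit's top-ranked hit against the query's proteome (reverse). When a
#' proteome hit table is not available the direction is \code{UNAVAILABLE}
#' (worth 1 rubric point rather than 2).
#'
#' @param query_id,hit_id Sequence identifiers.
#' @param forward_hits Hits of the query against the hit's proteome, sorted
#'   by ascending e-value, or \code{NULL} when unavailable.
#' @param reverse_hits Hits of the hit against the query's proteome,
#'   likewise, or \code{NULL}.
#' @return List with elements \code{forward} and \code{reverse}, each one
#'   of \code{BEST}, \code{NOT_BEST}, \code{UNAVAILABLE}.
#' @export
reciprocal_status <- function(query_id, hit_id, forward_hits = NULL,
                              reverse_hits = NULL) {
  one <- function(tab, top_id) {
    if (is.null(tab)) return("UNAVAILABLE")
    if (nrow(tab) && tab$subject_id[1] == top_id) "BEST" else "NOT_BEST"
  }
  list(forward = one(forward_hits, hit_id),
       reverse = one(reverse_hits, query_id))
}

RECIPROCAL_POINTS <- c(BEST = 2L, UNAVAILABLE = 1L, NOT_BEST = 0L)

# identity bins shared by the homolog and GO rubrics; both require the
# alignment to cover > 40% on the weaker side before identity counts.
# `top5` adds the homolog rubric's extra > 99% bin.
identity_points <- function(identity, q_cov, s_cov, top5 = TRUE) {
  if (min(q_cov, s_cov) <= 40) return(0L)
  if (top5 && identity > 99) 5L
  else if (identity >= 90) 4L
  else if (identity >= 70) 3L
  else if (identity >= 50) 2L
  else if (identity >= 30) 1L
  else 0L
}

coverage_points <- function(q_cov, s_cov) {
  m <- min(q_cov, s_cov)
  if (m >= 80) 2L else if (m >= 60) 1L else 0L
}

evalue_point <- function(evalue) {
  if (!is.na(evalue) && evalue < 0.001) 1L else 0L
}

#' Score a Swiss-Prot homolog
#'
#' Applies the homolog confidence rubric: 1 point for BLAST e-value below
#' 0.001; up to 5 for sequence identity (provided both-side coverage
#' exceeds 40 percent); up to 2 for alignment coverage of both query and
#' hit; and up to 2 points per reciprocal-best-hit direction (2 best, 1
#' when the proteome table is unavailable, 0 otherwise). Totals run 0-12
#' and map to tiers at 10/8/6.
#'
#' @param hit One hit (one-row data frame or list) from the \code{SPROT}
#'   collection.
#' @param reciprocal Result of \code{\link{reciprocal_status}}.
#' @param scheme Tier scheme; the rubric's 10/8/6 by default.
#' @return List of class \code{homolog_score} with the component points,
#'   \code{total} and \code{tier}.
#' @export
score_homolog <- function(hit,
                          reciprocal = list(forward = "UNAVAILABLE",
                                            reverse = "UNAVAILABLE"),
                          scheme = tier_scheme(10, 8, 6)) {
  if (!identical(as.character(hit$collection), "SPROT"))
    stop("homolog rubric applies to SPROT hits, got ", hit$collection)
  pts <- list(
    points_evalue = evalue_point(hit$evalue),
    points_identity = identity_points(hit$identity_pct, hit$q_cov_pct,
                                      hit$s_cov_pct, top5 = TRUE),
    points_coverage = coverage_points(hit$q_cov_pct, hit$s_cov_pct),
    points_forward = RECIPROCAL_POINTS[[reciprocal_state(reciprocal$forward)]],
    points_reverse = RECIPROCAL_POINTS[[reciprocal_state(reciprocal$reverse)]]
  )
  total <- sum(unlist(pts))
  structure(c(list(subject_id = as.character(hit$subject_id)), pts,
              list(total = total, tier = assign_tier(total, scheme))),
            class = "homolog_score")
}

#' Rank confident homologs for display and annotation transfer
#'
#' Keeps hits with e-value below 0.001, sorts by descending rubric total,
#' then ascending e-value, then subject id, and truncates to the \code{n}
#' closest.
#'
#' @param hits SPROT hits data frame.
#' @param scores List of \code{\link{score_homolog}} results, parallel to
#'   \code{hits} rows.
#' @param n Number of homologs to keep (default 10).
#' @return Data frame of the top homologs with score columns appended.
#' @export
top_homologs <- function(hits, scores, n = 10L) {
  if (!nrow(hits)) return(homolog_table(hits, scores))
  keep <- !is.na(hits$evalue) & hits$evalue < 0.001
  hits <- hits[keep, , drop = FALSE]
  scores <- scores[keep]
  tab <- homolog_table(hits, scores)
  ord <- order(-tab$total, tab$evalue, tab$subject_id)
  utils::head(tab[ord, , drop = FALSE], n)
}

homolog_table <- function(hits, scores) {
  data.frame(
    subject_id = as.character(hits$subject_id),
    evalue = if (nrow(hits)) hits$evalue else numeric(),
    identity_pct = if (nrow(hits)) hits$identity_pct else numeric(),
    q_cov_pct = if (nrow(hits)) hits$q_cov_pct else numeric(),
    s_cov_pct = if (nrow(hits)) hits$s_cov_pct else numeric(),
    annotation = if (nrow(hits)) hits$annotation else character(),
    points_evalue = vapply(scores, `[[`, 0L, "points_evalue"),
    points_identity = vapply(scores, `[[`, 0L, "points_identity"),
    points_coverage = vapply(scores, `[[`, 0L, "points_coverage"),
    points_forward = vapply(scores, `[[`, 0L, "points_forward"),
    points_reverse = vapply(scores, `[[`, 0L, "points_reverse"),
    total = vapply(scores, `[[`, 0, "total"),
    tier = vapply(scores, `[[`, "", "tier"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
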