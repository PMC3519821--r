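#' @name go_scoring
#' @title Gene Ontology term transfer with confidence scores
#'
#' @description
#' Candidate GO terms come from annotated homologs. Each term is scored by
#' the similarity of the best supporting hit (e-value, identity, coverage),
#' the reliability of the evidence code under which the term was assigned
#' to that hit, and a consensus bonus when at least three distinct hits
#' carry the term. Because GO is hierarchical, a term's ancestors are then
#' assigned the highest score among their descendants. Totals run 0-12
#' with tiers at 10/8/6.
NULL

GO_EVIDENCE_POINTS <- c(
  EXP = 3L, IDA = 3L,
  IPI = 2L, IMP = 2L, IGI = 2L, IEP = 2L, ISO = 2L, TAS = 2L,
  ISS = 1L, ISA = 1L, ISM = 1L, IGC = 1L, IBA = 1L, IBD = 1L, IKR = 1L,
  IRD = 1L, RCA = 1L, NAS = 1L, IC = 1L, IEA = 1L
)

go_evidence_points <- function(code) {
  p <- GO_EVIDENCE_POINTS[code]
  ifelse(is.na(p), 0L, p)
}

#' Score one candidate GO term from its supporting hits
#'
#' Each supporting hit contributes a base score: 1 point for e-value below
#' 0.001, up to 4 for identity (requires both-side coverage above 40
#' percent), up to 2 for both-side alignment coverage, plus evidence-code
#' points (experimental codes EXP/IDA 3; IPI, IMP, IGI, IEP, ISO, TAS 2;
#' curated/electronic codes 1; unknown codes 0). The term's base is the
#' maximum over its supporting hits, plus a consensus bonus of 2 when the
#' term is associated with at least three distinct hits.
#'
#' @param term GO term identifier.
#' @param supporting Data frame with hit columns (\code{subject_id},
#'   \code{evalue}, \code{identity_pct}, \code{q_cov_pct}, \code{s_cov_pct})
#'   and an \code{evidence} column, one row per (hit, assignment).
#' @param scheme Tier scheme (default 10/8/6).
#' @return List of class \code{go_score} with component points,
#'   \code{total}, \code{tier}, \code{supporting_hits} and
#'   \code{propagated_from} (\code{NA} for directly scored terms).
#' @export
score_go_term <- function(term, supporting, scheme = tier_scheme(10, 8, 6)) {
  if (is.null(supporting) || !nrow(supporting))
    stop("GO term ", term, " has no supporting hits")
  per_hit <- lapply(seq_len(nrow(supporting)), function(i) {
    h <- supporting[i, ]
    c(points_evalue = evalue_point(h$evalue),
      points_identity = identity_points(h$identity_pct, h$q_cov_pct,
                                        h$s_cov_pct, top5 = FALSE),
      points_coverage = coverage_points(h$q_cov_pct, h$s_cov_pct),
      points_evidence = unname(go_evidence_points(h$evidence)))
  })
  bases <- vapply(per_hit, sum, 0)
  best <- per_hit[[which.max(bases)]]
  distinct <- unique(as.character(supporting$subject_id))
  consensus <- if (length(distinct) >= 3L) 2L else 0L
  total <- max(bases) + consensus
  structure(list(
    term = term,
    points_evalue = unname(best[["points_evalue"]]),
    points_identity = unname(best[["points_identity"]]),
    points_coverage = unname(best[["points_coverage"]]),
    points_evidence = unname(best[["points_evidence"]]),
    points_consensus = consensus,
    total = total,
    tier = assign_tier(total, scheme),
    supporting_hits = distinct,
    propagated_from = NA_character_
  ), class = "go_score")
}

#' Build a GO hierarchy from a parent-edge table
#'
#' @param edges Data frame with columns \code{child_term},
#'   \code{parent_term} (is-a and part-of relations collapsed to plain
#'   parent edges).
#' @return List of class \code{go_hierarchy} with the edge table and the
#'   term set; rejects cyclic input.
#' @export
go_hierarchy <- function(edges) {
  edges <- unique(edges[c("child_term", "parent_term")])
  terms <- unique(c(edges$child_term, edges$parent_term))
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    if (!igraph::is_dag(g))
      stop("GO edge table contains a cycle")
  }
  structure(list(edges = edges, terms = terms), class = "go_hierarchy")
}

# all ancestors of `term` under the parent edges (term excluded)
go_ancestors <- function(hierarchy, term) {
  out <- character()
  frontier <- term
  while (length(frontier)) {
    parents <- hierarchy$edges$parent_term[
      hierarchy$edges$child_term %in% frontier]
    parents <- setdiff(unique(parents), c(out, term))
    out <- c(out, parents)
    frontier <- parents
  }
  out
}

#' Propagate GO scores to ancestor terms
#'
#' Once a term is assigned, its ancestors are assigned too: every ancestor
#' of a scored term receives the maximum of its own direct score (if any)
#' and the scores of all its scored descendants. Propagated entries record
#' the descendant that supplied the score. The operation is idempotent.
#'
#' @param scores Named list of \code{\link{score_go_term}} results, keyed
#'   by term.
#' @param hierarchy A \code{\link{go_hierarchy}}.
#' @param scheme Tier scheme used for propagated entries.
#' @return Named list of scores covering the input terms and all their
#'   ancestors.
#' @export
propagate_parents <- function(scores, hierarchy,
                              scheme = tier_scheme(10, 8, 6)) {
  direct <- scores
  out <- scores
  for (term in names(direct)) {
    for (anc in go_ancestors(hierarchy, term)) {
      cand <- direct[[term]]
      cur <- out[[anc]]
      if (is.null(cur) || cand$total > cur$total) {
        inherited <- cand
        inherited$term <- anc
        inherited$propagated_from <- term
        inherited$tier <- assign_tier(inherited$total, scheme)
        out[[anc]] <- inherited
      }
    }
  }
  out
}

#' Rank GO predictions for reporting
#'
#' Drops terms below the probable threshold and sorts by descending total,
#' breaking ties by term identifier.
#'
#' @param scores Named list of GO scores (after propagation).
#' @param scheme Tier scheme; its \code{probable} threshold is the
#'   reporting cut.
#' @return Data frame, one row per reported term.
#' @export
rank_go_predictions <- function(scores, scheme = tier_scheme(10, 8, 6)) {
  tab <- go_score_table(scores)
  tab <- tab[tab$total >= scheme$probable, , drop = FALSE]
  tab[order(-tab$total, tab$term), , drop = FALSE]
}

go_score_table <- function(scores) {
  data.frame(
    term = vapply(scores, `[[`, "", "term"),
    points_evalue = vapply(scores, `[[`, 0L, "points_evalue"),
    points_identity = vapply(scores, `[[`, 0L, "points_identity"),
    points_coverage = vapply(scores, `[[`, 0L, "points_coverage"),
    points_evidence = vapply(scores, `[[`, 0L, "points_evidence"),
    points_consensus = vapply(scores, `[[`, 0L, "points_consensus"),
    total = vapply(scores, `[[`, 0, "total"),
    tier = vapply(scores, `[[`, "", "tier"),
    supporting_hits = vapply(scores, function(s)
      paste(s$supporting_hits, collapse = ";"), ""),
    propagated_from = vapply(scores, `[[`, "", "propagated_from"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Collect candidate GO terms from annotated hits
#'
#' Explodes the \code{go_terms} list column of a GO-collection hits table
#' into one supporting row per (term, hit, evidence) and scores every term.
#'
#' @param hits GO hits data frame (\code{\link{read_hits}}).
#' @param scheme Tier scheme.
#' @return Named list of \code{go_score} objects keyed by term.
#' @export
score_go_hits <- function(hits, scheme = tier_scheme(10, 8, 6)) {
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    g <- hits$go_terms[[i]]
    if (!nrow(g)) next
    rows[[length(rows) + 1L]] <- data.frame(
      term = g$term, evidence = g$evidence,
      subject_id = hits$subject_id[i], evalue = hits$evalue[i],
      identity_pct = hits$identity_pct[i],
      q_cov_pct = hits$q_cov_pct[i], s_cov_pct = hits$s_cov_pct[i],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(list())
  support <- do.call(rbind, rows)
  terms <- sort(unique(support$term))
  scores <- lapply(terms, function(tm)
    score_go_term(tm, support[support$term == tm, , drop = FALSE], scheme))
  names(scores) <- terms
  scores
}
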