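#' @name report
#' @title Assembled annotation report
#'
#' @description
#' The final report for one query holds the consensus feature tracks, the
#' scored homolog / GO / EC predictions with confidence tiers, the
#' selected structure templates and the residue-coverage summary. It is
#' written both as loss-less JSON (machine readable, round-trips through
#' \code{\link{read_report}}) and as a plain-text summary in which every
#' consensus track is printed as one line aligned under the query
#' sequence.
NULL

new_report <- function(query, organism_type = "UNKNOWN") {
  structure(list(
    query = list(id = query$id, residues = query$residues,
                 length = query$length),
    metadata = list(organism_type = organism_type,
                    generator = "metannot",
                    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    consensus_tracks = list(),
    homologs = homolog_table(data.frame(), list()),
    go_terms = go_score_table(list())[0, ],
    ec_numbers = ec_prediction_table(list()),
    is_enzyme = FALSE,
    templates = template_report_table(list(), integer()),
    coverage = list(fraction_covered = 0,
                    fraction_covered_or_disordered = 0,
                    high_coverage = FALSE)
  ), class = "annotation_report")
}

template_report_table <- function(selected, new_residues) {
  data.frame(
    template_id = vapply(selected, `[[`, "", "template_id"),
    methods = vapply(selected, function(s) paste(s$method_set,
                                                 collapse = ";"), ""),
    points_identity = vapply(selected, `[[`, 0L, "points_identity"),
    points_probability = vapply(selected, `[[`, 0L, "points_probability"),
    points_evalue = vapply(selected, `[[`, 0L, "points_evalue"),
    points_consensus = vapply(selected, `[[`, 0L, "points_consensus"),
    total = vapply(selected, `[[`, 0, "total"),
    tier = vapply(selected, `[[`, "", "tier"),
    q_ranges = vapply(selected, function(s)
      paste(sprintf("%d-%d", s$q_ranges$start, s$q_ranges$end),
            collapse = ","), ""),
    new_residues = as.integer(new_residues),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a report to JSON and a plain-text summary
#'
#' @param report An \code{annotation_report}.
#' @param json_path Path for the machine-readable JSON
#'   (\code{\link{read_report}} inverts it exactly).
#' @param text_path Optional path for the human-readable summary.
#' @param width Line width of the aligned track blocks in the text summary.
#' @export
write_report <- function(report, json_path, text_path = NULL, width = 60L) {
  plain <- report
  plain$consensus_tracks <- lapply(report$consensus_tracks, function(t)
    list(feature = t$feature, symbols = t$symbols))
  class(plain) <- NULL
  jsonlite::write_json(plain, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  if (!is.null(text_path))
    writeLines(render_text_summary(report, width), text_path)
  invisible(json_path)
}

#' Read a report back from JSON
#'
#' @param json_path Path written by \code{\link{write_report}}.
#' @return The reconstructed \code{annotation_report}.
#' @export
read_report <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  as_df <- function(cols, template) {
    if (!length(cols) || !length(cols[[1]])) return(template[0, , drop = FALSE])
    df <- as.data.frame(cols, stringsAsFactors = FALSE)
    for (nm in names(template)) {
      if (is.integer(template[[nm]])) df[[nm]] <- as.integer(df[[nm]])
      if (is.numeric(template[[nm]]) && !is.integer(template[[nm]]))
        df[[nm]] <- as.numeric(df[[nm]])
    }
    df[names(template)]
  }
  rep <- new_report(structure(x$query, class = "query_sequence"),
                    x$metadata$organism_type)
  rep$metadata <- x$metadata
  rep$consensus_tracks <- lapply(x$consensus_tracks, function(t)
    new_consensus_track(t$feature, t$symbols, NULL))
  rep$homologs <- as_df(x$homologs, homolog_table(data.frame(), list()))
  rep$go_terms <- as_df(x$go_terms, go_score_table(list())[0, ])
  rep$ec_numbers <- as_df(x$ec_numbers, ec_prediction_table(list()))
  rep$is_enzyme <- isTRUE(x$is_enzyme)
  rep$templates <- as_df(x$templates,
                         template_report_table(list(), integer()))
  rep$coverage <- list(
    fraction_covered = as.numeric(x$coverage$fraction_covered),
    fraction_covered_or_disordered =
      as.numeric(x$coverage$fraction_covered_or_disordered),
    high_coverage = isTRUE(x$coverage$high_coverage))
  rep
}

#' Render the plain-text summary page
#'
#' Section I shows the query in fixed-width blocks with every consensus
#' track printed as an equal-width line directly beneath it; the remaining
#' sections list the tiered function and structure predictions.
#'
#' @param report An \code{annotation_report}.
#' @param width Block width in residues.
#' @return Character vector of lines.
#' @export
render_text_summary <- function(report, width = 60L) {
  out <- c(sprintf("Query: %s (%d aa)", report$query$id, report$query$length),
           "", "== Consensus local sequence features ==")
  L <- report$query$length
  starts <- seq(1L, L, by = width)
  label_w <- max(12L, nchar(vapply(report$consensus_tracks, `[[`, "",
                                   "feature"), type = "chars"), 8L)
  pad <- function(s) formatC(s, width = label_w, flag = "-")
  for (s in starts) {
    e <- min(s + width - 1L, L)
    out <- c(out, sprintf("%s %s", pad(sprintf("%d-%d", s, e)),
                          substr(report$query$residues, s, e)))
    for (t in report$consensus_tracks)
      out <- c(out, sprintf("%s %s", pad(t$feature), substr(t$symbols, s, e)))
    out <- c(out, "")
  }

  fmt_section <- function(title, df, cols, none) {
    lines <- c(sprintf("== %s ==", title))
    if (!nrow(df)) return(c(lines, none, ""))
    for (i in seq_len(nrow(df)))
      lines <- c(lines, paste(vapply(cols, function(cl)
        sprintf("%s=%s", cl, format(df[[cl]][i])), ""), collapse = "  "))
    c(lines, "")
  }
  out <- c(out,
    fmt_section("Close homologs", report$homologs,
                c("subject_id", "total", "tier", "annotation"),
                "none detected"),
    fmt_section("GO term predictions", report$go_terms,
                c("term", "total", "tier"), "none detected"),
    sprintf("Enzyme: %s", if (report$is_enzyme) "yes" else "no"),
    fmt_section("EC number predictions", report$ec_numbers,
                c("ec", "total", "tier", "sources"), "none detected"),
    fmt_section("Structure templates (non-redundant)", report$templates,
                c("template_id", "total", "tier", "q_ranges"),
                "none detected"),
    sprintf("Residue coverage by templates: %.1f%%",
            100 * report$coverage$fraction_covered),
    sprintf("Covered or disordered: %.1f%%  (high coverage: %s)",
            100 * report$coverage$fraction_covered_or_disordered,
            if (report$coverage$high_coverage) "yes" else "no"))
  out
}
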