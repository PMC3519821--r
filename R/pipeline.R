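#' Pipeline configuration
#'
#' Defaults reproduce the published rubrics exactly: double votes for
#' PSIPRED (secondary structure) and Phobius (signal peptide), tier
#' schemes 10/8/6 for homolog and GO scores and 7/5/3 for EC scores, and a
#' 30-residue minimum of newly covered residues in template selection.
#'
#' @param organism_type Recorded in the report metadata: one of
#'   \code{EUKARYOTE}, \code{GRAM_NEGATIVE}, \code{GRAM_POSITIVE},
#'   \code{UNKNOWN}.
#' @param votes A \code{\link{vote_config}}.
#' @param homolog_scheme,go_scheme,ec_scheme Tier schemes.
#' @param min_new Minimum newly covered residues per selected template.
#' @param top_n Number of closest homologs reported.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(organism_type = c("UNKNOWN", "EUKARYOTE",
                                         "GRAM_NEGATIVE", "GRAM_POSITIVE"),
                       votes = vote_config(),
                       homolog_scheme = tier_scheme(10, 8, 6),
                       go_scheme = tier_scheme(10, 8, 6),
                       ec_scheme = tier_scheme(7, 5, 3),
                       min_new = 30L,
                       top_n = 10L) {
  structure(list(organism_type = match.arg(organism_type), votes = votes,
                 homolog_scheme = homolog_scheme, go_scheme = go_scheme,
                 ec_scheme = ec_scheme, min_new = min_new, top_n = top_n),
            class = "run_config")
}

BUNDLE_FILES <- c(query = "query.fasta", tracks = "tracks.tsv",
                  hits_sprot = "hits_sprot.tsv", hits_nr = "hits_nr.tsv",
                  alignments = "alignments.tsv", hits_go = "hits_go.tsv",
                  go_edges = "go_edges.tsv", ec_evidence = "ec_evidence.tsv",
                  hits_templates = "hits_templates.tsv",
                  reciprocal = "reciprocal.tsv")

#' Read a prediction bundle from a directory
#'
#' A bundle directory holds the query (\code{query.fasta}), the predictor
#' tracks (\code{tracks.tsv}) and any of the optional hit / evidence
#' tables: \code{hits_sprot.tsv}, \code{hits_nr.tsv} plus
#' \code{alignments.tsv} (subject_id and the hit projected onto query
#' coordinates, for the conservation profile), \code{hits_go.tsv} with
#' \code{go_edges.tsv}, \code{ec_evidence.tsv}, \code{hits_templates.tsv},
#' and \code{reciprocal.tsv} (subject_id, forward, reverse status per
#' Swiss-Prot hit, precomputed with \code{\link{reciprocal_status}} from
#' the per-proteome searches). Missing optional files simply leave their
#' report section empty.
#'
#' @param dir Bundle directory.
#' @return A list of class \code{prediction_bundle}.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  if (!file.exists(p("query.fasta"))) stop("bundle lacks query.fasta")
  query <- read_query(p("query.fasta"))
  opt <- function(f, reader, ...) {
    if (file.exists(p(f))) reader(p(f), ...) else NULL
  }
  bundle <- list(
    query = query,
    tracks = if (file.exists(p("tracks.tsv")))
      read_tracks(p("tracks.tsv"), query) else list(),
    hits_sprot = opt("hits_sprot.tsv", read_hits, "SPROT", query$length),
    hits_nr = opt("hits_nr.tsv", read_hits, "NR", query$length),
    alignments = opt("alignments.tsv", read_alignments),
    hits_go = opt("hits_go.tsv", read_hits, "GO", query$length),
    go_edges = opt("go_edges.tsv", read_go_edges),
    ec_evidence = opt("ec_evidence.tsv", read_ec_evidence),
    hits_templates = opt("hits_templates.tsv", read_hits, "PDB",
                         query$length),
    reciprocal = opt("reciprocal.tsv", read_reciprocal)
  )
  structure(bundle, class = "prediction_bundle")
}

read_alignments <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("subject_id", "aligned") %in% names(df)))
    stop("alignments file must have columns subject_id, aligned")
  df[c("subject_id", "aligned")]
}

read_reciprocal <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("subject_id", "forward", "reverse") %in% names(df)))
    stop("reciprocal file must have columns subject_id, forward, reverse")
  for (col in c("forward", "reverse"))
    df[[col]] <- vapply(df[[col]], reciprocal_state, "")
  df[c("subject_id", "forward", "reverse")]
}

#' Write a prediction bundle to a directory
#'
#' Inverse of \code{\link{read_bundle}}; only the components present in
#' the bundle are written.
#'
#' @param bundle A \code{prediction_bundle}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeLines(c(paste0(">", bundle$query$id),
               gsub("(.{60})", "\\1\n", bundle$query$residues)),
             p("query.fasta"))
  if (length(bundle$tracks)) write_tracks(bundle$tracks, p("tracks.tsv"))
  for (nm in c("hits_sprot", "hits_nr", "hits_go", "hits_templates"))
    if (!is.null(bundle[[nm]]))
      write_hits(bundle[[nm]], p(paste0(nm, ".tsv")))
  if (!is.null(bundle$alignments))
    write.table(bundle$alignments, p("alignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$go_edges))
    write_go_edges(bundle$go_edges, p("go_edges.tsv"))
  if (!is.null(bundle$ec_evidence))
    write_ec_evidence(bundle$ec_evidence, p("ec_evidence.tsv"))
  if (!is.null(bundle$reciprocal))
    write.table(bundle$reciprocal, p("reciprocal.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the full annotation pipeline on a bundle
#'
#' Executes feature consensus, homolog scoring, GO term scoring with
#' parent propagation, EC evidence combination, and template scoring with
#' greedy non-redundant selection, and assembles the report. Deterministic
#' for a fixed bundle and configuration; bundle sections that are absent
#' leave their report section empty.
#'
#' @param bundle A \code{prediction_bundle} (\code{\link{read_bundle}} or
#'   \code{\link{make_bundle}}) or a bundle directory path.
#' @param config A \code{\link{run_config}}.
#' @return An \code{annotation_report}.
#' @export
run_pipeline <- function(bundle, config = run_config()) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  query <- bundle$query
  report <- new_report(query, config$organism_type)

  report$consensus_tracks <- build_consensus_tracks(bundle, config)

  if (!is.null(bundle$hits_sprot) && nrow(bundle$hits_sprot)) {
    hits <- bundle$hits_sprot
    scores <- lapply(seq_len(nrow(hits)), function(i) {
      rec <- lookup_reciprocal(bundle$reciprocal, hits$subject_id[i])
      score_homolog(hits[i, ], rec, config$homolog_scheme)
    })
    report$homologs <- top_homologs(hits, scores, config$top_n)
  }

  if (!is.null(bundle$hits_go) && nrow(bundle$hits_go)) {
    scores <- score_go_hits(bundle$hits_go, config$go_scheme)
    if (length(scores) && !is.null(bundle$go_edges) &&
        nrow(bundle$go_edges)) {
      scores <- propagate_parents(scores, go_hierarchy(bundle$go_edges),
                                  config$go_scheme)
    }
    report$go_terms <- rank_go_predictions(scores, config$go_scheme)
  }

  if (!is.null(bundle$ec_evidence) && nrow(bundle$ec_evidence)) {
    ev <- bundle$ec_evidence
    tr <- ev[ev$source == "TRANSFER", , drop = FALSE]
    transfers <- if (nrow(tr))
      data.frame(ec = tr$ec, score = as.numeric(tr$confidence),
                 subject_id = tr$subject_id, stringsAsFactors = FALSE)
    ez <- ev$ec[ev$source == "EZYPRED"]
    efr <- ev[ev$source == "EFICAZ", , drop = FALSE]
    ef <- if (nrow(efr)) list(ec = efr$ec[1], confidence = efr$confidence[1])
    report$ec_numbers <- combine_ec_evidence(
      if (nrow(tr)) transfers else NULL,
      if (length(ez)) ez[1] else NULL, ef, config$ec_scheme)
    report$is_enzyme <- is_enzyme(report$ec_numbers, config$ec_scheme)
  }

  disorder <- consensus_by_feature(report$consensus_tracks, "DISORDER")
  if (!is.null(bundle$hits_templates) && nrow(bundle$hits_templates)) {
    hits <- template_detection_filter(bundle$hits_templates)
    if (nrow(hits)) {
      scores <- lapply(split(seq_len(nrow(hits)), hits$subject_id),
                       function(idx) score_template(hits[idx, , drop = FALSE]))
      ranked <- rank_templates(unname(scores))
      sel <- select_nonredundant(ranked, query$length, config$min_new)
      report$templates <- template_report_table(sel$selected,
                                                sel$new_residues)
      report$coverage <- coverage_stats(sel, disorder)
    }
  }
  report
}

lookup_reciprocal <- function(reciprocal, subject_id) {
  if (is.null(reciprocal))
    return(list(forward = "UNAVAILABLE", reverse = "UNAVAILABLE"))
  i <- match(subject_id, reciprocal$subject_id)
  if (is.na(i))
    return(list(forward = "UNAVAILABLE", reverse = "UNAVAILABLE"))
  list(forward = reciprocal$forward[i], reverse = reciprocal$reverse[i])
}

consensus_by_feature <- function(tracks, feature) {
  for (t in tracks) if (t$feature == feature) return(t)
  NULL
}

build_consensus_tracks <- function(bundle, config) {
  tracks <- bundle$tracks
  out <- list()
  have <- function(f) any(vapply(tracks, function(t) t$feature == f, NA))
  if (have("SS3"))
    out$SS3 <- consensus_ss3(tracks, config$votes)
  for (f in c("DISORDER", "TM", "SIGNAL", "COIL", "LOWCOMPLEX"))
    if (have(f))
      out[[f]] <- consensus_binary(tracks, f, config$votes)
  if (!is.null(out$SIGNAL) && !is.null(out$TM)) {
    res <- resolve_sp_tm(out$SIGNAL, out$TM)
    out$SIGNAL <- res$signal
    out$TM <- res$tm
  }
  aligned <- character()
  if (!is.null(bundle$hits_nr) && !is.null(bundle$alignments)) {
    kept <- profile_filter(bundle$hits_nr)
    aligned <- bundle$alignments$aligned[
      bundle$alignments$subject_id %in% kept$subject_id]
  }
  out$CONSERVATION <- conservation_track(bundle$query, aligned)
  unname(out)
}

#' Serialize consensus tracks in the tracks.tsv dialect
#'
#' Consensus tracks are written with predictor name \code{CONSENSUS} so
#' they can be read back with \code{\link{read_tracks}}.
#'
#' @param tracks List of consensus tracks (from a report).
#' @param path Output path.
#' @export
write_consensus_tracks <- function(tracks, path) {
  write_tracks(lapply(tracks, function(t)
    prediction_track("CONSENSUS", t$feature, t$symbols)), path)
}
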