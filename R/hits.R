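#' @name hits
#' @title Tabular homology-search hits
#'
#' @description
#' Hits from sequence and profile searches are exchanged as tab-separated
#' files in a BLAST-tabular-like dialect with annotation columns:
#' \code{subject_id, method, evalue, probability_pct, identity_pct, q_start,
#' q_end, s_start, s_end, q_cov_pct, s_cov_pct, annotation, go_terms,
#' ec_numbers}. Trailing optional columns may be empty. \code{go_terms}
#' holds \code{;}-separated \code{TERM|EVIDENCE} pairs, \code{ec_numbers}
#' \code{;}-separated dotted EC strings. All coordinates are 1-based
#' inclusive. Profile searches report \code{probability_pct} and may omit
#' \code{evalue}; sequence searches do the opposite.
NULL

HIT_COLLECTIONS <- c("SPROT", "NR", "GO", "PDB", "SCOP", "CDD")
HIT_METHODS <- c("BLAST", "RPSBLAST", "HHPRED")

HIT_COLUMNS <- c("subject_id", "method", "evalue", "probability_pct",
                 "identity_pct", "q_start", "q_end", "s_start", "s_end",
                 "q_cov_pct", "s_cov_pct", "annotation", "go_terms",
                 "ec_numbers")

#' Read search hits from a hits TSV file
#'
#' @param path Path to the hits file (dialect in \link{hits}).
#' @param collection Which collection the hits come from: one of
#'   \code{SPROT}, \code{NR}, \code{GO}, \code{PDB}, \code{SCOP}, \code{CDD}.
#' @param query_length Optional query length; when given, query ranges are
#'   checked against it.
#' @return A data frame with one row per hit; \code{go_terms} and
#'   \code{ec_numbers} are list columns (a data frame of
#'   \code{term}/\code{evidence} pairs, and a character vector).
#' @export
read_hits <- function(path, collection, query_length = NULL) {
  collection <- match.arg(collection, HIT_COLLECTIONS)
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  missing_cols <- setdiff(setdiff(HIT_COLUMNS, c("go_terms", "ec_numbers")),
                          names(raw))
  if (length(missing_cols))
    stop("hits file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  for (opt in c("go_terms", "ec_numbers"))
    if (!opt %in% names(raw)) raw[[opt]] <- ""

  n <- nrow(raw)
  num <- function(col, allow_empty = FALSE) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    empty <- !nzchar(trimws(x))
    bad <- which(is.na(out) & !empty)
    if (length(bad))
      stop("hits file ", path, " line ", bad[1] + 1L,
           ": non-numeric ", col, " '", x[bad[1]], "'")
    if (!allow_empty && any(empty))
      stop("hits file ", path, " line ", which(empty)[1] + 1L,
           ": empty ", col)
    out
  }

  hits <- data.frame(
    subject_id = raw$subject_id,
    collection = collection,
    method = raw$method,
    evalue = num("evalue", allow_empty = TRUE),
    probability_pct = num("probability_pct", allow_empty = TRUE),
    identity_pct = num("identity_pct"),
    q_start = as.integer(num("q_start")),
    q_end = as.integer(num("q_end")),
    s_start = as.integer(num("s_start")),
    s_end = as.integer(num("s_end")),
    q_cov_pct = num("q_cov_pct"),
    s_cov_pct = num("s_cov_pct"),
    annotation = raw$annotation,
    stringsAsFactors = FALSE
  )
  hits$go_terms <- lapply(raw$go_terms, parse_go_terms)
  hits$ec_numbers <- lapply(raw$ec_numbers, parse_ec_field)

  for (i in seq_len(n)) {
    line <- i + 1L
    if (!hits$method[i] %in% HIT_METHODS)
      stop("hits file ", path, " line ", line, ": unknown method '",
           hits$method[i], "'")
    if (!is.na(hits$evalue[i]) && hits$evalue[i] <= 0)
      stop("hits file ", path, " line ", line, ": e-value must be positive")
    if (hits$q_start[i] > hits$q_end[i] || hits$s_start[i] > hits$s_end[i])
      stop("hits file ", path, " line ", line, ": inverted alignment range")
    if (!is.null(query_length) && hits$q_end[i] > query_length)
      stop("hits file ", path, " line ", line,
           ": query range exceeds query length ", query_length)
    for (col in c("identity_pct", "q_cov_pct", "s_cov_pct", "probability_pct")) {
      v <- hits[[col]][i]
      if (!is.na(v) && (v < 0 || v > 100))
        stop("hits file ", path, " line ", line, ": ", col,
             " outside [0, 100]")
    }
  }
  hits
}

parse_go_terms <- function(field) {
  field <- trimws(field)
  if (!nzchar(field))
    return(data.frame(term = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(field, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad))
    stop("malformed GO term field: '", field, "' (expected TERM|EVIDENCE)")
  data.frame(term = vapply(parts, `[[`, "", 1L),
             evidence = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

parse_ec_field <- function(field) {
  field <- trimws(field)
  if (!nzchar(field)) return(character())
  strsplit(field, ";", fixed = TRUE)[[1]]
}

#' Write search hits to a hits TSV file
#'
#' Inverse of \code{\link{read_hits}}; absent optional values are written as
#' empty strings.
#'
#' @param hits Hits data frame as returned by \code{\link{read_hits}}.
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, scientific = NA,
                                                     trim = TRUE, digits = 15))
  out <- data.frame(
    subject_id = hits$subject_id,
    method = hits$method,
    evalue = fmt_num(hits$evalue),
    probability_pct = fmt_num(hits$probability_pct),
    identity_pct = fmt_num(hits$identity_pct),
    q_start = hits$q_start, q_end = hits$q_end,
    s_start = hits$s_start, s_end = hits$s_end,
    q_cov_pct = fmt_num(hits$q_cov_pct),
    s_cov_pct = fmt_num(hits$s_cov_pct),
    annotation = hits$annotation,
    go_terms = vapply(hits$go_terms, function(g) {
      if (!nrow(g)) "" else paste(paste(g$term, g$evidence, sep = "|"),
                                  collapse = ";")
    }, ""),
    ec_numbers = vapply(hits$ec_numbers, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GO parent-edge table
#'
#' Tab-separated with header columns \code{child_term}, \code{parent_term}.
#'
#' @param path Path to the edge file.
#' @return Data frame of child/parent term pairs.
#' @export
read_go_edges <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("child_term", "parent_term") %in% names(df)))
    stop("GO edge file must have columns child_term, parent_term")
  df[c("child_term", "parent_term")]
}

#' Write a GO parent-edge table
#' @param edges Data frame with \code{child_term}, \code{parent_term}.
#' @param path Output path.
#' @export
write_go_edges <- function(edges, path) {
  write.table(edges[c("child_term", "parent_term")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read EC evidence records
#'
#' Tab-separated with header columns \code{source} (one of \code{TRANSFER},
#' \code{EZYPRED}, \code{EFICAZ}), \code{ec}, \code{confidence} and an
#' optional trailing \code{subject_id} (the Swiss-Prot hit a TRANSFER row
#' came from). For TRANSFER rows \code{confidence} is the homolog rubric
#' total; for EFICAZ rows it is a probability in [0, 1] or the word
#' \code{LOW}; EZYPRED rows leave it empty.
#'
#' @param path Path to the evidence file.
#' @return Data frame with columns \code{source}, \code{ec},
#'   \code{confidence} (character, as given) and \code{subject_id}.
#' @export
read_ec_evidence <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE,
                   na.strings = NULL)
  if (!all(c("source", "ec", "confidence") %in% names(df)))
    stop("EC evidence file must have columns source, ec, confidence")
  if (!"subject_id" %in% names(df)) df$subject_id <- ""
  bad <- !df$source %in% c("TRANSFER", "EZYPRED", "EFICAZ")
  if (any(bad))
    stop("EC evidence file line ", which(bad)[1] + 1L,
         ": unknown source '", df$source[which(bad)[1]], "'")
  for (ec in df$ec) parse_ec(ec)  # validates
  df[c("source", "ec", "confidence", "subject_id")]
}

#' Write EC evidence records
#' @param evidence Data frame as from \code{\link{read_ec_evidence}}.
#' @param path Output path.
#' @export
write_ec_evidence <- function(evidence, path) {
  write.table(evidence[c("source", "ec", "confidence", "subject_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
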