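#' Validated query protein sequence
#'
#' Constructs a query-sequence object from an identifier and a residue
#' string. Residues must be drawn from the 20 standard amino-acid letters
#' plus \code{X} (unknown). Queries shorter than 30 or longer than 4000
#' residues are rejected: below 30 residues the downstream predictors and
#' homology searches are unreliable, and above 4000 the per-residue track
#' format becomes unwieldy.
#'
#' @param id Non-empty sequence identifier.
#' @param residues Amino-acid string (upper or lower case; coerced to upper).
#' @return An object of class \code{query_sequence} with fields \code{id},
#'   \code{residues} and \code{length}. Residue positions are 1-based
#'   inclusive everywhere in this package.
#' @export
query_sequence <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("query id must be a non-empty string")
  residues <- toupper(gsub("[ \t\r\n]", "", residues))
  bad <- gsub(paste0("[", AA_LETTERS, "]"), "", residues)
  if (nzchar(bad))
    stop("query contains non-amino-acid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = " "))
  n <- nchar(residues)
  if (n < QUERY_MIN_LENGTH)
    stop("query length ", n, " below minimum ", QUERY_MIN_LENGTH, " residues")
  if (n > QUERY_MAX_LENGTH)
    stop("query length ", n, " above maximum ", QUERY_MAX_LENGTH, " residues")
  structure(list(id = id, residues = residues, length = n),
            class = "query_sequence")
}

AA_LETTERS <- "ACDEFGHIKLMNPQRSTVWYX"
QUERY_MIN_LENGTH <- 30L
QUERY_MAX_LENGTH <- 4000L

#' Read a query sequence from FASTA or plain text
#'
#' A single-record FASTA file is read with \pkg{seqinr}; a headerless plain
#' text file (the residue string, possibly wrapped over several lines) is
#' also accepted and assigned the id \code{"query"}.
#'
#' @param path Path to the query file.
#' @return A \code{\link{query_sequence}}.
#' @export
read_query <- function(path) {
  if (!file.exists(path)) stop("query file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, ">")) {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE)
    if (length(recs) != 1L)
      stop("expected a single FASTA record, found ", length(recs))
    query_sequence(attr(recs[[1]], "name"), as.character(recs[[1]]))
  } else {
    query_sequence("query", paste(readLines(path, warn = FALSE), collapse = ""))
  }
}

#' @export
print.query_sequence <- function(x, ...) {
  cat(sprintf("<query %s: %d aa>\n", x$id, x$length))
  invisible(x)
}
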