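#' Filter homologs for the conservation profile
#'
#' Keeps the hits suitable for building a positional conservation profile:
#' query coverage above 40 percent (so the alignment spans enough of the
#' query to be informative) and identity below 90 percent (so
#' near-duplicates do not swamp the residue distribution). Both
#' inequalities are strict.
#'
#' @param hits Hits data frame (\code{\link{read_hits}}).
#' @return The rows passing the filter.
#' @export
profile_filter <- function(hits) {
  hits[hits$q_cov_pct > 40 & hits$identity_pct < 90, , drop = FALSE]
}

#' Positional conservation track from aligned homologs
#'
#' Computes a per-residue conservation index from homolog sequences
#' projected onto query coordinates. At each query position the observed
#' residue distribution (query residue included, gap characters ignored)
#' has Shannon entropy H; the conservation value is \eqn{1 - H / \ln 20},
#' which is 1 for a perfectly conserved column and 0 for a column uniform
#' over the 20 residue types. Values are binned to display digits 0-9 by
#' \code{floor(10 * value)}, with 1.0 mapping to 9.
#'
#' With no homologs every column holds the query residue alone, giving
#' zero entropy and digit 9 throughout.
#'
#' @param query A \code{\link{query_sequence}}.
#' @param aligned Character vector of homolog strings, each exactly query
#'   length, with \code{-} or \code{.} at positions the homolog does not
#'   align to.
#' @return A \code{CONSERVATION} consensus track; its \code{tallies} field
#'   holds the raw conservation values.
#' @export
conservation_track <- function(query, aligned = character()) {
  L <- query$length
  bad <- which(nchar(aligned) != L)
  if (length(bad))
    stop("aligned homolog string ", bad[1], " has ", nchar(aligned[bad[1]]),
         " characters; expected query length ", L)
  cols <- matrix(unlist(strsplit(c(query$residues, toupper(aligned)), "")),
                 nrow = length(aligned) + 1L, byrow = TRUE)
  values <- apply(cols, 2, function(col) {
    col <- col[!col %in% c("-", ".")]
    p <- table(col) / length(col)
    h <- -sum(p * log(p))
    1 - h / log(20)
  })
  values <- pmin(pmax(values, 0), 1)
  digits <- pmin(floor(10 * values), 9)
  track <- new_consensus_track("CONSERVATION",
                               paste(digits, collapse = ""),
                               matrix(values, nrow = 1,
                                      dimnames = list("value", NULL)))
  track
}
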