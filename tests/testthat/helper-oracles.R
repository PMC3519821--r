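# Independent reference implementations used as oracles. These are written
# as straight-line enumerations, deliberately sharing no code with the
# package internals.

# --- brute-force weighted voting -------------------------------------------

# tally votes for one residue position given per-track (symbol, weight)
oracle_ss3_call <- function(symbols, weights) {
  tal <- c(H = 0, E = 0, C = 0)
  for (k in seq_along(symbols))
    if (symbols[k] %in% names(tal))
      tal[symbols[k]] <- tal[symbols[k]] + weights[k]
  winners <- names(tal)[tal == max(tal)]
  if (length(winners) == 1) return(winners)
  heavy_states <- symbols[weights > 1]
  for (st in heavy_states) if (st %in% winners) return(st)
  if ("C" %in% winners) "C" else winners[1]
}

oracle_ss3_track <- function(tracks, weights) {
  L <- nchar(tracks[[1]]$symbols)
  mats <- lapply(tracks, function(t) strsplit(t$symbols, "")[[1]])
  vapply(seq_len(L), function(i)
    oracle_ss3_call(vapply(mats, `[`, "", i), weights), "")
}

oracle_binary_track <- function(tracks, weights, pos_sym, threshold) {
  L <- nchar(tracks[[1]]$symbols)
  mats <- lapply(tracks, function(t) strsplit(t$symbols, "")[[1]])
  vapply(seq_len(L), function(i) {
    v <- sum(weights[vapply(mats, `[`, "", i) == pos_sym])
    v >= threshold
  }, NA)
}

# --- step-by-step greedy template selection --------------------------------

# templates: list of lists with $id and $residues (integer vector);
# returns ids accepted when each adds >= min_new uncovered residues
oracle_greedy <- function(templates, L, min_new) {
  covered <- rep(FALSE, L)
  accepted <- character()
  for (t in templates) {
    fresh <- t$residues[t$residues <= L]
    fresh <- fresh[!covered[fresh]]
    if (length(unique(fresh)) >= min_new) {
      covered[fresh] <- TRUE
      accepted <- c(accepted, t$id)
    }
  }
  accepted
}

# --- exhaustive GO propagation ---------------------------------------------

# edges: data.frame(child_term, parent_term); direct: named numeric totals.
# For every term, the propagated total is the max direct total over the
# term itself and all terms that can reach it via parent edges.
oracle_propagate <- function(edges, direct) {
  terms <- unique(c(edges$child_term, edges$parent_term, names(direct)))
  reaches <- function(from, to) {
    seen <- from
    repeat {
      nxt <- unique(edges$parent_term[edges$child_term %in% seen])
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) return(to %in% seen)
      seen <- c(seen, nxt)
    }
  }
  out <- numeric()
  for (tm in terms) {
    sources <- names(direct)[vapply(names(direct), function(s)
      s == tm || reaches(s, tm), NA)]
    if (length(sources)) out[tm] <- max(direct[sources])
  }
  out
}

# random DAG with edges from lower-numbered child to higher-numbered parent
random_go_dag <- function(n_nodes, n_edges) {
  terms <- sprintf("GO:%07d", seq_len(n_nodes))
  pairs <- t(replicate(n_edges, sort(sample.int(n_nodes, 2))))
  data.frame(child_term = terms[pairs[, 1]], parent_term = terms[pairs[, 2]],
             stringsAsFactors = FALSE)
}

# --- shared fixture helpers ------------------------------------------------

sprot_hit <- function(subject_id = "S1", evalue = 1e-50, identity = 95,
                      q_cov = 90, s_cov = 90, q_end = 100L) {
  data.frame(subject_id = subject_id, collection = "SPROT",
             method = "BLAST", evalue = evalue, probability_pct = NA_real_,
             identity_pct = identity, q_start = 1L, q_end = q_end,
             s_start = 1L, s_end = q_end, q_cov_pct = q_cov,
             s_cov_pct = s_cov, annotation = "", stringsAsFactors = FALSE)
}

go_support <- function(subject_id, evalue = 1e-50, identity = 95,
                       q_cov = 90, s_cov = 90, evidence = "IDA") {
  data.frame(subject_id = subject_id, evalue = evalue,
             identity_pct = identity, q_cov_pct = q_cov, s_cov_pct = s_cov,
             evidence = evidence, stringsAsFactors = FALSE)
}

template_hit <- function(subject_id, method = "BLAST", evalue = NA,
                         probability = NA, identity = 50, q_start = 1L,
                         q_end = 100L) {
  data.frame(subject_id = subject_id, collection = "PDB", method = method,
             evalue = evalue, probability_pct = probability,
             identity_pct = identity, q_start = as.integer(q_start),
             q_end = as.integer(q_end), s_start = 1L,
             s_end = as.integer(q_end - q_start + 1L),
             q_cov_pct = 50, s_cov_pct = 50, annotation = "",
             stringsAsFactors = FALSE)
}

random_track_set <- function(L, n_tracks) {
  preds <- c("PSIPRED", paste0("P", seq_len(n_tracks - 1L)))
  lapply(preds, function(p)
    prediction_track(p, "SS3",
                     paste(sample(c("H", "E", "C"), L, replace = TRUE),
                           collapse = "")))
}
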