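#' @name fixtures
#' @title Deterministic synthetic prediction bundles
#'
#' @description
#' The generator plants a known truth (secondary-structure string, signal
#' peptide, transmembrane helices, disordered segments, EC number, GO
#' terms, template layout) and derives predictor tracks from it by
#' independent per-residue symbol flips at a per-predictor noise rate.
#' The default 5 percent noise reflects the typical disagreement between
#' modern per-residue predictors on globular proteins. Everything is
#' driven by an explicit seed; the same seed yields a byte-identical
#' bundle.
NULL

# assemble a hits data frame row by row (internal)
hit_rows <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      subject_id = r$subject_id, collection = r$collection,
      method = r$method,
      evalue = if (is.null(r$evalue)) NA_real_ else r$evalue,
      probability_pct = if (is.null(r$probability_pct)) NA_real_
                        else r$probability_pct,
      identity_pct = r$identity_pct,
      q_start = as.integer(r$q_start), q_end = as.integer(r$q_end),
      s_start = as.integer(r$s_start), s_end = as.integer(r$s_end),
      q_cov_pct = r$q_cov_pct, s_cov_pct = r$s_cov_pct,
      annotation = if (is.null(r$annotation)) "" else r$annotation,
      stringsAsFactors = FALSE)
  }))
  df$go_terms <- lapply(rows, function(r)
    if (is.null(r$go_terms)) parse_go_terms("") else r$go_terms)
  df$ec_numbers <- lapply(rows, function(r)
    if (is.null(r$ec_numbers)) character() else r$ec_numbers)
  df
}

segment_mask <- function(L, segments) {
  mask <- logical(L)
  for (s in segments) mask[s[1]:s[2]] <- TRUE
  mask
}

flip_binary <- function(mask, pos_sym, noise) {
  flip <- stats::runif(length(mask)) < noise
  out <- xor(mask, flip)
  paste(ifelse(out, pos_sym, "."), collapse = "")
}

flip_ss3 <- function(truth, noise) {
  chars <- strsplit(truth, "")[[1]]
  flip <- which(stats::runif(length(chars)) < noise)
  for (i in flip)
    chars[i] <- sample(setdiff(SS3_STATES, chars[i]), 1)
  paste(chars, collapse = "")
}

#' Generate a coherent synthetic prediction bundle
#'
#' @param seed Integer seed; the only source of randomness.
#' @param length Query length (30-4000), default 200.
#' @param n_sprot_hits,n_go_hits,n_templates Table sizes.
#' @param noise Per-residue symbol-flip probability applied independently
#'   to every predictor track (default 0.05).
#' @param has_signal,has_tm Whether a signal peptide / transmembrane
#'   helices are planted.
#' @return A \code{prediction_bundle}; the planted truth is in
#'   \code{attr(bundle, "planted")} (SS3 string plus logical masks for
#'   the binary features, the true EC, GO terms and template layout).
#' @export
make_bundle <- function(seed, length = 200L, n_sprot_hits = 8L,
                        n_go_hits = 6L, n_templates = 5L, noise = 0.05,
                        has_signal = TRUE, has_tm = TRUE) {
  if (length < QUERY_MIN_LENGTH || length > QUERY_MAX_LENGTH)
    stop("bundle query length must be in [", QUERY_MIN_LENGTH, ", ",
         QUERY_MAX_LENGTH, "]")
  withr::with_seed(seed, make_bundle_impl(length, n_sprot_hits, n_go_hits,
                                          n_templates, noise, has_signal,
                                          has_tm))
}

make_bundle_impl <- function(L, n_sprot, n_go, n_templates, noise,
                             has_signal, has_tm) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  residues <- paste(sample(aa20, L, replace = TRUE), collapse = "")
  query <- query_sequence("synthetic_query", residues)

  # --- planted local features ---
  sp_end <- if (has_signal) sample(18:25, 1) else 0L
  signal_mask <- segment_mask(L, if (sp_end) list(c(1L, sp_end)) else list())

  tm_segs <- list()
  if (has_tm && L >= sp_end + 80L) {
    tm_start <- sp_end + sample(30:40, 1)
    tm_segs <- list(c(tm_start, tm_start + sample(17:23, 1)))
  }
  tm_mask <- segment_mask(L, tm_segs)

  dis_len <- max(10L, round(0.08 * L))
  dis_start <- L - dis_len + 1L
  disorder_mask <- segment_mask(L, list(c(dis_start, L)))

  ss3 <- character(L)
  i <- 1L
  while (i <= L) {
    len <- min(sample(4:12, 1), L - i + 1L)
    ss3[i:(i + len - 1L)] <- sample(SS3_STATES, 1)
    i <- i + len
  }
  ss3[tm_mask] <- "H"
  ss3[disorder_mask] <- "C"
  ss3 <- paste(ss3, collapse = "")

  tracks <- c(
    lapply(c("PSIPRED", "SSPRO"), function(p)
      prediction_track(p, "SS3", flip_ss3(ss3, noise), L)),
    list(prediction_track("DISEMBL-coils", "SS3", {
      coil <- strsplit(ss3, "")[[1]] == "C"
      flip <- stats::runif(L) < noise
      paste(ifelse(xor(coil, flip), "C", "."), collapse = "")
    }, L)),
    lapply(c("DISEMBL-missing", "DISPRO", "DISOPRED", "IsUnstruct"),
           function(p) prediction_track(p, "DISORDER",
                                        flip_binary(disorder_mask, "*",
                                                    noise), L)),
    lapply(c("TMHMM", "TOPPRED", "HMMTOP", "MEMSAT", "MEMSATSVM", "Phobius"),
           function(p) prediction_track(p, "TM",
                                        flip_binary(tm_mask, "H", noise), L)),
    lapply(c("SignalP-HMM", "SignalP-NN", "MEMSATSVM", "Phobius"),
           function(p) prediction_track(p, "SIGNAL",
                                        flip_binary(signal_mask, "S",
                                                    noise), L)),
    list(prediction_track("COILS", "COIL",
                          flip_binary(logical(L), "x", noise / 5), L),
         prediction_track("SEG", "LOWCOMPLEX",
                          flip_binary(logical(L), "x", noise / 5), L))
  )

  # --- Swiss-Prot hits + reciprocal statuses ---
  true_ec <- "2.7.11.1"
  sprot <- NULL
  reciprocal <- NULL
  ec_rows <- list()
  if (n_sprot > 0) {
    rows <- lapply(seq_len(n_sprot), function(i) {
      idn <- round(stats::runif(1, 25, 99), 1)
      qc <- round(stats::runif(1, 30, 100), 1)
      sc <- round(stats::runif(1, 30, 100), 1)
      qlen <- max(1L, round(L * qc / 100))
      list(subject_id = sprintf("SPROT_%03d", i), collection = "SPROT",
           method = "BLAST", evalue = 10^(-stats::runif(1, 1, 120)),
           identity_pct = idn, q_start = 1L, q_end = qlen,
           s_start = 1L, s_end = qlen, q_cov_pct = qc, s_cov_pct = sc,
           annotation = sprintf("synthetic annotation %d", i),
           ec_numbers = if (i <= min(4L, n_sprot)) true_ec else character())
    })
    sprot <- do.call(hit_rows, rows)
    st <- c("BEST", "NOT_BEST", "UNAVAILABLE")
    reciprocal <- data.frame(
      subject_id = sprot$subject_id,
      forward = sample(st, n_sprot, replace = TRUE),
      reverse = sample(st, n_sprot, replace = TRUE),
      stringsAsFactors = FALSE)
    scores <- lapply(seq_len(n_sprot), function(i)
      score_homolog(sprot[i, ], list(forward = reciprocal$forward[i],
                                     reverse = reciprocal$reverse[i])))
    for (i in seq_len(n_sprot)) {
      if (length(sprot$ec_numbers[[i]]))
        ec_rows[[length(ec_rows) + 1L]] <- data.frame(
          source = "TRANSFER", ec = true_ec,
          confidence = as.character(scores[[i]]$total),
          subject_id = sprot$subject_id[i], stringsAsFactors = FALSE)
    }
  }
  ec_rows[[length(ec_rows) + 1L]] <- data.frame(
    source = "EZYPRED", ec = "2.7.-.-", confidence = "",
    subject_id = "", stringsAsFactors = FALSE)
  ec_rows[[length(ec_rows) + 1L]] <- data.frame(
    source = "EFICAZ", ec = true_ec,
    confidence = as.character(round(stats::runif(1, 0.6, 0.99), 2)),
    subject_id = "", stringsAsFactors = FALSE)
  ec_evidence <- do.call(rbind, ec_rows)

  # --- NR hits and aligned strings for the conservation profile ---
  n_nr <- 6L
  aa_chars <- strsplit(residues, "")[[1]]
  nr_rows <- list()
  aligned <- character(n_nr)
  for (i in seq_len(n_nr)) {
    idn <- round(stats::runif(1, 35, 95), 1)
    qs <- sample(seq_len(max(1L, L %/% 4)), 1)
    qe <- min(L, qs + round(L * stats::runif(1, 0.4, 0.9)))
    qc <- round(100 * (qe - qs + 1) / L, 1)
    mut <- aa_chars
    flip <- which(stats::runif(L) > idn / 100)
    mut[flip] <- sample(aa20, length(flip), replace = TRUE)
    mut[-(qs:qe)] <- "-"
    aligned[i] <- paste(mut, collapse = "")
    nr_rows[[i]] <- list(subject_id = sprintf("NR_%03d", i),
                         collection = "NR", method = "BLAST",
                         evalue = 10^(-stats::runif(1, 4, 60)),
                         identity_pct = idn, q_start = qs, q_end = qe,
                         s_start = 1L, s_end = qe - qs + 1L,
                         q_cov_pct = qc,
                         s_cov_pct = round(stats::runif(1, 50, 100), 1))
  }
  hits_nr <- do.call(hit_rows, nr_rows)
  alignments <- data.frame(subject_id = hits_nr$subject_id,
                           aligned = aligned, stringsAsFactors = FALSE)

  # --- GO hits and hierarchy ---
  true_go <- c("GO:0016301", "GO:0005524")
  go_edges <- data.frame(
    child_term = c("GO:0016301", "GO:0003824", "GO:0005524"),
    parent_term = c("GO:0003824", "GO:0003674", "GO:0000166"),
    stringsAsFactors = FALSE)
  hits_go <- NULL
  if (n_go > 0) {
    codes <- names(GO_EVIDENCE_POINTS)
    rows <- lapply(seq_len(n_go), function(i) {
      terms <- sample(true_go, sample(1:2, 1))
      g <- data.frame(term = terms,
                      evidence = sample(codes, length(terms),
                                        replace = TRUE),
                      stringsAsFactors = FALSE)
      qc <- round(stats::runif(1, 45, 100), 1)
      list(subject_id = sprintf("GOHIT_%03d", i), collection = "GO",
           method = "BLAST", evalue = 10^(-stats::runif(1, 4, 80)),
           identity_pct = round(stats::runif(1, 35, 98), 1),
           q_start = 1L, q_end = max(1L, round(L * qc / 100)),
           s_start = 1L, s_end = max(1L, round(L * qc / 100)),
           q_cov_pct = qc, s_cov_pct = round(stats::runif(1, 45, 100), 1),
           go_terms = g)
    })
    hits_go <- do.call(hit_rows, rows)
  }

  # --- template layout: overlapping segments walking along the query ---
  template_layout <- list()
  hits_templates <- NULL
  if (n_templates > 0) {
    rows <- list()
    span <- max(60L, L %/% max(1L, n_templates - 1L))
    pos <- 1L
    for (i in seq_len(n_templates)) {
      qs <- min(pos, max(1L, L - 40L))
      qe <- min(L, qs + span + sample(0:30, 1))
      pos <- qe - sample(10:25, 1)
      id <- sprintf("TMPL_%s", LETTERS[i])
      template_layout[[id]] <- c(qs, qe)
      methods <- sample(HIT_METHODS, sample(1:3, 1))
      for (m in methods) {
        r <- list(subject_id = id, collection = "PDB", method = m,
                  identity_pct = round(stats::runif(1, 20, 95), 1),
                  q_start = qs, q_end = qe, s_start = 1L,
                  s_end = qe - qs + 1L,
                  q_cov_pct = round(100 * (qe - qs + 1) / L, 1),
                  s_cov_pct = round(stats::runif(1, 60, 100), 1))
        if (m == "HHPRED") {
          r$probability_pct <- round(stats::runif(1, 80, 100), 2)
        } else {
          r$evalue <- 10^(-stats::runif(1, 3, 60))
        }
        rows[[length(rows) + 1L]] <- r
      }
    }
    hits_templates <- do.call(hit_rows, rows)
  }

  bundle <- structure(list(
    query = query, tracks = tracks, hits_sprot = sprot, hits_nr = hits_nr,
    alignments = alignments, hits_go = hits_go, go_edges = go_edges,
    ec_evidence = ec_evidence, hits_templates = hits_templates,
    reciprocal = reciprocal
  ), class = "prediction_bundle")
  attr(bundle, "planted") <- list(
    ss3 = ss3, signal = signal_mask, tm = tm_mask, disorder = disorder_mask,
    coil = logical(L), lowcomplex = logical(L),
    ec = true_ec, go_terms = true_go, template_layout = template_layout)
  bundle
}

#' Per-residue consensus recovery against the planted truth
#'
#' Runs the feature-consensus stage on a synthetic bundle and measures the
#' fraction of residue calls matching the planted truth, per feature and
#' pooled over all voted tracks. Pooling is the fair summary for the full
#' predictor panel: features voted by many predictors (transmembrane,
#' signal) recover almost perfectly, while the secondary-structure call
#' rests on only two committed predictors and tracks their error rate.
#'
#' @param bundle A bundle from \code{\link{make_bundle}} (must carry its
#'   \code{planted} attribute).
#' @param config A \code{\link{run_config}}.
#' @return List with \code{by_feature} (named accuracies) and
#'   \code{pooled} (residue-weighted mean over the voted features).
#' @export
consensus_recovery_accuracy <- function(bundle, config = run_config()) {
  planted <- attr(bundle, "planted")
  if (is.null(planted)) stop("bundle carries no planted truth")
  tracks <- build_consensus_tracks(bundle, config)
  get <- function(f) {
    for (t in tracks) if (t$feature == f) return(t$symbols)
    NULL
  }
  acc <- c()
  n_pos <- c()
  ss3 <- get("SS3")
  if (!is.null(ss3)) {
    acc["SS3"] <- mean(strsplit(ss3, "")[[1]] ==
                         strsplit(planted$ss3, "")[[1]])
    n_pos["SS3"] <- nchar(ss3)
  }
  binary_truth <- list(DISORDER = planted$disorder, TM = planted$tm,
                       SIGNAL = planted$signal, COIL = planted$coil,
                       LOWCOMPLEX = planted$lowcomplex)
  for (f in names(binary_truth)) {
    sym <- get(f)
    if (is.null(sym) || is.null(binary_truth[[f]])) next
    called <- strsplit(sym, "")[[1]] == POSITIVE_SYMBOL[[f]]
    acc[f] <- mean(called == binary_truth[[f]])
    n_pos[f] <- nchar(sym)
  }
  list(by_feature = acc, pooled = sum(acc * n_pos) / sum(n_pos))
}

#' Hand-built canonical worked example
#'
#' A 120-residue bundle whose every rubric outcome was computed by hand
#' from the scoring tables, stored beside the bundle so the pipeline can
#' be regression-tested field by field. The bundle exercises secondary
#' structure voting with a disagreeing predictor, the double-weight rules,
#' a signal peptide overriding a falsely called N-terminal transmembrane
#' helix, the homolog / GO / EC rubrics including consensus bonuses and
#' parent propagation, and template selection at the exact 30-residue
#' boundary.
#'
#' @return List with elements \code{bundle} and \code{expected} (named
#'   scores and selections).
#' @export
worked_example <- function() {
  L <- 120L
  residues <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 6), collapse = "")
  query <- query_sequence("worked_example", residues)

  seg <- function(segments, pos_sym, L) {
    paste(ifelse(segment_mask(L, segments), pos_sym, "."), collapse = "")
  }
  ss3_truth <- paste(c(rep("C", 20), rep("H", 30), rep("C", 10),
                       rep("E", 30), rep("C", 30)), collapse = "")
  ss3_sspro <- paste(c(rep("C", 20), rep("H", 30), rep("H", 10),
                       rep("E", 30), rep("C", 30)), collapse = "")
  coil_line <- gsub("[HE]", ".", ss3_truth)

  tracks <- list(
    prediction_track("PSIPRED", "SS3", ss3_truth, L),
    prediction_track("SSPRO", "SS3", ss3_sspro, L),
    prediction_track("DISEMBL-coils", "SS3", coil_line, L),
    prediction_track("SignalP-HMM", "SIGNAL", seg(list(c(1, 20)), "S", L), L),
    prediction_track("SignalP-NN", "SIGNAL", seg(list(c(1, 20)), "S", L), L),
    prediction_track("MEMSATSVM", "SIGNAL", seg(list(), "S", L), L),
    prediction_track("Phobius", "SIGNAL", seg(list(c(1, 18)), "S", L), L),
    prediction_track("TMHMM", "TM", seg(list(c(5, 25)), "H", L), L),
    prediction_track("TOPPRED", "TM", seg(list(c(5, 25)), "H", L), L),
    prediction_track("HMMTOP", "TM", seg(list(c(5, 25)), "H", L), L),
    prediction_track("Phobius", "TM", seg(list(c(5, 25)), "H", L), L),
    prediction_track("MEMSAT", "TM", seg(list(), "H", L), L),
    prediction_track("MEMSATSVM", "TM", seg(list(), "H", L), L),
    prediction_track("DISEMBL-missing", "DISORDER",
                     seg(list(c(100, 120)), "*", L), L),
    prediction_track("DISPRO", "DISORDER",
                     seg(list(c(60, 70), c(100, 120)), "*", L), L),
    prediction_track("DISOPRED", "DISORDER",
                     seg(list(c(100, 120)), "*", L), L),
    prediction_track("IsUnstruct", "DISORDER", seg(list(), "*", L), L),
    prediction_track("COILS", "COIL", seg(list(c(30, 40)), "x", L), L),
    prediction_track("SEG", "LOWCOMPLEX", seg(list(), "x", L), L)
  )

  sprot <- hit_rows(
    list(subject_id = "SPH1", collection = "SPROT", method = "BLAST",
         evalue = 1e-80, identity_pct = 95, q_start = 1L, q_end = 110L,
         s_start = 1L, s_end = 110L, q_cov_pct = 90, s_cov_pct = 92,
         annotation = "serine/threonine kinase", ec_numbers = "2.7.11.1"),
    list(subject_id = "SPH2", collection = "SPROT", method = "BLAST",
         evalue = 1e-30, identity_pct = 75, q_start = 1L, q_end = 84L,
         s_start = 1L, s_end = 84L, q_cov_pct = 70, s_cov_pct = 65,
         annotation = "putative kinase", ec_numbers = "2.7.11.1"),
    list(subject_id = "SPH3", collection = "SPROT", method = "BLAST",
         evalue = 1e-10, identity_pct = 45, q_start = 1L, q_end = 102L,
         s_start = 1L, s_end = 102L, q_cov_pct = 85, s_cov_pct = 50,
         annotation = "uncharacterized protein"),
    list(subject_id = "SPH4", collection = "SPROT", method = "BLAST",
         evalue = 0.01, identity_pct = 30, q_start = 1L, q_end = 36L,
         s_start = 1L, s_end = 36L, q_cov_pct = 30, s_cov_pct = 30,
         annotation = "marginal hit")
  )
  reciprocal <- data.frame(
    subject_id = c("SPH1", "SPH2", "SPH3", "SPH4"),
    forward = c("BEST", "UNAVAILABLE", "NOT_BEST", "UNAVAILABLE"),
    reverse = c("BEST", "UNAVAILABLE", "UNAVAILABLE", "UNAVAILABLE"),
    stringsAsFactors = FALSE)

  hits_go <- hit_rows(
    list(subject_id = "G1", collection = "GO", method = "BLAST",
         evalue = 1e-50, identity_pct = 90, q_start = 1L, q_end = 102L,
         s_start = 1L, s_end = 102L, q_cov_pct = 85, s_cov_pct = 85,
         go_terms = data.frame(term = "GO:0016301", evidence = "IDA",
                               stringsAsFactors = FALSE)),
    list(subject_id = "G2", collection = "GO", method = "BLAST",
         evalue = 1e-20, identity_pct = 55, q_start = 1L, q_end = 84L,
         s_start = 1L, s_end = 84L, q_cov_pct = 70, s_cov_pct = 75,
         go_terms = data.frame(term = c("GO:0016301", "GO:0005524"),
                               evidence = c("IEA", "IEA"),
                               stringsAsFactors = FALSE)),
    list(subject_id = "G3", collection = "GO", method = "BLAST",
         evalue = 1e-15, identity_pct = 35, q_start = 1L, q_end = 78L,
         s_start = 1L, s_end = 78L, q_cov_pct = 65, s_cov_pct = 62,
         go_terms = data.frame(term = "GO:0016301", evidence = "TAS",
                               stringsAsFactors = FALSE))
  )
  go_edges <- data.frame(
    child_term = c("GO:0016301", "GO:0003824", "GO:0005524"),
    parent_term = c("GO:0003824", "GO:0003674", "GO:0000166"),
    stringsAsFactors = FALSE)

  ec_evidence <- data.frame(
    source = c("TRANSFER", "TRANSFER", "EZYPRED", "EFICAZ"),
    ec = c("2.7.11.1", "2.7.11.1", "2.7.-.-", "2.7.11.1"),
    confidence = c("11", "7", "", "0.85"),
    subject_id = c("SPH1", "SPH2", "", ""),
    stringsAsFactors = FALSE)

  hits_templates <- hit_rows(
    list(subject_id = "TMPL_A", collection = "PDB", method = "BLAST",
         evalue = 1e-60, identity_pct = 85, q_start = 1L, q_end = 90L,
         s_start = 1L, s_end = 90L, q_cov_pct = 75, s_cov_pct = 90),
    list(subject_id = "TMPL_A", collection = "PDB", method = "HHPRED",
         probability_pct = 99.9, identity_pct = 85, q_start = 1L,
         q_end = 90L, s_start = 1L, s_end = 90L, q_cov_pct = 75,
         s_cov_pct = 90),
    list(subject_id = "TMPL_B", collection = "PDB", method = "HHPRED",
         probability_pct = 95, identity_pct = 40, q_start = 70L,
         q_end = 120L, s_start = 1L, s_end = 51L, q_cov_pct = 42.5,
         s_cov_pct = 100),
    list(subject_id = "TMPL_C", collection = "PDB", method = "BLAST",
         evalue = 1e-8, identity_pct = 30, q_start = 85L, q_end = 120L,
         s_start = 1L, s_end = 36L, q_cov_pct = 30, s_cov_pct = 100)
  )

  bundle <- structure(list(
    query = query, tracks = tracks, hits_sprot = sprot, hits_nr = NULL,
    alignments = NULL, hits_go = hits_go, go_edges = go_edges,
    ec_evidence = ec_evidence, hits_templates = hits_templates,
    reciprocal = reciprocal
  ), class = "prediction_bundle")

  expected <- list(
    ss3 = ss3_truth,
    signal = seg(list(c(1, 18)), "S", L),
    tm = seg(list(), "H", L),            # SP run clears the 5-25 helix
    disorder = seg(list(c(100, 120)), "*", L),
    conservation_digit = "9",            # no profile: query alone
    homolog_order = c("SPH1", "SPH2", "SPH3"),
    homolog_totals = c(SPH1 = 11, SPH2 = 7, SPH3 = 3),
    homolog_tiers = c(SPH1 = "VERY_CONFIDENT", SPH2 = "PROBABLE",
                      SPH3 = "UNASSIGNED"),
    go_order = c("GO:0003674", "GO:0003824", "GO:0016301"),
    go_totals = c("GO:0003674" = 12, "GO:0003824" = 12,
                  "GO:0016301" = 12),
    go_dropped = "GO:0005524",           # total 5, below the cut
    ec = "2.7.11.1", ec_total = 8.5, ec_tier = "VERY_CONFIDENT",
    is_enzyme = TRUE,
    template_order = c("TMPL_A", "TMPL_B"),
    template_totals = c(TMPL_A = 13, TMPL_B = 5),
    template_rejected = "TMPL_C",        # adds 0 new residues
    template_new_residues = c(90L, 30L),
    fraction_covered = 1.0
  )
  list(bundle = bundle, expected = expected)
}
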