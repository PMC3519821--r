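test_that("query validation enforces the 30-4000 residue bounds exactly", {
  aa <- function(n) paste(rep("ACDEFGHIKL", ceiling(n / 10)), collapse = "")
  expect_equal(query_sequence("q", substr(aa(30), 1, 30))$length, 30)
  expect_equal(query_sequence("q", substr(aa(4000), 1, 4000))$length, 4000)
  expect_error(query_sequence("q", substr(aa(29), 1, 29)), "minimum 30")
  expect_error(query_sequence("q", substr(aa(4001), 1, 4001)),
               "maximum 4000")
  expect_error(query_sequence("q", paste0(substr(aa(35), 1, 34), "B")),
               "non-amino-acid")
  expect_error(query_sequence("", substr(aa(35), 1, 35)), "non-empty")
})

test_that("FASTA and headerless plain-text queries are both read", {
  seq35 <- paste(rep("ACDEF", 7), collapse = "")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">myprot description here", seq35), fa)
  q <- read_query(fa)
  expect_equal(q$id, "myprot")
  expect_equal(q$length, 35)

  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(substr(seq35, 1, 20), substr(seq35, 21, 35)), txt)
  q2 <- read_query(txt)
  expect_equal(q2$id, "query")
  expect_equal(q2$residues, seq35)

  multi <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", seq35, ">b", seq35), multi)
  expect_error(read_query(multi), "single")
})

test_that("track parsing validates length and alphabet, naming the predictor", {
  q <- query_sequence("q", paste(rep("ACDEFG", 5), collapse = ""))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(list(
    prediction_track("PSIPRED", "SS3", strrep("H", 30)),
    prediction_track("SignalP-HMM", "SIGNAL",
                     paste0("SSS", strrep(".", 27)))), path)
  tracks <- read_tracks(path, q)
  expect_length(tracks, 2)
  expect_equal(tracks[[2]]$feature, "SIGNAL")
  expect_equal(substr(tracks[[2]]$symbols, 1, 4), "SSS.")

  writeLines(c("predictor\tfeature\tsymbols",
               paste("SSPRO", "SS3", strrep("H", 29), sep = "\t")), path)
  expect_error(read_tracks(path, q), "SSPRO")
  writeLines(c("predictor\tfeature\tsymbols",
               paste("SSPRO", "SS9", strrep("H", 30), sep = "\t")), path)
  expect_error(read_tracks(path, q))
  writeLines(c("predictor\tfeature\tsymbols",
               paste("SSPRO", "SS3", strrep("Z", 30), sep = "\t")), path)
  expect_error(read_tracks(path, q), "alphabet")
})

test_that("track length validation rejects exactly the mismatched lengths", {
  q <- query_sequence("q", paste(rep("ACDEFG", 10), collapse = ""))
  for (len in c(30L, 55L, 60L, 61L, 90L)) {
    sym <- strrep("H", len)
    if (len == q$length) {
      expect_silent(prediction_track("PSIPRED", "SS3", sym, q$length))
    } else {
      expect_error(prediction_track("PSIPRED", "SS3", sym, q$length),
                   "residues")
    }
  }
})

test_that("hits files round-trip including GO-term and EC list columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("subject_id", "method", "evalue", "probability_pct",
            "identity_pct", "q_start", "q_end", "s_start", "s_end",
            "q_cov_pct", "s_cov_pct", "annotation", "go_terms",
            "ec_numbers"), collapse = "\t"),
    paste(c("P12345", "BLAST", "1e-50", "", "95", "1", "100", "1", "100",
            "90", "92", "a kinase", "GO:0003924|IDA;GO:0005525|IEA",
            "2.7.11.1"), collapse = "\t"),
    paste(c("d1abc_", "HHPRED", "", "99.5", "30", "5", "80", "1", "76",
            "60", "80", "", "", ""), collapse = "\t")), path)
  hits <- read_hits(path, "SPROT")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$go_terms[[1]]$term, c("GO:0003924", "GO:0005525"))
  expect_equal(hits$go_terms[[1]]$evidence, c("IDA", "IEA"))
  expect_equal(hits$ec_numbers[[1]], "2.7.11.1")
  expect_true(is.na(hits$evalue[2]))
  expect_equal(hits$probability_pct[2], 99.5)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, out)
  again <- read_hits(out, "SPROT")
  expect_equal(again, hits)
})

test_that("malformed hit rows fail with the offending line", {
  header <- paste(c("subject_id", "method", "evalue", "probability_pct",
                    "identity_pct", "q_start", "q_end", "s_start", "s_end",
                    "q_cov_pct", "s_cov_pct", "annotation"), collapse = "\t")
  good <- paste(c("A", "BLAST", "1e-5", "", "50", "1", "50", "1", "50",
                  "50", "50", ""), collapse = "\t")
  cases <- list(
    c(evalue = "abc", msg = "non-numeric"),
    c(evalue = "1e-5", q_start = "60", msg = "inverted")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header, good,
               paste(c("B", "BLAST", "abc", "", "50", "1", "50", "1", "50",
                       "50", "50", ""), collapse = "\t")), path)
  expect_error(read_hits(path, "NR"), "line 3")
  writeLines(c(header,
               paste(c("B", "BLAST", "1e-5", "", "50", "60", "50", "1",
                       "50", "50", "50", ""), collapse = "\t")), path)
  expect_error(read_hits(path, "NR"), "inverted")
  writeLines(c(header,
               paste(c("B", "BLAST", "1e-5", "", "150", "1", "50", "1",
                       "50", "50", "50", ""), collapse = "\t")), path)
  expect_error(read_hits(path, "NR"), "\\[0, 100\\]")
})

test_that("reports round-trip through JSON and render aligned text", {
  we <- worked_example()
  report <- run_pipeline(we$bundle)
  json <- withr::local_tempfile(fileext = ".json")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_report(report, json, txt)
  back <- read_report(json)

  norm <- function(r) {
    r$metadata$created <- NULL
    r$consensus_tracks <- lapply(r$consensus_tracks, function(t)
      list(feature = t$feature, symbols = t$symbols))
    rownames(r$homologs) <- rownames(r$go_terms) <- NULL
    rownames(r$ec_numbers) <- rownames(r$templates) <- NULL
    r
  }
  expect_equal(norm(back), norm(report))

  lines <- readLines(txt)
  seq_lines <- grep("^[0-9]+-[0-9]+ ", lines, value = TRUE)
  expect_length(seq_lines, 2)  # 120 residues in 60-wide blocks
  # every track line in a block has the same width as the sequence line
  first_block <- lines[seq(which(lines == seq_lines[1]),
                           length.out = 1 + length(report$consensus_tracks))]
  expect_length(unique(nchar(first_block)), 1)
})

test_that("an empty template section renders as none detected", {
  we <- worked_example()
  we$bundle$hits_templates <- NULL
  report <- run_pipeline(we$bundle)
  expect_equal(nrow(report$templates), 0)
  txt <- render_text_summary(report)
  sec <- which(txt == "== Structure templates (non-redundant) ==")
  expect_equal(txt[sec + 1], "none detected")
})
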