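test_that("secondary-structure voting honors weights and tie rules", {
  tr <- function(p, s) prediction_track(p, "SS3", s)
  # PSIPRED's two votes beat one disagreeing single vote
  ct <- consensus_ss3(list(tr("PSIPRED", "H"), tr("SSPRO", "E")))
  expect_equal(ct$symbols, "H")
  # unanimity: tally equals total weight
  ct <- consensus_ss3(list(tr("PSIPRED", "C"), tr("SSPRO", "C"),
                           tr("OTHER", "C")))
  expect_equal(ct$symbols, "C")
  expect_equal(unname(ct$tallies["C", 1]), 4)
  # coil-only caller adds a C vote; 3 vs 1 keeps H
  ct <- consensus_ss3(list(tr("PSIPRED", "H"), tr("SSPRO", "H"),
                           tr("DISEMBL-coils", "C")))
  expect_equal(ct$symbols, "H")
  # genuine tie without PSIPRED involvement falls to C
  ct <- consensus_ss3(list(tr("A", "H"), tr("B", "C")))
  expect_equal(ct$symbols, "C")
  expect_error(consensus_ss3(list()), "SS3")
})

test_that("binary features call positives at their documented thresholds", {
  L <- 10L
  tr <- function(p, f, mask) {
    sym <- POSITIVE_SYMBOL[[f]]
    prediction_track(p, f, paste(ifelse(mask, sym, "."), collapse = ""))
  }
  pos <- function(ct) which(strsplit(ct$symbols, "")[[1]] != ".")

  # disorder: 2 of 4 single-vote predictors suffice
  m <- c(rep(TRUE, 4), rep(FALSE, 6))
  tracks <- list(tr("DISEMBL-missing", "DISORDER", m),
                 tr("DISPRO", "DISORDER", m),
                 tr("DISOPRED", "DISORDER", rep(FALSE, L)),
                 tr("IsUnstruct", "DISORDER", rep(FALSE, L)))
  expect_equal(pos(consensus_binary(tracks, "DISORDER")), 1:4)
  # one predictor alone is below the disorder threshold
  expect_equal(pos(consensus_binary(tracks[c(1, 3, 4)], "DISORDER")),
               integer())

  # signal: Phobius alone (2 votes) is below the 3-vote threshold
  sp <- list(tr("Phobius", "SIGNAL", c(rep(TRUE, 5), rep(FALSE, 5))),
             tr("SignalP-HMM", "SIGNAL", rep(FALSE, L)),
             tr("SignalP-NN", "SIGNAL", rep(FALSE, L)))
  expect_equal(pos(consensus_binary(sp, "SIGNAL")), integer())
  # Phobius plus one single-vote predictor reaches it
  sp[[2]] <- tr("SignalP-HMM", "SIGNAL", c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(pos(consensus_binary(sp, "SIGNAL")), 1:5)

  # TM: strict majority of contributing votes (2 of 3 here)
  tm <- list(tr("TMHMM", "TM", c(rep(TRUE, 6), rep(FALSE, 4))),
             tr("HMMTOP", "TM", c(rep(TRUE, 6), rep(FALSE, 4))),
             tr("MEMSAT", "TM", rep(FALSE, L)))
  expect_equal(pos(consensus_binary(tm, "TM")), 1:6)
  expect_equal(pos(consensus_binary(tm[c(1, 3)], "TM")), integer())

  # all-negative residues stay negative for any feature
  allneg <- list(tr("COILS", "COIL", rep(FALSE, L)))
  expect_equal(pos(consensus_binary(allneg, "COIL")), integer())
})

test_that("voting equals an independent brute-force tally at every residue", {
  withr::local_seed(42)
  cfg <- vote_config()
  for (rep_i in 1:50) {
    L <- sample(5:40, 1)
    n <- sample(2:5, 1)
    tracks <- random_track_set(L, n)
    weights <- vapply(tracks, function(t)
      if (t$predictor == "PSIPRED") 2 else 1, 0)
    got <- strsplit(consensus_ss3(tracks, cfg)$symbols, "")[[1]]
    expect_equal(got, oracle_ss3_track(tracks, weights))
  }
})

test_that("consensus is invariant under track order and monotone under agreement", {
  withr::local_seed(7)
  for (rep_i in 1:20) {
    L <- sample(10:30, 1)
    tracks <- random_track_set(L, 4)
    base <- consensus_ss3(tracks)
    perm <- consensus_ss3(sample(tracks))
    expect_equal(perm$symbols, base$symbols)
    # a predictor that repeats the consensus never flips any call
    agree <- prediction_track("AGREE", "SS3", base$symbols)
    expect_equal(consensus_ss3(c(tracks, list(agree)))$symbols,
                 base$symbols)
  }
})

test_that("a consensus signal peptide clears an overlapping N-terminal TM run", {
  L <- 80L
  mk <- function(f, segs) {
    mask <- rep(FALSE, L)
    for (s in segs) mask[s[1]:s[2]] <- TRUE
    sym <- POSITIVE_SYMBOL[[f]]
    metannot:::new_consensus_track(f, paste(ifelse(mask, sym, "."),
                                            collapse = ""), NULL)
  }
  # SP 1-22 overlaps TM 5-25: the TM run is cleared, a distal one kept
  res <- resolve_sp_tm(mk("SIGNAL", list(c(1, 22))),
                       mk("TM", list(c(5, 25), c(40, 60))))
  tm <- strsplit(res$tm$symbols, "")[[1]]
  expect_true(all(tm[1:30] == "."))
  expect_true(all(tm[40:60] == "H"))
  # no overlap: both kept
  res <- resolve_sp_tm(mk("SIGNAL", list(c(1, 22))),
                       mk("TM", list(c(40, 60))))
  expect_equal(res$tm$symbols, mk("TM", list(c(40, 60)))$symbols)
  # no signal peptide: TM unchanged
  res <- resolve_sp_tm(mk("SIGNAL", list()), mk("TM", list(c(5, 25))))
  expect_equal(res$tm$symbols, mk("TM", list(c(5, 25)))$symbols)
  expect_error(resolve_sp_tm(mk("SIGNAL", list()),
                             metannot:::new_consensus_track("TM", "..", NULL)),
               "length")
})

test_that("profile filter keeps >40% coverage and <90% identity, strictly", {
  hits <- rbind(sprot_hit("a", identity = 80, q_cov = 50),
                sprot_hit("b", identity = 80, q_cov = 40),
                sprot_hit("c", identity = 95, q_cov = 95),
                sprot_hit("d", identity = 90, q_cov = 50),
                sprot_hit("e", identity = 89.9, q_cov = 40.1))
  expect_equal(profile_filter(hits)$subject_id, c("a", "e"))
})

test_that("conservation is the entropy index, binned to monotone digits", {
  q30 <- query_sequence("q", strrep("A", 30))
  # identical column everywhere: zero entropy, digit 9
  ct <- conservation_track(q30, c(strrep("A", 30), strrep("A", 30)))
  expect_equal(ct$symbols, strrep("9", 30))
  # no homologs: query alone, digit 9
  expect_equal(conservation_track(q30)$symbols, strrep("9", 30))
  # column {A,A,A,G}: 1 - H/ln20 with H = -(3/4 ln 3/4 + 1/4 ln 1/4)
  ct <- conservation_track(q30, c(strrep("A", 30), strrep("A", 30),
                                  strrep("G", 30)))
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(unname(ct$tallies["value", 1]), 1 - h / log(20))
  expect_equal(substr(ct$symbols, 1, 1), "8")
  # uniform over the 20 residue types: max entropy, digit 0
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aligned <- vapply(aa20[-1], function(a) strrep(a, 30), "")
  ct <- conservation_track(q30, aligned)
  expect_equal(ct$symbols, strrep("0", 30))
  # values bounded and digits monotone in the value
  vals <- ct$tallies["value", ]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(conservation_track(q30, "AAA"), "length")
})
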