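test_that("template scoring pools hits and applies the rubric bins", {
  # profile-profile hit alone: identity 30 -> 1, probability 99.5 -> 4
  s <- score_template(template_hit("T1", "HHPRED", probability = 99.5,
                                   identity = 30))
  expect_equal(s$total, 5)
  expect_equal(s$points_evalue, 0)
  # sequence hit alone at the detection edge: only the e-value bin scores
  s <- score_template(template_hit("T2", "BLAST", evalue = 1e-3,
                                   identity = 15))
  expect_equal(s$total, 1)
  expect_equal(s$points_identity, 0)
  # all three methods: consensus bonus 2
  hits <- rbind(template_hit("T3", "BLAST", evalue = 1e-60, identity = 85),
                template_hit("T3", "RPSBLAST", evalue = 1e-20,
                             identity = 80),
                template_hit("T3", "HHPRED", probability = 99.995,
                             identity = 82))
  s <- score_template(hits)
  expect_equal(s$points_consensus, 2)
  expect_equal(s$points_identity, 4)     # best identity 85
  expect_equal(s$points_probability, 5)  # 99.995 in the top bin
  expect_equal(s$points_evalue, 4)       # 1e-60 below 1e-54
  expect_equal(s$total, 15)
  # two methods: bonus 1
  s <- score_template(hits[1:2, ])
  expect_equal(s$points_consensus, 1)
  expect_error(score_template(hits[0, ]), "no hits")
  expect_error(score_template(rbind(template_hit("A"), template_hit("B"))),
               "share")
})

test_that("rubric bins are monotone and totals never exceed 16", {
  idn <- vapply(c(10, 20, 39, 40, 59, 60, 79, 80, 89, 90, 100),
                metannot:::template_identity_points, 0L)
  expect_true(all(diff(idn) >= 0))
  expect_equal(range(idn), c(0, 5))
  prob <- vapply(c(70, 80, 84, 85, 89, 90, 98, 99, 99.9, 99.99, 100),
                 metannot:::template_probability_points, 0L)
  expect_true(all(diff(prob) >= 0))
  expect_equal(range(prob), c(0, 5))
  ev <- vapply(c(1, 1e-2, 1e-3, 1e-6, 1e-7, 1e-18, 1e-19, 1e-54, 1e-60),
               metannot:::template_evalue_points, 0L)
  expect_true(all(diff(ev) >= 0))
  expect_equal(range(ev), c(0, 4))
  expect_equal(5 + 5 + 4 + 2, 16)
  # a single template saturating every bin attains it
  hits <- rbind(template_hit("T", "BLAST", evalue = 1e-60, identity = 95),
                template_hit("T", "RPSBLAST", evalue = 1e-30,
                             identity = 90),
                template_hit("T", "HHPRED", probability = 100,
                             identity = 95))
  expect_equal(score_template(hits)$total, 16)
})

test_that("detection cuts differ by method", {
  hits <- rbind(template_hit("A", "BLAST", evalue = 1e-3),
                template_hit("B", "BLAST", evalue = 2e-3),
                template_hit("C", "RPSBLAST", evalue = 9e-3),
                template_hit("D", "RPSBLAST", evalue = 2e-2),
                template_hit("E", "HHPRED", probability = 80),
                template_hit("F", "HHPRED", probability = 79.9))
  expect_equal(template_detection_filter(hits)$subject_id,
               c("A", "C", "E"))
})

test_that("greedy selection accepts exactly the 30-new-residue boundary", {
  top <- score_template(template_hit("TOP", "BLAST", evalue = 1e-40,
                                     identity = 90, q_start = 1,
                                     q_end = 100))
  plus30 <- score_template(template_hit("P30", "BLAST", evalue = 1e-10,
                                        identity = 50, q_start = 80,
                                        q_end = 130))
  plus29 <- score_template(template_hit("P29", "BLAST", evalue = 1e-10,
                                        identity = 50, q_start = 80,
                                        q_end = 129))
  sel <- select_nonredundant(list(top, plus30), 200L)
  expect_equal(vapply(sel$selected, `[[`, "", "template_id"),
               c("TOP", "P30"))
  expect_equal(sel$new_residues, c(100L, 30L))
  sel <- select_nonredundant(list(top, plus29), 200L)
  expect_equal(vapply(sel$selected, `[[`, "", "template_id"), "TOP")
  # the first template is held to the same rule
  tiny <- score_template(template_hit("TINY", "BLAST", evalue = 1e-40,
                                      identity = 90, q_start = 1,
                                      q_end = 29))
  sel <- select_nonredundant(list(tiny), 200L)
  expect_length(sel$selected, 0)
  expect_equal(sel$fraction_covered, 0)
  expect_error(select_nonredundant(list(top), 200L, min_new = 0), "min_new")
  sel <- select_nonredundant(list(), 200L)
  expect_length(sel$selected, 0)
})

test_that("greedy selection matches an independent reference on random instances", {
  withr::local_seed(99)
  for (rep_i in 1:100) {
    L <- sample(60:300, 1)
    n <- sample(1:12, 1)
    scores <- lapply(seq_len(n), function(i) {
      qs <- sample(seq_len(max(1, L - 30)), 1)
      qe <- min(L, qs + sample(10:150, 1))
      score_template(template_hit(sprintf("T%02d", i), "BLAST",
                                  evalue = 10^(-sample(3:60, 1)),
                                  identity = sample(20:95, 1),
                                  q_start = qs, q_end = qe))
    })
    ranked <- rank_templates(scores)
    sel <- select_nonredundant(ranked, L)
    ref <- oracle_greedy(lapply(ranked, function(s)
      list(id = s$template_id,
           residues = metannot:::template_residues(s))), L, 30L)
    expect_equal(vapply(sel$selected, `[[`, "", "template_id"), ref)
    expect_true(all(sel$new_residues >= 30))
    expect_equal(sum(sel$new_residues), sum(sel$mask))
    expect_gte(sel$fraction_covered, 0)
    expect_lte(sel$fraction_covered, 1)
  }
})

test_that("coverage statistics combine templates and consensus disorder", {
  top <- score_template(template_hit("T", "BLAST", evalue = 1e-40,
                                     identity = 90, q_start = 1,
                                     q_end = 150))
  sel <- select_nonredundant(list(top), 200L)
  dis <- metannot:::new_consensus_track("DISORDER",
    paste(c(rep(".", 150), rep("*", 20), rep(".", 30)), collapse = ""), NULL)
  st <- coverage_stats(sel, dis)
  expect_equal(st$fraction_covered, 0.75)
  expect_equal(st$fraction_covered_or_disordered, 0.85)
  expect_true(st$high_coverage)
  st <- coverage_stats(sel, NULL)
  expect_equal(st$fraction_covered_or_disordered, 0.75)
  expect_false(st$high_coverage)
  full <- select_nonredundant(list(score_template(
    template_hit("T", "BLAST", evalue = 1e-40, identity = 90,
                 q_start = 1, q_end = 200))), 200L)
  st <- coverage_stats(full, NULL)
  expect_equal(st$fraction_covered, 1)
  expect_true(st$high_coverage)
  short <- metannot:::new_consensus_track("DISORDER", "..", NULL)
  expect_error(coverage_stats(sel, short), "length")
})
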