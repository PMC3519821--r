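# metannot

Consensus meta-prediction and confidence-scored annotation of protein
sequences.

## What it does

Characterizing a single unknown protein means running many independent
tools — per-residue predictors of secondary structure, disorder,
transmembrane helices and signal peptides, plus sequence and profile
searches against curated, ontology-annotated and structural databases —
and then reconciling their disagreements by hand. `metannot` is that
reconciliation layer, as an R package. Given a *prediction bundle* (the
already-computed outputs for one 30–4,000-residue query, as plain TSV
files), it produces:

* **Consensus feature tracks** — at each residue, predictors vote for
  their call; PSIPRED and Phobius carry two votes each. Binary features
  use thresholds (disorder ≥ 2 votes, signal peptide ≥ 3 of 5,
  transmembrane a strict majority), and a consensus signal peptide
  clears a falsely predicted N-terminal transmembrane helix. A
  conservation track is computed as the per-column entropy index
  1 − H/ln 20 over profile-filtered homologs, binned to digits 0–9.
* **Confidence-scored homologs** — each Swiss-Prot hit earns 0–12 points
  from its e-value (< 0.001: 1), identity (1–5), both-sides alignment
  coverage (1–2) and reciprocal-best-hit status in both directions
  (0–2 each); tiers *very confident* / *confident* / *probable* at
  ≥ 10/8/6 points.
* **GO term predictions** — candidate terms from annotated homologs score
  0–12 from hit similarity plus evidence-code points (experimental 3,
  down to electronic 1) and a consensus bonus for ≥ 3 distinct hits;
  scores propagate to parent terms (a parent gets the highest score of
  its offspring).
* **EC number predictions** — homolog transfer, a 2-level and a 4-level
  de novo predictor are combined (tiers at ≥ 7/5/3); agreement across
  depths is equality on mutually specified levels, so `1.1.1.1` agrees
  with `1.1.-.-`.
* **Structure templates** — hits from three detection routes pool into
  per-template scores (identity, probability, e-value bins plus a
  cross-method consensus bonus); ranked templates are selected greedily,
  each accepted template covering ≥ 30 residues not covered by
  higher-ranked ones, with residue-coverage statistics.

No external predictor is ever executed; a deterministic generator
(`make_bundle()`) synthesizes coherent bundles with a planted truth for
testing, and `worked_example()` is a hand-scored 120-residue regression
fixture.

## Worked example

```r
library(metannot)
we <- worked_example()
report <- run_pipeline(we$bundle)
report$homologs[, c("subject_id", "evalue", "identity_pct", "total", "tier")]
#>   subject_id evalue identity_pct total           tier
#> 1       SPH1  1e-80           95    11 VERY_CONFIDENT
#> 2       SPH2  1e-30           75     7       PROBABLE
#> 3       SPH3  1e-10           45     3     UNASSIGNED
```

SPH1 collects 1 (e-value) + 4 (identity 95% with coverage > 40%) + 2
(both coverages ≥ 80%) + 2 + 2 (reciprocal best hit both ways) = 11
points. The GO section shows the kinase-activity term at the full 12
points (base 10 from an IDA-annotated close homolog, +2 for three
distinct supporting hits) propagated to its two ancestors:

```r
report$go_terms[, c("term", "total", "tier", "propagated_from")]
#>        term total           tier propagated_from
#>  GO:0003674    12 VERY_CONFIDENT      GO:0016301
#>  GO:0003824    12 VERY_CONFIDENT      GO:0016301
#>  GO:0016301    12 VERY_CONFIDENT            <NA>

report$ec_numbers[, c("ec", "total", "tier", "sources")]
#>        ec total           tier                 sources
#>  2.7.11.1   8.5 VERY_CONFIDENT TRANSFER;EZYPRED;EFICAZ

report$templates[, c("template_id", "total", "tier", "q_ranges", "new_residues")]
#>  template_id total           tier q_ranges new_residues
#>       TMPL_A    13 VERY_CONFIDENT     1-90           90
#>       TMPL_B     5      CONFIDENT   70-120           30
```

The EC candidate sums 3 (transfer from a homolog scoring 11) + 2
(2-level predictor agrees) + 3.5 (4-level predictor agrees at confidence
0.85) = 8.5. Template `TMPL_B` is kept because it adds exactly 30 new
residues (91–120); a third template spanning 85–120 adds none and is
rejected. `write_report()` emits a loss-less `summary.json` and an
aligned plain-text summary:

```
1-60         ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWY
SS3          CCCCCCCCCCCCCCCCCCCCHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHCCCCCCCCCC
SIGNAL       SSSSSSSSSSSSSSSSSS..........................................
...
```

A thin command-line front end is installed at
`inst/scripts/metannot` (`metannot run --bundle DIR --out DIR`,
`metannot simulate --seed N --out DIR`).

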