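---
title: "Consensus meta-prediction and confidence-scored annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus meta-prediction and confidence-scored annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metannot)
```

## The problem

A biologist with a single uncharacterized protein sequence typically runs a
dozen independent tools — secondary-structure, disorder, transmembrane-helix
and signal-peptide predictors, sequence and profile searches against
curated, structural and ontology-annotated databases — and is then left to
reconcile a dozen disagreeing outputs. `metannot` implements the
integration layer of that workflow: given the already-computed outputs for
one query (a *prediction bundle*), it produces consensus per-residue
feature tracks, confidence-scored homolog, Gene Ontology (GO) and Enzyme
Commission (EC) predictions, and a ranked non-redundant set of templates
for homology modeling. It never runs an external predictor itself; a
deterministic fixture generator stands in for them so the whole decision
layer is testable in isolation.

Queries are restricted to 30–4,000 residues: shorter sequences defeat most
per-residue predictors and alignment statistics, longer ones are better
analyzed per domain. All coordinates are 1-based inclusive, matching BLAST
tabular convention.

## Consensus feature tracks

Each predictor contributes one per-residue symbol string aligned to the
query. At every position the final call is decided by weighted voting.
Most predictors carry one vote; PSIPRED (secondary structure) and Phobius
(signal peptide) carry two, reflecting their documented accuracy.

**Three-state secondary structure.** Votes are tallied for helix (H),
strand (E) and coil (C). A coil-only caller (the DISEMBL "coils" output)
participates with a C vote where it calls coil and abstains elsewhere; to
carry this, SS3-feature tracks admit `.` as an explicit no-call symbol.
On a tie the double-weighted predictor's state wins if it is among the
tied maxima; otherwise C if C is tied; otherwise the first tied state in
H, E, C order. The last clause exists only for the corner case of an H/E
tie in which C is not maximal — calling C there would report a state
without a maximal tally — and makes the call deterministic.

**Binary features.** A residue is positive when the weighted votes reach
the feature's threshold:

| feature | panel (votes) | threshold | rationale |
|---|---|---|---|
| disorder | 4 single-vote predictors | 2 | two independent predictors is the accepted support level for disorder |
| signal peptide | SignalP-HMM 1, SignalP-NN 1, MEMSATSVM 1, Phobius 2 | 3 of 5 | consensus between predictors is the main confidence indicator; Phobius plus any one other suffices |
| transmembrane helix | whatever TM tracks are present | strict majority of supplied votes | robust to missing predictors |
| coiled coil, low complexity | single predictor | 1 | pass-through |

The signal and transmembrane thresholds are this package's design
choices; no published value exists for them. Both are configurable
through `vote_config()`.

**Signal peptide vs N-terminal transmembrane helix.** The two features
are the same hydrophobic physics seen by different models, and a signal
peptide is routinely mis-called as a first TM helix. When the consensus
signal track has a positive run starting at residue 1, any consensus TM
run overlapping that run is cleared (`resolve_sp_tm()`); the signal call
wins because it is the consensus of a panel tuned for exactly this
discrimination, while the TM panel has no notion of cleavage.

**Conservation.** Homologs passing the profile filter (query coverage
strictly above 40%, identity strictly below 90%) are projected onto query
coordinates. Each column's conservation is the entropy index
$1 - H/\ln 20$, with $H$ the Shannon entropy of the observed residue
distribution (query included, gaps ignored), binned to digits 0–9 by
$\lfloor 10\,v \rfloor$ (with $v{=}1 \mapsto 9$). This is a deliberate,
openly documented substitute for profile-weighted conservation indices
such as AL2CO's: it preserves the ranking behavior that matters for
display (identical column → 9, uniform column → 0, monotone in between)
without sequence weighting or gap penalties. With no homologs the track
degenerates to the query alone — digit 9 everywhere — which is the
honest statement that no variation has been observed.

## Confidence rubrics

All function predictions are scored by additive point rubrics and
labeled by tier: `VERY_CONFIDENT` / `CONFIDENT` / `PROBABLE` at
totals ≥ 10/8/6 (homologs, GO) or ≥ 7/5/3 (EC).

**Homologs (0–12).** 1 point for BLAST e-value < 0.001; identity points
(1–5 for 30–50 / 50–70 / 70–90 / 90–99 / >99 %) provided min(query, hit
coverage) > 40%; coverage points (1 for both ≥ 60%, 2 for both ≥ 80%);
2 points per reciprocal-best-hit direction, 1 when the proteome table is
unavailable, 0 for a non-best hit. Published bin endpoints overlap
(e.g. "30% to 50%", "50% to 70%"); this package uses left-closed bins
with the top bin closed, so identity exactly 50 falls in the 50–70 bin
and exactly 99 in the 90–99 bin. The identity rows' coverage condition is
read on both sides (min of query and hit coverage), consistent with the
explicit "both query and hit" wording of the coverage criterion.

**GO terms (0–12).** Each supporting (hit, evidence) pair contributes
e-value, identity (top bin 90–100 → 4; no fifth bin) and coverage points
as above plus evidence-code points: experimental (EXP, IDA) 3;
(IPI, IMP, IGI, IEP, ISO, TAS) 2; curated/electronic (ISS, ISA, ISM,
IGC, IBA, IBD, IKR, IRD, RCA, NAS, IC, IEA) 1; unknown codes 0. A term's
base is the **maximum** over its supporting hits — max rather than sum
keeps the total inside the printed 0–12 range — plus 2 when at least
three *distinct* hits (by subject id) carry the term. Ancestors then
inherit the highest score among their descendants (`propagate_parents()`,
validated as a DAG via igraph), each propagated entry recording its
source term; propagation happens before the reporting cut at 6 points,
so a parent can be reported on the strength of a sub-threshold ancestor
structure only if some descendant itself clears the bar.

**EC numbers (tiers 7/5/3).** Candidates are pooled from homolog
transfer, a 2-level de novo predictor and a 4-level de novo predictor
with confidence. Agreement across prediction depths is equality on all
mutually specified levels (`1.1.1.1` agrees with `1.1.-.-`); exact-string
equality would make the 2-level bonus unreachable by construction. When
one candidate refines another, only the most specific representative is
scored. Points: best agreeing homolog total in [6,8) → 1, [8,10) → 2,
≥ 10 → 3; +1 for three distinct agreeing Swiss-Prot hits; +2 for 2-level
agreement; EFICAz-style confidence 2 (LOW or < 0.6), 2.5, 3, 3.5, 4 for
bands up to 0.6/0.7/0.8/0.9/1. A query is called an enzyme when any
candidate reaches the probable tier (≥ 3).

**Structure templates.** Detection cuts are method-specific: sequence
search e ≤ 1e-3, profile search e ≤ 1e-2, profile-profile probability
≥ 80%. All hits to one template pool into one score: best identity
(bins 20/40/60/80/90 → 1–5), best probability (bins 80/85/90/99/99.99 →
1–5), best e-value (printed bands overlap; implemented as the disjoint
intervals (1e-6, 1e-2] → 1, (1e-18, 1e-6] → 2, (1e-54, 1e-18] → 3,
≤ 1e-54 → 4, the only reading monotone in significance), plus 1 or 2
for detection by two or three methods. Ranked templates (total desc,
e-value asc, probability desc, id asc) are scanned greedily; a template
is kept only if it covers ≥ 30 residues not covered by higher-ranked
accepted templates. The first template is held to the same 30-residue
rule — a uniform rule, and a sub-30-residue template is uninformative
for modeling. A template's covered range may be a union of intervals
(multiple alignment segments); "new residues" is a set difference, not
an interval length. Display tiers for templates (very confident at
probability ≥ 99 or e ≤ 1e-18; confident at ≥ 90 or ≤ 1e-6) are this
package's convention, kept in one place (`template_tier`).

Coverage statistics report the fraction of residues covered by selected
templates, the fraction covered **or** consensus-disordered (disordered
residues are not expected to adopt modelable structure), and a flag for
combined coverage above 80%.

## The synthetic bundle generator

`make_bundle(seed, ...)` plants a truth — an SS3 segment string, a signal
peptide of 18–25 residues, a transmembrane helix well separated from it,
a C-terminal disordered tail of about 8% of the sequence, a true EC
number, two true GO terms inside a small hierarchy, and an overlapping
template layout walking along the query — and derives every predictor
track from it by independent per-residue symbol flips. The default flip
rate of 5% per predictor reflects typical disagreement between modern
per-residue predictors on globular proteins; the noise model is
deliberately simple (independent flips, no segment-level errors, no
predictor-specific biases), which is sufficient to exercise the voting
machinery but means passing recovery tests say nothing about correlated
predictor failure on real proteins (compositionally biased regions,
mispredicted translation starts). Hit tables, alignments and evidence
files honor all format invariants, so every generated bundle parses
through the same readers real bundles use. All randomness flows from
the explicit seed (`withr::with_seed`); the same seed gives a
byte-identical bundle.

Recovery of the planted truth is summarized by
`consensus_recovery_accuracy()`, pooled over the voted tracks
residue-by-residue. Pooling is the fair summary for this panel: features
voted by four to six predictors (disorder, transmembrane, signal)
recover nearly perfectly even at 10% noise, while the three-state
secondary-structure call rests on only two committed predictors and so
tracks the better predictor's own error rate. At 10% noise the pooled
accuracy stays above 95%; at zero noise every track equals the truth
exactly.

`worked_example()` is the complementary fixture: a hand-built 120-residue
bundle whose every rubric outcome (homolog totals 11/7/3, a GO term at
the full 12 points with propagation to two ancestors, an EC candidate at
8.5 points, template selection accepting a second template that adds
exactly 30 residues and rejecting a third that adds none) was computed by
hand from the scoring tables and is stored beside the bundle.

## Numerical and interface choices

* Problem sizes in the test suite — up to 1,000 random instances for the
  greedy-selection and voting cross-checks, DAGs of up to 30 terms for
  propagation, queries of 120–300 residues — were chosen as the smallest
  scales at which every code path (ties, boundary bins, multi-interval
  templates) is exercised.
* Half-point EC scores are kept as exact decimals; tier comparison is ≥
  on the decimal value.
* Unknown residues (X) are legal in queries and vote normally with
  whatever symbol a predictor emitted.
* Ties everywhere break deterministically (documented per operation);
  re-running a bundle reproduces the report byte-for-byte apart from the
  timestamp.
* The bundle formats are normalized TSV dialects defined by this package,
  not any predictor's native output; converters from native formats are
  out of scope. The EC evidence table carries an optional trailing
  `subject_id` column so the three-distinct-hits consensus bonus can be
  counted as specified; without it, rows count as distinct hits.
* Partial bundles are first-class: a missing optional table leaves its
  report section empty and every other section unchanged.

## Limitations

* Reciprocal-best-hit status is consumed precomputed (`reciprocal.tsv`,
  derived with `reciprocal_status()` from per-proteome hit tables); the
  package does not run the reverse searches.
* The conservation index ignores sequence weighting; dense clades of
  near-identical homologs inflate apparent conservation (mitigated, but
  not removed, by the < 90% identity profile filter).
* GO relations are collapsed to plain parent edges; is-a and part-of are
  not distinguished.
* Transmembrane topology (inside/outside loop orientation) is passed
  through from individual predictors, never voted on.
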