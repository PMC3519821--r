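Package: metannot
Title: Consensus Meta-Prediction and Confidence-Scored Annotation of Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates the outputs of many per-residue sequence predictors and
    homology searches for a single query protein into consensus local-feature
    tracks (secondary structure, disorder, transmembrane helices, signal
    peptides, coiled coils, low complexity, conservation), confidence-scored
    homolog, Gene Ontology and Enzyme Commission predictions, and a ranked
    non-redundant set of structure-modeling templates. Scoring follows
    point rubrics with confidence tiers, weighted per-residue voting with
    conflict resolution, parent propagation over the GO hierarchy, and greedy
    interval-coverage template selection. Includes a deterministic synthetic
    bundle generator so the whole pipeline is testable without running any
    external predictor.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    seqinr,
    igraph,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
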