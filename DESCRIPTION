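Package: delimitax
Title: Integrative Species Delimitation from Morphology, Climate Envelopes
    and Gene Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for integrative species delimitation in the
    spirit of recent squamate taxonomy: candidate discovery from a rooted
    gene tree (exclusivity of per-taxon haplotype clades), diagnosability of
    binary characters with one-sided Wilson binomial tolerance bounds,
    morphological gap detection with two-sided Howe normal tolerance
    intervals, climate-envelope niche models compared with Schoener's D and
    a niche identity randomization test, and a rule-based integration of
    these lines of evidence into per-pair delimitation verdicts. Includes a
    virtual-species synthetic data generator (characters, climate layers,
    occurrences, trees) so every stage is testable end to end, plus packaged
    fixtures encoding the character and measurement tables of the Liolaemus
    walkeri species complex.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
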