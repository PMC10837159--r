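Package: bloodsRNA
Title: Small RNA Expression Atlas Analysis for Purified Blood Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for small RNA sequencing of purified human
    blood components and whole blood. Resolves multi-class annotation
    candidates by an RNA-class priority hierarchy, bins rRNA- and
    Y RNA-derived fragments on their parent transcripts, collapses
    sequence-level counts to annotation labels, applies inclusion filters
    and reads-per-million normalization, performs purity- and
    embedding-based sample quality control, estimates the proportional
    contribution of each blood component to whole-blood small RNA profiles
    by per-cell RNA-content weighting, derives component expression
    profiles and overrepresented small RNAs (one-vs-rest Wilcoxon tests),
    and correlates whole-blood expression with blood cell counts. Includes
    a seeded synthetic-cohort generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
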