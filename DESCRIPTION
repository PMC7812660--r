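Package: polyporeR
Title: Occurrence-Record Pipelines for Regional Polypore Checklists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synthesising regional checklists of wood-inhabiting
    fungi (polypores) from heterogeneous occurrence records: CSV ingestion
    and validation with field-standard recoding rules (Renvall decay stages,
    woody-debris fractions, habitat keys), Chao1 species-richness estimation
    from singleton/doubleton tallies, checklist reconciliation ledgers with
    regional-extinction and turnover accounting, rule-based classification
    of regular and specialist substrate associations, and assemblage
    analysis with Bray-Curtis dissimilarity, non-metric multidimensional
    scaling (Kruskal stress-1 with monotone regression), multi-response
    permutation procedures (MRPP), UPGMA host clustering and habitat
    set-overlap counts. A seeded synthetic occurrence-record generator with
    known ground truth supports end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
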