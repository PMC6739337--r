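Package: repsig
Title: Drug Repurposing by Compound-Proteome Interaction-Signature Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Consensus-based drug repurposing from a compound-by-protein
    interaction-score matrix. Compounds are compared by the root mean squared
    deviation (RMSD) of their proteome-wide interaction signatures; for each
    indication the TopX signature neighbours of its approved drugs are pooled
    into consensus counts, from which psychoactive-enrichment statistics
    (normalized indication ranks and normalized compound ranks) are computed
    and contrasted against two Monte-Carlo randomized controls with one-sided
    Kolmogorov-Smirnov and paired t tests. Also provides thresholded
    indication-indication association networks from shared psychoactive
    predictions, scaffold-based (SMARTS substructure) classification of
    psychoactive compounds, and a synthetic-cohort generator with planted
    group structure and tunable enrichment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
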