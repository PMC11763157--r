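Package: eornet
Title: Disease-Network Recovery Scoring and Drug-Combination Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how completely a treatment restores a
    disease-perturbed transcriptome over a protein-protein interaction
    network. Builds a disease network from the intersection of a
    transcriptome gene universe with a disease reference gene list, scores
    each gene's efficiency of recovery (EoR) from sham/model/treatment fold
    changes, tabulates recovery rates and combination-specific gene sets,
    computes Bliss-independence combination indices from plate-assay
    readouts, screens differential and restored metabolites, and estimates
    taxon-metabolite Spearman associations. A synthetic-data module with
    planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
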