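Package: microdialysR
Title: Intraoperative Microdialysis Metabolomics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intraoperative microdialysis untargeted
    metabolomics of gliomas sampled across radiographically distinct regions
    (enhancing tumour, non-enhancing tumour, adjacent brain, and CSF). Reads
    catheter-annotated peak-area matrices and metabolite-set (GMT/GMX) files,
    performs within-batch median normalization and presence filtering, builds
    per-case paired fold-change ranked metabolite lists, computes weighted
    running-sum metabolite-set enrichment with permutation-based normalized
    enrichment scores and false discovery rates, runs exact paired Wilcoxon
    signed-rank differential abundance tests, produces Spearman correlation
    maps and Ward hierarchical clustering, and tests plasma-contamination
    (bloody-versus-clean CSF) enrichment. A synthetic cohort generator with
    ground truth supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite
Config/testthat/edition: 3
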