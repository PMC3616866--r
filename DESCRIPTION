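Package: fuserec
Title: Gene-Family Reconciliation and Domain Fusion/Fission Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint inference of gene duplication/loss and protein domain
    fusion/fission events in a gene family evolving along a species tree.
    Implements duplication-loss parsimony reconciliation by
    last-common-ancestor mapping, exact two-state weighted-parsimony
    reconstruction of ancestral protein architectures (fused receptor kinase
    versus split cytoplasmic kinase), categorical dating of events onto
    species-tree branches, per-branch gain/loss/fusion/fission ledgers with
    ancestor counts, and a birth-death gene-family simulator with
    ground-truth event logs for end-to-end validation. Motivated by the
    evolution of the plant S-domain receptor-like kinase (SRLK) family.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
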