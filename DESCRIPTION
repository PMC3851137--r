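Package: cagcnet
Title: Conserved Anti-Coexpression Gene Networks for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds single-species anti-coexpression networks from expression
    compendia by reciprocal bottom-percentile Pearson correlation ranking,
    intersects them across species through one-to-one orthology into conserved
    anti-coexpression gene networks, and extracts per-gene conserved
    anti-coexpressed gene clusters (CAGCs). Cluster coherence is validated by
    Fisher-exact functional enrichment against node-label-permuted null
    networks (Kolmogorov-Smirnov comparison of functional-index
    distributions). Drug targets are associated to disease phenotypes by
    testing CAGC overlap with phenotype clusters derived from a phenotype
    similarity matrix, and the predicted direction of drug effect is validated
    against drug-perturbation rank matrices with two-sided Mann-Whitney tests
    under Benjamini-Hochberg control. Includes a seeded synthetic-fixture
    generator that plants anti-correlated conserved modules, phenotype
    families and drug-responsive gene sets so the whole pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
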