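Package: orthovar
Title: Ortholog Conservation and Paralog Evidence Transfer for Gene-Family Variant Interpretation
Version: 0.1.0
Authors@R:
    person("orthovar", "maintainers", email = "orthovar@example.org", role = c("aut", "cre"))
Description: Tools to interpret human missense variants across a paralogous
    gene family using deep ortholog conservation. Computes per-codon
    synonymous/nonsynonymous substitution statistics and a quantized
    conservation score with a 21-codon sliding window from codon-aligned
    ortholog open reading frames; maps protein residues into a shared,
    zero-free domain coordinate system so clinical evidence can be
    transferred between paralogs; integrates variant tables in four
    database schemas (population allele counts, clinical significance,
    rare-disease phenotype profiles, and somatic tissue/histology);
    and applies prioritization rules including cross-paralog clinical
    co-occurrence, a CADD/selection filter, an outside-domain conserved
    context rule, and a domain enrichment statistic. Includes a seeded
    synthetic-family generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
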