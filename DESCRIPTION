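Package: redtax
Title: Genome-Resolved Taxonomy with Relative Evolutionary Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rank-normalized, genome-resolved prokaryotic taxonomy:
    quality gating of metagenome-assembled genomes (paralog-corrected
    contamination, weighted completeness, MIMAG tiers), two-stage greedy
    dereplication of genome collections into species clusters from
    MinHash-based average nucleotide identity, construction of trimmed
    concatenated marker-gene supermatrices with partition tracking, balanced
    taxon down-sampling, distance-based tree building with outgroup rooting
    and monophyly testing, and computation of relative evolutionary
    divergence (RED) with per-rank interval models that turn node depths
    into rank assignments and reclassification proposals. A bundled
    simulator generates clade-structured genome collections with planted
    species clusters, rank-labeled tree nodes, and injected incompleteness
    and contamination, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
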