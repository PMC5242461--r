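Package: gsphylo
Title: Gene-Structure-Aware Phylogenetics with Molecular Morphology Characters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-structure-aware molecular evolution studies of
    single-pass membrane protein families such as the uroplakin UPK2/3 group and
    the R3 receptor tyrosine phosphatases: exon/intron reconstruction from
    genomic versus CDS sequence with intron phase annotation, projection of
    homologous introns onto protein alignments, detection of conserved cysteine
    pairs, short conserved segments, signature motifs and furin cleavage sites,
    binary molecular-morphology (MM) character coding with partitioned NEXUS
    output, maximum parsimony (Fitch scoring, heuristic search, nonparametric
    bootstrap, consensus), a lightweight Bayesian MCMC over combined
    amino-acid + binary partitions with split-frequency convergence diagnostics,
    and a simulator of gene families with known truth (duplications,
    clade-specific domain and feature losses) for end-to-end validation.
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
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
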