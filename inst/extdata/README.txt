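Synthetic fixtures (generated with gsphylo::build_gene, fixed seed).

synthetic_upk3a_like_{genomic,cds,protein}.fa: a single synthetic gene whose
architecture mirrors the human UPK3A gene model used throughout the package
documentation: 287 residues, five introns with canonical GT/AG splice sites
and phases 1, 1, 2, 1, 2 (intron 3 is phase 2).  These are NOT the real UPK3A
sequences; they encode the same gene-structure truth for offline testing.
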