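---
title: "Gene-structure-aware phylogenetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-structure-aware phylogenetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Deep gene-family relationships are often invisible to sequence comparison
alone: after hundreds of millions of years, amino-acid identity between
paralogs can fall so low that alignments carry little signal, and DNA-level
matrices saturate entirely.  Gene *architecture* decays much more slowly.
Intron positions (measured as the CDS nucleotide offset of the splice
junction) and intron *phases* (offset mod 3: phase 0 between codons, phase 1
after the first nucleotide, phase 2 after the second) are conserved across
vast distances, and cysteine pairs that form disulfide bridges are gained and
lost as pairs.  The uroplakin UPK2/3 family and the R3 receptor tyrosine
phosphatases are the motivating case: single-pass membrane proteins whose
juxtamembrane FN3-like region shares a five-intron pattern with phases
(1, 1, 2, 1, 2), four conserved extracellular cysteines (C1--C4, with the
C3-x(n)-C4-NGPL signature behind the fourth), and a cleavable R-x-[R/K]-R
furin site, despite weak sequence similarity.

`gsphylo` turns that style of argument into a tested pipeline:

1. reconstruct exon/intron structure from genomic vs CDS sequence and
   annotate intron phases (`infer_gene_model()`, `annotate_introns()`);
2. project introns onto a protein alignment and group them into
   homologous-intron characters (`cluster_homologous_introns()`);
3. detect conserved cysteine pairs, signature motifs, conserved segments and
   furin sites (`detect_conserved_cysteines()`, `scan_motif()`,
   `conserved_segment_scan()`, `find_furin_sites()`, `find_shared_region()`);
4. code the features as binary molecular-morphology (MM) characters, `G` for
   present and `T` for absent, and build partitioned matrices
   (`code_characters()`, `build_combined_matrix()`, `write_nexus()`);
5. analyse protein, MM and combined matrices by maximum parsimony with
   bootstrap and by a lightweight Bayesian MCMC (`search_mp()`,
   `bootstrap_mp()`, `run_mcmc()`), and report clade relationships against an
   outgroup (`run_grid()`, `test_clade_relationships()`).

A simulator (`simulate_family()`) generates gene families with known truth so
that every stage can be validated end to end without any external data.

# The simulator and what it emulates

`simulation_config()` describes a family: a tree (a fixed Newick or a
birth--death tree), a protein length, a substitution rate, intron positions
with required phases, cysteine pairs, literal motifs, an optional furin site,
and clade loss events.  The default configuration is a 10-taxon family on a
fixed tree in which a four-gene UPK-like clade is sister to a PTPRQ-like gene
inside a larger PTPR-like radiation, with a distant outgroup; five introns
have phases (1, 1, 2, 1, 2); the UPK2-like pair loses intron 5 (the
cytoplasmic-tail junction) and one UPK2a-like gene loses the C3--C4 pair.

Design choices that matter, and why:

* **Feature sites are frozen.**  Implanted cysteines, motif residues and the
  furin site never mutate, so "conserved in all sequences" is exact unless a
  loss event removes the feature.  The analyses treat these features as
  binary present/absent characters; a probabilistic implant would blur the
  truth the tests need.
* **The background contains no cysteine.**  The root protein is drawn from
  the 19 non-C residues at free sites (drift can still introduce transient
  cysteines).  The configured pairs are therefore the only conserved-cysteine
  signal; without this, near-invariant background columns that happen to
  carry a root cysteine mimic conserved pairs and scramble the N-to-C
  pairing.  For the same reason the furin wildcard position excludes C.
* **Substitution model.**  Each free site is redrawn uniformly over the 20
  residues with probability `1 - exp(-branch_length)`.  The infinite-branch
  marginal is exactly uniform and the redraw count is binomial, which gives
  the tests closed-form oracles.  There is no rate heterogeneity and no
  indel process (the true alignment is the sequences themselves); both are
  out of scope, and their absence means passing tests say nothing about
  alignment error on real data.
* **Intron bodies are `GT` + {A,C,T} + `AG`.**  With no interior `G`, donor
  and acceptor dinucleotides occur only at true boundaries, so the
  maximal-exon chaining of `infer_gene_model()` is provably unique and the
  round-trip oracle (inference recovers the generating model exactly) is
  meaningful.  Real introns are not purine-free; on real data the chaining
  relies on exact CDS-genome agreement and canonical splice sites.
* **Losses are Dollo-like.**  A loss event applies instantaneously on the
  clade stem and is never regained, matching the pair-loss narrative the MM
  coding assumes.
* **Branch-length floor on random trees** (`min_branch`, default 0.15 of the
  tree height).  Unconstrained birth--death trees contain near-zero internal
  edges that no method can resolve; the floor models radiations with
  substantial stems, the regime in which recovery statements are meaningful.
* **Divergence.**  The default `substitution_rate = 2` (root-to-tip 2
  substitutions/site on the height-1 study tree) emulates the motivating
  family, whose members retain only weak sequence identity.  The recovery
  experiments on random trees use `substitution_rate = 0.6` -- moderate
  divergence, root-to-tip 0.6 -- because recovery guarantees are a statement
  about the moderate regime; at saturation even exact searches are misled by
  homoplasy a few steps short of the true tree.

# Feature detection parameters

* `detect_conserved_cysteines(min_fraction)`: a column is a
  conserved-cysteine column when at least `min_fraction` of non-gap rows
  carry `C`.  The operation's default is 0.5 (a permissive screen); the study
  pipeline uses 0.85, which keeps a pair detectable when a single lineage of
  an 8--10 taxon family has lost it (7/8 = 0.875) while excluding drift.
  Columns are numbered N to C and paired consecutively; a trailing unpaired
  cysteine is reported but not coded, because bridge cysteines move in pairs.
* `scan_motif()` grammar: dash-separated tokens; literals (`NGPL`), `x`,
  bounded runs `x(2,40)`, classes `[RK]`.  Bounded runs match lazily, so hits
  are leftmost-shortest, and hits do not overlap.  The C3-x(n)-C4-NGPL
  signature is `"C-x(2,40)-C-N-G-P-L"`.
* `find_furin_sites()` implements the minimal R-x-[R/K]-R rule; overlapping
  matches are all reported and cleavage is after the final arginine.  No
  attempt is made to reproduce trained predictors.
* `conserved_segment_scan(min_length = 4, min_identity = 0.7)`: maximal runs
  of gap-free columns whose majority residue reaches `min_identity`.  The
  thresholds are explicit configuration -- "short conserved fragment" has no
  canonical quantitative definition -- and the validation relies on
  simulator truth (implanted frozen motifs), not on a claim that these
  defaults are right for any real alignment.
* `find_shared_region()` is a full Smith--Waterman/Gotoh local aligner
  (affine gaps, default BLOSUM62 with gap open 10 / extend 1; a gap of
  length L costs open + L*extend).  Co-optimal alignments are resolved
  toward the smallest target start, then the smallest query start.
  `find_tm_helix()` is a 19-residue maximum-hydropathy window (Kyte--
  Doolittle), a convenience for reporting region boundaries only.

# Character coding and matrices

Features become binary characters coded `G` (present) / `T` (absent), with
`?` for unscored taxa; this literal nucleotide coding keeps combined
amino-acid + MM matrices valid input for standard phylogenetics programs,
and the NEXUS writer emits a protein-datatype DATA block plus `aa`/`mm`
charsets.  Column order is deterministic: cysteine pairs N to C, then intron
characters left to right along the alignment.  The six-character study
scheme is C1--C2, C3--C4 and introns 1--4; intron 5 sits beyond the
transmembrane span, outside the analysed juxtamembrane region, and is
therefore not part of the default MM partition even though the simulator
implants it and the structure stage recovers its clade-specific absence.

# Parsimony

`fitch_length()` is the Fitch intersection/union pass over site patterns
(bit masks, pattern compression), with gaps and `?` as missing data rather
than a 21st state.  Scoring a multifurcating basal node by folding children
sequentially equals rooting on one of its edges, so the unrooted length is
well defined.  `search_mp()` does stepwise random-addition (greedy best
insertion) followed by hill-climbing branch swapping; the neighbourhood is
SPR by default with NNI as the cheap option.  Full TBR is not implemented:
at the scale this package targets (8--30 taxa) SPR local optima match
broader swaps in practice, and the exhaustive-enumeration tests bound any
gap at small taxon counts.  All distinct optimal topologies found are
returned (canonical sorted-Newick deduplication).  `bootstrap_mp()`
resamples columns jointly across partitions, runs one random-addition
search per replicate (configurable), counts each replicate's bipartitions
from the strict consensus of that replicate's optima, and reports the
majority-rule consensus with percent supports.

# Bayesian layer

`pruning_loglik()` is the pruning recursion over site patterns; amino acids
use a 20-state equal-rates model by default (a user-supplied reversible
exchangeability matrix is accepted), and the MM partition uses the 2-state
Mk model.  Using a proper likelihood for the binary partition -- rather than
a parsimony pseudo-term -- keeps the joint posterior well defined; Mk is the
standard likelihood counterpart of parsimony-style coding.  Equal-rates
transition probabilities have the closed form
`P(same) = 1/k + (1 - 1/k) exp(-k t/(k-1))`, which both speeds up the chain
(the matrix product collapses to a column-sum broadcast) and provides
analytic test oracles.  Likelihoods are computed unscaled with a scaled
fallback on underflow.

`run_mcmc()` is Metropolis--Hastings over (topology, branch lengths):
uniform prior over unrooted topologies, iid exponential(mean 0.1) branch
lengths, NNI topology moves and multiplier branch-length moves (tuning
constant 2, topology:branch weights 1:3).  Both NNI swap partners are drawn
uniformly; selecting either deterministically breaks the symmetry of the
joint proposal (the reverse move can have zero probability) and measurably
biases the topology posterior -- the suite checks the chain against
Monte-Carlo marginal likelihoods on 4 taxa.  Runs are independent chains
with consecutive seeds.  `asdsf()` is the across-run (population) standard
deviation of split frequencies averaged over splits reaching a 10% floor in
at least one run; with two fully conflicting resolved 4-taxon runs each
conflicting split contributes exactly 0.5.  Burn-in (default 25%), sample
interval and the floor are conventional choices exposed in
`mcmc_config()`.

# The analysis grid and relationship reports

`run_grid()` executes the default eight cells -- MP and MP-bootstrap on
protein / MM / combined, Bayes on protein and combined -- writes one Newick
tree per cell and a manifest (config fingerprint, per-cell seeds, package
version) sufficient to re-run byte-identically.  `test_clade_relationships()`
roots at the configured outgroup and evaluates monophyly, the sister-clade
taxon set, and embeddedness, formalised as strict MRCA descent:
`embedded(A, B)` iff MRCA(A) is a strict descendant of MRCA(B).  Support
thresholds (70% bootstrap / 0.95 posterior) are reported alongside raw
values, never applied silently.

On the default synthetic family the MM-only cells are expected to be poorly
resolved: with one outgroup taxon, the six binary characters contain almost
no parsimony-informative variation, so their strict consensus is a star and
the embedding verdict fails there -- which mirrors the motivating study's own
tally, where six of the eight trees supported the embedding and the
remainder were unresolved or discordant.

# Problem sizes used by the tests

The suite and the acceptance script run entirely on simulated data at desk
scale, chosen as the smallest sizes at which each property is meaningful:
10-taxon study families with 200-residue proteins; 20 random 8-taxon
families for recovery; exhaustive topology enumeration at 5--7 taxa;
brute-force ancestral enumeration on 4-taxon fixtures; local-alignment
brute force at lengths up to 12 with an independent reference aligner at
length 50; MCMC chains of 10^4--10^5 generations with 100--200 bootstrap
replicates (the method default remains 1000).

# Limitations

* No indels, no rate heterogeneity, no codon model: simulator realism is
  deliberately limited to the structures the analyses consume.
* The exon chaining requires exact CDS-genome agreement; real data need
  pre-cleaning, and alternative splicing is out of scope.
* The alignment consumed downstream is assumed given (the simulator emits
  the true alignment); no aligner is reimplemented.
* Manual curation steps (e.g. hand-aligned intron-1 positions in the
  motivating study) have no automatic counterpart; the clustering tolerance
  (`column_tolerance`, default 0 = strict conservation) is the only knob.
* The Bayesian layer uses a fixed amino-acid model rather than averaging
  over empirical matrices, and no Metropolis coupling; convergence on hard
  posteriors must be checked via `asdsf()` and longer chains.
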