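---
title: "Recognizing chlorophototrophic Gemmatimonadetes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing chlorophototrophic Gemmatimonadetes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcfinder)
```

## The problem

Chlorophototrophic Gemmatimonadetes bacteria (CGB) carry a ~42 kb
photosynthesis gene cluster (PGC) encoding bacteriochlorophyll synthesis
(*bch* genes and the cyclase *acsF*), reaction-center proteins (*puf*),
reaction-center assembly proteins (*puh*), carotenoid synthesis (*crt*)
and regulators (*ppsR*, *aerR*). Two properties make CGB recognizable
and classifiable directly from annotated genomes and metagenome-assembled
genomes (MAGs):

1. **A diagnostic cluster architecture.** The PGC is built from the same
   six sub-clusters found in purple phototrophic Proteobacteria
   (*bchP2G*, *bchFNBHLM*, *lhaA-puhABC*, *pufBALMC*, *crtF-bchCXYZ*,
   *bchID*), but in Gemmatimonadetes the singleton *acsF* consistently
   sits between *bchFNBHLM* and *lhaA-puhABC* and *bchO* between
   *pufBALMC* and *crtF-bchCXYZ* — placements not observed in
   proteobacterial PGCs.
2. **A marker-based lifestyle signal.** Several tetrapyrrole-pathway
   enzymes exist in oxygen-dependent and oxygen-independent versions
   (*acsF*/*bchE*, *hemF*/*hemN*, *hemJ*/*hemG*). Lacking *bchE* while
   carrying the bacteriophytochrome pair *BphP*/*BphO* indicates an
   aerobic anoxygenic phototroph; carrying *bchE* indicates a
   microaerophilic one.

`pgcfinder` turns these observations into a tested pipeline: protein
family assignment, cluster chaining, architecture fingerprinting,
classification, pairwise comparison, and a synthetic-genome simulator
that provides ground truth for validation.

## Family assignment

Each protein-bearing feature is searched against a packaged reference
set (one representative protein per family) by Smith–Waterman local
alignment with BLOSUM62 and affine gaps (open 11, extend 1), the
standard protein-search parameterization. Raw scores are converted to
bit scores and E-values with the Karlin–Altschul statistics for this
parameter set ($\lambda = 0.267$, $K = 0.041$), using search space
$m \times n$ = query length × total reference length:

$$\mathrm{bits} = \frac{\lambda S - \ln K}{\ln 2},
\qquad E = mn\,2^{-\mathrm{bits}}.$$

A family call requires `E < 1e-5` **and** alignment coverage of the
reference protein `> 0.40`; both are exposed in
`search_thresholds()`. The best family per locus is chosen by bit
score, with ties broken by percent identity and then lexicographic
family name, so results are deterministic. Residues outside the scoring
alphabet are replaced by `X` (scored as a weak mismatch) with a
warning.

Coverage is measured against the *reference* length because the rule
screens for homolog completeness relative to the known gene: a query
covering 30% of AcsF is a fragment, whatever its own length.

**Split genes.** MAG assemblies fragment genes. Same-family hits on one
contig within `split_gap` (default 3 kb) whose combined coverage passes
the rule are kept and flagged `split`; adjacent same-family hits that
pass individually are flagged too. A split *acsF* therefore still
counts as present — the behaviour observed in real glacier MAGs where
*acsF* is split into two fragments yet clearly present.

The packaged reference set is a synthetic stand-in: one sequence per
family, generated once from a fixed seed with realistic lengths and
residue composition. Every simulation and test is expressed relative to
this set, so the package needs no downloads and self-search of every
reference recovers its own family at 100% identity. The consequence to
keep in mind is that absolute E-values against *real* proteins will
differ; the threshold semantics, not the reference sequences, are the
normative part, and `read_family_refs()` accepts any user-supplied
`>family|source` FASTA.

## Cluster chaining

`detect_clusters()` chains genes assigned to photosynthesis families
(categories *bch*, *puf*, *puh*, *crt*, *regulatory*) along each
contig. Two photosynthesis genes join one cluster iff their genomic gap
is at most `max_gap` (default 6 kb) **and** at most `max_intervening`
(default 5) consecutive non-photosynthesis genes separate them.
Intervening hypothetical ORFs are therefore transparent — the stretch
of unknown ORFs between the *puh* and *puf* operons does not break the
cluster — while the `min_members` floor (default 4) keeps scattered
heme-pathway or carotenoid genes from surfacing as spurious clusters.
The defaults derive from the cluster's own geometry: ~35 genes in
~42 kb implies sub-kilobase intergenic gaps, so 6 kb is generous within
a cluster yet far below the distance to any unlinked phototrophy gene.
No published chaining constants exist for this architecture; all three
parameters are exposed.

On circular contigs the chain wraps the assembly origin, so detection
is invariant to where the origin was placed — verified by rotating a
planted cluster across the origin and recovering the identical member
set.

`probe_continuity()` implements the fused-anchor logic: *acsF*, *bchO*
and *puhE* are the positionally flexible loci of the PGC, so requiring
all three inside a single candidate distinguishes complete, continuous
clusters from fragmented ones.

## Architecture fingerprint

`segment_subclusters()` collapses maximal runs of consecutive members
belonging to the same canonical sub-cluster into blocks; the anchors
(*acsF*, *bchO*, *puhE*, *ppsR*, *aerR*) and anything non-canonical
stay singleton blocks. Block orientation is the majority strand of its
members (ties: first member), which is robust to a single mis-annotated
strand inside a co-oriented operon.

A cluster read from the opposite strand is the same architecture, so
signatures are canonicalized: of the two possible readings (as-is, and
reversed with orientations flipped), the lexicographically smaller
serialization is kept. Segmentation is then invariant to a uniform
strand flip plus coordinate reversal.

The placement markers are strict positional betweenness: the *acsF*
marker is true iff the *acsF* block index lies strictly between the
indices of *bchFNBHLM* and *lhaA-puhABC* (either reading direction),
and analogously for *bchO* between *pufBALMC* and *crtF-bchCXYZ*. We
deliberately test betweenness rather than immediate adjacency: an
intervening singleton (e.g. a regulator) does not change the diagnostic
relative placement, and hypothetical ORFs never enter the block
sequence at all. Missing elements make the marker false and are listed
in the signature's `missing` field.

`compare_architectures()` scores gene-order difference as

> breakpoints (adjacent block pairs of one order not adjacent in the
> other, over shared blocks) + orientation mismatches (shared blocks) +
> blocks present in exactly one signature.

This distance is symmetric and zero exactly for identical
architectures; the triangle inequality is *not* asserted (breakpoint
distances do not guarantee it). The definition is an artifact decision
— the underlying claim is qualitative (no proteobacterial PGC shows the
same sub-cluster orientations and relative positions) — and is
validated against an exhaustive brute-force oracle on block
permutations. The packaged proteobacterial contrast architectures are
synthetic stand-ins encoding representative permuted/reoriented
variants, labelled as such; all of them sit at distance > 0 from the
Gemmatimonadetes template.

## Classification rules

- **CGB membership**: at least one *puf*, one *puh* and one *bch* gene
  (category-level; `unknown` counts as absent, a conservative
  inclusion rule).
- **Oxygen lifestyle**: aerobic-indicated iff *bchE* absent and both
  *BphP* and *BphO* present; microaerophilic-indicated iff *bchE*
  present; otherwise indeterminate. These are *indications* — the
  output is an evidence class, never a physiological claim.
- **Completeness floor**: an absence in an incomplete MAG may be an
  assembly gap. Below `completeness_floor` (default 75%), any call that
  depends on an absence is downgraded to indeterminate, and `unknown`
  cells are never evaluable as absences. The floor value is a package
  choice (the real MAGs in the packaged fixture span 67.9–90.6%
  completeness, and 75% splits trusted from untrusted absences in that
  regime); it is configurable in `oxygen_rules()`.
- **Taxonomy**: ANI ≥ 96% → same species; ANI < 95% → different
  species, with 16S identity then deciding genus membership (> 95%
  same genus, ≤ 95% new genus candidate); 16S alone uses the 95% /
  98.7% genus/species thresholds. Two open points are resolved
  conservatively: an ANI inside the 95–96% band returns *conflicting
  evidence* unless the 16S value independently corroborates same
  species (> 98.7%) — the band is quoted in the literature as a band,
  and inventing a point cut inside it would be arbitrary — and an ANI
  below 95% with no 16S value reports the most conservative rank
  change (*new species same genus*), since genus-level claims need
  16S or phylogenomic support.

## Pairwise comparison

Per-family protein identity uses global alignment with terminal gaps
trimmed: identity = matches / alignment columns × 100, internal gap
columns counting in the denominator (BLAST-style reporting; the
convention matters and is stated because published identity figures do
not specify it). The high-identity flag is strict: identity must
*exceed* 90%, so exactly 90.0 is not flagged.

Nucleotide synteny blocks are found by exact 11-mer anchoring grouped
by diagonal, chained (anchors within 200 bp), extended outward by exact
match, and scored by per-base identity; inverted matches are searched
on the reverse complement. Overlaps on the first sequence are resolved
greedily in favour of the higher identity × length product. Both
reporting dialects use strict cutoffs: *pgc* (identity > 70%, length >
500 bp) for cluster-scale comparison, *genome* (identity > 80%, length
> 2 kb) for genome-scale comparison. The anchoring approach is
deterministic and adequate at desk scale; it models substitutions, not
indels — a block interrupted by an indel surfaces as two blocks, which
is acceptable for the package's substitution-only simulations and
conservative (never inflates block lengths) on real data.

## The simulator and what passing tests mean

`simulate_genome()` emulates the statistical structure the analysis
assumes:

- the template architecture with sub-kilobase intergenic gaps
  (default 50–500 bp, matching a ~42 kb / ~35 gene cluster);
- planted proteins mutated to a target identity by sampling
  BLOSUM62-positive exchanges at `round((1 - t) L)` distinct positions —
  realized identity is within rounding of the target, and no indels are
  introduced by default so closed-form identity oracles stay exact;
- coding sequences back-translated with the bacterial genetic code
  (table 11) under uniform synonymous codon choice;
- hypothetical ORFs between the *puh* and *puf* operons and random
  background ORFs (200–1500 codons) rejection-sampled to be
  non-significant against the reference set;
- standalone oxygen-marker genes (default *BphP* + *BphO*, the aerobic
  profile of the Greenland isolate) planted outside the cluster;
- optional circularity, in-place gene splitting, and MAG-style
  fragmentation.

`fragment_to_mag()` cuts the genome at uniform random breakpoints and
retains each piece independently with probability equal to the target
completeness. Independent retention is chosen deliberately over
"drop pieces until the retained fraction reaches the target": the
sequential variant conditions retention on the running total and biases
the retained fraction, whereas Bernoulli retention makes the
retained-gene fraction an exactly unbiased estimator of completeness
(a gene counts as retained when at least half its length survives).
Across 200 replicate fragmentations at completeness 0.8 the mean
retained-gene fraction stays within the 95% binomial interval of the
target, with observed bias ~0.01.

What the simulator does **not** model — indels, codon usage bias, real
paralogy and domain sharing between families (e.g. *bchL*/*bchX*, which
are true homologs in nature but independent sequences in the synthetic
reference set), annotation errors, sequencing error, compositional
heterogeneity — bounds what a passing suite shows: the pipeline's
logic, thresholds, coordinate handling and determinism are validated;
discrimination between genuinely homologous families on real data
inherits BLAST-equivalent behaviour from the threshold semantics but is
not separately demonstrated here.

## Numerical choices and validation sizes

- Alignment engine scores are checked for exact equality against an
  independently written full-matrix dynamic-programming reference
  (`sw_score_reference`, compiled code) on 100 random pairs up to 500
  residues.
- Architecture distances are checked against an exhaustive brute-force
  oracle on all 24 permutations of four shared blocks, plus orientation
  and content variants.
- Parameter recovery runs 50 simulated genomes at target identity 0.75
  (≥ 95% planted-family recovery, exactly one cluster, both markers
  true) and 200 fragmentation replicates at completeness 0.8. These
  sizes give stable pass/fail behaviour at desk scale and are the
  package's own validation choices.
- Ties everywhere break deterministically (bit score → identity →
  family name; majority strand → first member; canonical serialization
  order), so identical inputs give byte-identical reports.

## Limitations

- The rule engine consumes ANI / 16S identity values; it does not
  compute them (use FastANI or similar upstream).
- Fragmented PGCs spread over several MAG contigs are reported as
  separate candidates; the package does not scaffold them, and
  continuity is then false unless all three anchors co-occur on one
  contig.
- The oxygen-lifestyle output is an indication based on two species'
  genomic contrast; it is not a growth-physiology prediction.
- Phylogenetics (gene trees, phylogenomic placement) is out of scope.
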