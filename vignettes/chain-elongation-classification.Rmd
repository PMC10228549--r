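---
title: "Classifying MAGs into chain-elongation functional groups"
author: "magce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying MAGs into chain-elongation functional groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Mixed anaerobic communities fed carbohydrate-rich agroindustrial residues
can accumulate medium-chain fatty acids (MCFAs).  A useful ecological
model partitions the genomes recovered from such reactors
(metagenome-assembled genomes, MAGs) into functional guilds: *Ferment to
Intermediates* (FTI) organisms convert carbohydrates to lactic acid or
ethanol; *Intermediate Chain Elongators* (ICE) elongate those
intermediates to MCFAs through reverse β-oxidation; *Carbohydrate Chain
Elongators* (CCE) elongate directly from carbohydrates; everything else
is *uninvolved*.  `magce` infers these roles from genome sequence alone,
using the presence of enzyme homologs in five diagnostic pathways:
homolactic fermentation, the heterolactic phosphoketolase pathway, the
bifid shunt, lactic acid utilization (LAU: the electron-confurcating
lactate dehydrogenase ecLDH with the electron-transfer flavoprotein
subunits EtfA/EtfB) and reverse β-oxidation (rBOX: including the
acetyl-CoA C-acetyltransferase and the electron-bifurcating acyl-CoA
dehydrogenase).

The central assumption is that pathway *presence* — not expression — is
informative: a genome carrying most of the rBOX roster but little
carbohydrate-fermentation machinery is a plausible chain elongator.  The
package therefore reduces each genome to a pathway-completeness profile
and classifies on that.

## Translated homology search

Each enzyme query (protein) is searched against all six reading frames of
every contig, emulating a translated nucleotide search:

1. frames +1..+3 come from the forward strand, −1..−3 from the reverse
   complement; stop codons are kept as `*` (scored −4 against every
   residue by BLOSUM62), codons containing `N` become `X`;
2. exact 4-mer words shared by query and frame seed candidate regions,
   which are extended without gaps under an x-drop of 20; regions whose
   ungapped score reaches `ungapped_min` (default 50) are passed on;
3. an exact affine-gap Smith–Waterman (gap of length L costs
   11 + L·1) is run in a window around each seeded region, so every
   reported score is the true local optimum for that window — the test
   suite checks equality with an independent dynamic-programming oracle
   on random and planted instances;
4. raw scores become bit scores through the gapped Karlin–Altschul
   parameters λ = 0.267, K = 0.041 (the published constants for BLOSUM62
   with 11/1 gaps), and `E = m·n·2^(−bits)` uses the uncorrected product
   of query length and total translated database length.

A hit survives only if `E < 10⁻¹⁰`, percent identity > 25 and query
coverage > 70 — generous thresholds chosen for presence/absence calling,
which is all the downstream analysis consumes.  At most one hit per
(query, genome) is kept, the highest bit score.  The `ungapped_min`
prefilter deserves a note: an alignment able to pass the E-value
threshold needs a raw score around 140 or more, and with substitutions
spread along a full-length gene its best ungapped stretch scores far
above 50, so the prefilter prunes random seed noise without touching
detectable homologs.  Low-complexity masking is not implemented; the
synthetic genomes contain no low-complexity sequence, and on real data
the three filters remove most of what masking would.

## Pathway profiles and the band rule

A profile holds, per pathway, the percent of its enzyme roster detected,
plus per-enzyme presence bits and the same percentage restricted to
pathway-*unique* enzymes (enzymes occurring in exactly one roster; the
phosphoketolase `xpk`, shared by the two heterolactic pathways, is the
deliberate counter-example).  The rule classifier applies bands — high
means ≥ 60% of a roster, low means ≤ 40% — in a fixed order, first match
wins: FTI when any carbohydrate-fermentation pathway is high and both LAU
and rBOX are low; ICE when both heterolactic pathways are low and LAU and
rBOX are high; CCE when additionally LAU is low; otherwise uninvolved.
The 60/40 bands are the only quantitative anchors available for
"high/low" detection language and are exposed in `rule_thresholds()`.
Classification is applied per genome directly; the dendrogram from
`hierarchical_cluster()` (Euclidean distance, complete linkage — the
defaults of the common heatmap tooling) remains available for the
cluster-then-label workflow.

## The trained classifier

`train_classifier()` fits any algorithm satisfying a small contract
(fit on features/labels, predict class probabilities).  The in-package
default is multinomial softmax regression with an L2 penalty
(λ = 10⁻⁴) trained by full-batch gradient descent from zero
initialisation — deterministic by construction; the seed only shuffles
cross-validation folds.  Gradient boosting or any other library can be
plugged in through the same contract (`algorithm = "multinom"` wires up
`nnet::multinom` as an example).  The report carries stratified
cross-validated log loss (natural log, probabilities clipped at 10⁻¹⁵),
the class-frequency baseline on the same folds, the percent improvement,
and per-class average precision and one-vs-rest ROC AUC from out-of-fold
predictions.  Features are the five pathway percentages plus the
per-enzyme bits; both granularities are included because either encoding
alone discards information the other keeps.

## Dereplication

Genome redundancy is removed with a Mash-style sketch: canonical 16-mer
hashes, bottom-5000 sketch, Jaccard index j converted by
`ANI = 1 + ln(2j/(1+j))/k` and clamped to [0, 1]; fewer than three shared
sketch hashes reports the "unrelated" sentinel 0.  Genomes are ranked by
`score = completeness − 0.5·contamination + 5·log10(N50)` (weights
configurable, size term available) and clustered greedily: each genome
joins the first representative within the 99% ANI threshold, else founds
a cluster.  Representatives are therefore the best-scoring member of
each cluster and the representative set is independent of input order.
This single-phase greedy scheme matches a full pairwise clustering when
clusters are well separated — true of near-clone redundancy, which is
the case dereplication addresses — and is a documented simplification
otherwise (no strain-heterogeneity term, no secondary alignment-based
ANI phase).

## Community analysis

Relative abundances are percentages per sample; each sample also carries
an "unmapped" residual so MAG fractions plus residual total 100.
Presence means abundance strictly above 0 in at least one sample of an
experiment; the high-abundance set contains genomes reaching at least 1%
in at least one sample anywhere.  Bray–Curtis dissimilarities (via
`vegan::vegdist`) feed an in-package NMDS: initial configuration from
classical scaling, then alternating isotonic regression (`stats::isoreg`
on the observed dissimilarity order) and Guttman/SMACOF updates,
minimising Kruskal stress-1.  An update is accepted only if stress
decreases, so the per-restart stress trajectory is non-increasing by
construction; random restarts perturb the initial configuration and the
best restart is reported.  PerMANOVA uses the squared-distance
decomposition `pseudo-F = ((SS_T − SS_W)/(a−1)) / (SS_W/(N−a))` with
unrestricted label permutations and
`p = (1 + #{F_perm ≥ F_obs})/(1 + n_perm)`; the implementation is
cross-checked against `vegan::adonis2` in the tests.  Pairwise tests are
Benjamini–Hochberg adjusted via `stats::p.adjust`.  By convention the
ordination runs on Bray–Curtis while the omnibus/pairwise tests in the
pipeline run on Euclidean distances of the abundance profiles — the two
stages follow the conventions of the analyses they emulate, and both
distances are available to either function.

## EtfB function assignment

EtfAB complexes partner either with ecLDH (lactic acid utilization) or
with the acyl-CoA dehydrogenase (chain elongation), and the β-subunit
separates the two.  `find_etfb_homologs()` searches labeled reference
EtfB sequences against a genome (same filters as the main search),
keeping every locus and merging overlapping hits (longest alignment
wins).  `assign_label()` computes ends-free pairwise alignment identity
distances (1 − identity, identity normalised by the shorter sequence so a
short spurious overlap cannot masquerade as a close homolog) to every
reference and assigns the nearest label only when the gap to the other
label's best distance reaches `margin_min` (default 0.10); otherwise the
call is "other", mirroring the unresolved leaves of a reference
phylogeny.  This nearest-reference-with-margin scheme is a deliberate,
documented simplification of a maximum-likelihood tree with bootstrap
support: it reproduces the three-way outcome (LAU / ACD / unclear) at
desk scale and is testable.

## What the synthetic data emulates — and what it does not

`sim_config()` defaults define the study conditions: genomes of four
50 kb contigs; embedded genes reverse-translated with uniform-random
synonymous codons (standard genetic code; codon bias is irrelevant to
amino-acid-level search) and mutated at the amino-acid level to target
identities {0.95, 0.85, 0.75} (re-encoded to codons, so the *protein*
identity is controlled exactly, while clone divergence is applied at the
nucleotide level — each stage is perturbed on the scale its detector
measures); quality metrics uniform on completeness 75–100% and
contamination 0–7.5%, the bounds typical of curated MAG sets; group
content by construction — assigned pathways embed their full roster,
non-assigned pathways contribute at most one enzyme each with
probability 1/2; chain-elongating genomes carry the ACD-associated EtfB
so the Fig-10-style repertoire (ICE: both copies, CCE: ACD only) holds by
construction.  Abundance matrices draw each experiment a sparse base
composition and each sample a Dirichlet deviate around it
(concentration 60), with an unmapped residual uniform on 5–35% —
chosen so represented totals span the range seen in real reactor
summaries.

Passing tests on these data show the *machinery* is correct: filters,
scores, coordinates, clustering, calibration.  They do not show that
real MAGs are this separable.  Real genomes have shared ancestry,
paralogs, fragmented assemblies, contamination from other taxa and
low-complexity sequence; pathway completeness in real data is graded,
not near-binary.  The 100% rule recovery and ~100% ML accuracy on
synthetic cohorts are therefore consistency checks (the generator and
the classifier agree on the group definitions), not accuracy estimates
for real communities.

## Numerical choices and degenerate inputs

Ties in the aligner resolve to the first optimum in row-major order
(smallest query end, then subject end).  `isoreg` handles the isotonic
fit including ties in the observed dissimilarities.  NMDS on an all-zero
distance matrix returns a zero configuration with zero stress; a
non-symmetric matrix or negative entries are errors.  PerMANOVA requires
at least two groups with at least two samples each; its p-value floor is
1/(n_perm + 1).  Probabilities entering log loss are clipped to
[10⁻¹⁵, 1 − 10⁻¹⁵].  Genomes shorter than the sketch k-mer are an error;
sketch Jaccard below three shared hashes reports ANI 0.  The FASTA
reader upper-cases sequences, tolerates wrapped lines and CRLF, and
refuses duplicate ids or invalid characters with the offending line
number.

## Problem sizes

The test suite validates the aligner on 200 random pairs plus planted
six-frame instances, homolog recovery on 100 plantings per identity
level, dereplication on the 240-genome/23-clone fixture, rule recovery
on 20 cohorts of 40 study-scale genomes (800 searches), classifier
generalisation across independent 40-genome cohorts, PerMANOVA
calibration on 1000 null simulations at 999 permutations, and pipeline
byte-reproducibility at the default configuration.  The acceptance
script reruns the same computations at moderately reduced replication
(50 plantings per level, five rule-recovery cohorts) so a complete
from-scratch reproduction stays in the low minutes on one CPU.

## Known limitations

* The search omits composition-based statistics, effective-length
  corrections and low-complexity masking; E-values are conventional, not
  BLAST-identical.  Presence calls at the stated thresholds are robust
  to this; borderline hits near the filter boundaries are not.
* Greedy dereplication can differ from full pairwise clustering when
  genuine ANI chains straddle the threshold.
* The EtfB assignment is a distance heuristic; it cannot represent
  paraphyly among references the way a tree would.
* The ethanol-based chain-elongation route is not modelled as a separate
  group: too few isolated reference organisms exist to anchor a training
  class, so those genomes fall where their pathway content puts them.
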