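---
title: "Methods: chemoreceptor repertoire dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemoreceptor repertoire dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemrep)
```

# Scope

Polyphagous moths carry unusually large gustatory-receptor (GR)
repertoires -- hundreds of genes, mostly in tandem clusters of "bitter"
receptor clades -- and the interesting questions about them are
procedural: how to annotate such a family exhaustively, whether mobile
elements congregate around the clusters, how the repertoire grew and
shrank along the species tree, and whether any of it is under positive
selection. `chemrep` implements that four-stage analysis as reusable,
tested components, together with synthetic-data generators so every stage
can be exercised and calibrated without any external download.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, what the generators do and do not
emulate, and the known limitations. It states no empirical result that
the test suite does not itself compute.

# Coordinates and interval algebra

All internal coordinates are 0-based half-open on named scaffolds; GFF3
(1-based closed) and BED (0-based half-open) are converted at the I/O
boundary. Overlap means at least one shared base on the same scaffold,
strand-agnostic. `merge_intervals()` also merges *touching* intervals:
two flanked gene windows that abut belong to one cluster region, and the
convention is fixed so region counts are reproducible. Flanked windows
are clipped at `[0, scaffold_length)`; whether the original study clipped
at scaffold ends is unstated, so clipping is our documented choice.

# Iterative annotation

The translated homology search is deliberately an *exact* Smith-Waterman
over all six reading frames (BLOSUM62, gap open 11 / extend 1) rather
than a seeded heuristic: at desk scale determinism beats speed, and an
exact search can be checked against an independent dynamic-programming
oracle. The raw-score threshold (`min_score`, default 60) plays the role
of an e-value cutoff. Additional HSPs per frame are recovered by masking
each reported alignment and re-searching.

HSPs from one query, scaffold and strand are chained when collinear in
both query and genome with genomic gaps at most `max_intron` (default
50,000 bp, the standard noctuid RNA-mapping bound). Chains maximize
summed HSP score; chaining is exact and oracle-checked by subset
enumeration. Splice-site dinucleotides are *not* enforced -- gene models
here are homology chains, not spliced predictions.

`iterate_annotation()` runs search -> chain -> accept, then feeds the
proteins of newly accepted loci back as queries until a whole round adds
nothing. Two models claiming one locus (reciprocal overlap > 50% of the
shorter span) resolve to the higher score; how the original curators
resolved such conflicts is unstated, so the threshold is our convention,
chosen and documented for reproducibility. Loci never overlap accepted
loci, so the repertoire grows monotonically and the loop terminates.

# Curation rules

* **Alleles**: two annotated proteins at >= 90% global-alignment identity
  (identical positions over non-gap-pair columns) are alleles of one
  gene; clusters form by single linkage, because each new sequence is
  compared against all annotated ones; only the longest member keeps its
  category, ties broken by smallest identifier for determinism.
* **Pseudogenes**: any internal stop codon.
* **Complete**: start codon, terminal stop, and protein strictly longer
  than 350 aa; otherwise **partial**.
* **Motif**: the GR transmembrane-domain-7 signature `TYhhhhhQF` is
  searched in the C-terminal 100 aa (TM7 is C-terminal); `h` is the
  Kyte-Doolittle-positive set plus aromatics `{A,V,L,I,M,F,W,C,Y}`. A
  miss flags a model for inspection; it never rejects one.

Summary tables report per-category counts, the annotated total, the
"final" repertoire (total minus pseudogenes and alleles), integer
percentages of the total, and per-clade counts with their share of
complete+partial genes at one decimal. Two cells of the published
originals of these tables are known to be internally inconsistent with
their own margins; the arithmetic here is the definition, so those cells
are not reproduced.

# TE enrichment

The counting units are the merged universe regions (every annotated gene
widened by `flank = 10,000` bp and merged); a universe region is a query
region when it intersects any merged window around the gene family of
interest. Each TE consensus family yields one 2x2 table (query x
overlaps-family, overlap = 1 bp or more, no TE length filter) tested by a
one-sided (greater) Fisher's exact test -- the enrichment direction is
the question, although the original analysis does not state sidedness.
FDR correction is Benjamini-Hochberg below 100 tests and Storey's
estimator (lambda = 0.5) above, since Storey's pi0 needs many tests to be
stable.

**Calibration geometry.** Region-based overlap counting has a structural
confounder: merged regions vary in width, and query regions are
size-biased (a wider region is more likely to contain a gene of the
family of interest), so under a factor-1 null the test is anti-
conservative in heterogeneous geometries. The type-I calibration in the
acceptance suite therefore uses an exchangeable world designed *a
priori*: single-gene loci of identical footprint, placed with a minimum
separation larger than twice the flank so windows never merge
(`min_gene_separation = 21,000`), with universe/query/overlap sizes
(about 1,500 regions, 150 query, per-region hit probability near 0.4)
chosen from an exact pre-computation of the discrete test's achievable
size, which plateaus just above 0.04 -- as close to the nominal 0.05 as
Fisher's exact test permits. The power run keeps the realistic
three-gene clusters, where a 10x local intensity dwarfs the size bias.
Real analyses on real annotations inherit the size-bias caveat, as does
any region-based overlap analysis.

# Reconciliation

Gene trees are mapped onto the species tree by standard LCA parsimony:
leaves map through a user-supplied prefix map, internal nodes to the LCA
of their children's images; a node duplicating is one that maps with a
child; losses are the speciations a lineage passes without leaving a
surviving sibling copy. Input trees must be rooted and binary --
rearrangement of weakly supported edges is a distinct algorithm and is
out of scope; gene trees are taken as correct.

Reported per species branch: **gains** are duplications mapped to the
node the branch leads into (root duplications ride a stem branch);
**losses** as above; **ancestral counts** are lineages present at a node
*after* duplications at that node. Under these conventions the
conservation identity `count(child) = count(parent) + gains - losses`
holds on every branch and leaf counts equal observed repertoire sizes;
both are tested, and the duplication+loss cost is verified exhaustively
against a minimum over all consistent mappings. When the gene-tree root
maps below the species root, the origination path implies losses that are
reported in the branch table (so counts stay conserved) but -- following
the usual parsimony convention -- are not part of `dl_cost`.

# Selection screen

The codon machinery is Goldman-Yang: rates between sense codons differing
at one nucleotide are `pi_j * kappa^[transition] * omega^[nonsynonymous]`,
with F3x4 frequencies estimated from the alignment by default and
branch lengths in expected substitutions per codon site under the site-
class mixture (classes share one scale so the mixture has unit rate).
Likelihoods use Felsenstein pruning over the 61 sense codons (C++ via
RcppArmadillo, eigendecomposition of the reversible generator shared
across site classes); gaps are missing data; pruning is verified against
direct summation over internal-node states.

Models: **M0** (single omega; kappa, omega and all branch lengths free);
**M8/M8a** (beta-distributed omega in 10 equal-probability classes at
quantile midpoints, plus a free class `omega_s >= 1`, fixed at 1 under
M8a); **branch-site model A** and its `omega_2 = 1` null on a designated
foreground branch. For the mixture models, branch lengths are
re-optimized as a common scale on the M0 estimates rather than edge by
edge: at desk scale the M0 tree is accurate, the scale absorbs the
rate-convention difference between models, and nesting (the alternative
contains its null) is preserved exactly, which the tests rely on. The
optimizer is box-constrained quasi-Newton (`nlminb`) on log/logit-
transformed parameters, relative tolerance 1e-8, with M8 warm-started
from the M8a optimum (and the alternative from its null), which both
speeds convergence and enforces `lnL_alt >= lnL_null` structurally.
Deterministically jittered restarts are available (`restarts =`) but
default to 0: the warm-start chain makes them redundant in the simulated
regimes, and the calibration suites are runtime-bound.

Both LRTs use a plain chi-square with df = 1, conservative relative to
the 50:50 boundary mixture; site identification under the branch-site
alternative is a naive empirical-Bayes posterior above 0.95 for the
positively selected classes (BEB is not implemented; the magnitude of
"a few sites per gene" is the check, not the method).

`run_cascade()` encodes the screen's gates: the M8-vs-M8a comparison runs
only when the M0 omega exceeds 0.3; branch-site tests on all terminal
branches run only when that comparison is significant at 0.05; q-values
are computed across the branches *within* each clade (whether the
original pooled across clades is unstated; within-clade is the
conservative reading); branches with q < 0.05 are reported with their
sites. Every skipped stage records the gate value that caused the skip,
so the report is auditable.

# Synthetic worlds

`simulate_genome()` plants tandem clusters of receptor genes (paralogs of
a cluster ancestor at 0.3 aa substitutions/site -- far enough apart that
the 90% allele band cannot confuse paralogs), allelic copies at 95%
identity (slightly shortened so the retained copy is unambiguous),
internal-stop pseudogenes (rate 0.05), and scaffold-boundary truncations
(rate 0.1) produced by genuinely cutting the scaffold mid-gene. Defaults
(40 scaffolds x 500 kb, 30 clusters of 3, 470 background genes, TE
families at 0.015 copies/kb) give realistic *proportions* -- about 10%
of genic regions belong to the receptor family -- at desk scale. TE
placement is a piecewise-constant Poisson process: background intensity
times an enrichment factor inside the cluster-flank windows. TEs are
intervals with family and order labels only; sequence content of repeats
is deliberately not emulated, so a green enrichment test establishes the
counting and testing machinery, not repeat detection.

`simulate_gene_family()` runs a per-lineage birth-death process along the
species tree (duplication rate lambda, loss rate mu), returns the pruned
surviving gene tree and the exact per-branch event truth; all-extinct (or
single-survivor) replicates are resampled with an incremented seed and
the resample count is reported. `simulate_codon_alignment()` samples
sites from the discretized class structure of the fitted models and
propagates exact `exp(Qt)` transitions, recording true site classes and
all internal node states; indels are not simulated. Protein evolution in
the genome generator is flat per-site substitution -- enough to control
identity, which is all its consumers measure.

Every generator requires a seed and is byte-deterministic given it.

# Numerical edge cases

* Invariant alignments make omega unidentifiable; `fit_m0()` refuses them
  with a diagnostic rather than returning a boundary estimate.
* Fisher p-values are clamped into `(0, 1]`; odds ratios are `ad/bc` with
  `Inf` when `bc = 0` and signal present.
* "Longest sequence" ties in allele collapse break lexicographically.
* The gap-fraction threshold for dropping sequences before codeml-style
  fitting is unstated in the original; 0.5 is our documented convention.
* Degenerate pattern columns (all gaps) are removed after gappy-row
  filtering; stop codons in a codon alignment are an error, because
  pseudogenes must be excluded upstream.

# Limitations

* The annotation search is exhaustive DP: suitable for desk-scale
  genomes and fixtures, not for 465-Mb assemblies.
* Clade labels are inputs; placement of genes into expansion clades from
  the phylogeny is out of scope, as is orthology-based naming.
* The enrichment test inherits the size-bias caveat of region-based
  overlap counting discussed above.
* Branch-site site identification is naive empirical Bayes, not BEB.
* Reproducing the published real-data values (the SINE q-value, ancestral
  repertoire sizes, per-clade omega estimates, genome-wide TE fractions)
  requires the real genome, annotations and trees; the test suite instead
  verifies each component against oracles and planted-truth simulations.
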