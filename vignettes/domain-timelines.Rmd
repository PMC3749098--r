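---
title: "Methods: domain timelines, constraint analysis and dipeptide signatures"
author: "codechron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain timelines, constraint analysis and dipeptide signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codechron)
```

# The model

`codechron` reconstructs relative timelines of protein domain structures from
a structural census and connects them to tRNA ancestrality and to the
dipeptide composition of proteins. The reconstruction rests on two standing
assumptions:

1. **Abundance grows with age.** The genomic abundance of a domain structure
   increases with time at a global level (duplication, de novo creation,
   co-option), so abundance-derived character states can be polarized: the
   hypothetical ancestor of a tree of domains sits at the *maximum* state of
   every character.
2. **Conformational order grows with age** for tRNA substructure characters,
   which are therefore polarized from an all-minimum (state 0) ancestor.

Neither assumption is tested by this package; both are inputs to it. Every
downstream quantity (node distances, clock ages, constraint statistics)
inherits them.

## From census to characters

An `AbundanceMatrix` holds nonnegative counts `g` (domains × proteomes).
`encodeCharacters()` turns each proteome column into one linearly ordered
multistate character:

* optional `ln(g + 1)` transform (the default; abundances are heavy-tailed),
* rescaling to `[0, 1]` by the column maximum (per-column normalization is
  the default because characters are proteome-wise abundance profiles; a
  global-maximum mode is exposed via `perColumn = FALSE` since the choice is
  not forced by anything in the data),
* discretization into `S` equal-width bins with edges at `i/S`: low bins are
  half-open, the top bin closed, so a rescaled value of exactly 1 maps to
  state `S − 1`. The convention is arbitrary but must be fixed for
  reproducibility; it is pinned by tests.

The default `S = 24` matches the `0–9A–N` character alphabet used by the
NEXUS dialect, the widest single-symbol alphabet the file format supports
here. All-zero columns map to state 0 for every taxon (a column with no
information should not contribute steps).

## Wagner parsimony

Characters are linearly ordered and reversible: a change from state `i` to
`j` costs `|i − j|`. `wagnerLength()` computes the minimum total cost over
ancestral-state assignments by dynamic programming over the tree: each node
carries a cost vector over states, and the child-to-parent transfer
`min_j c(j) + |i − j|` is computed with two linear passes rather than a full
`S × S` minimization. Because the cost is symmetric and reversible the score
does not depend on root placement, which is what makes Lundberg rooting a
separate, later step.

`searchMP()` offers three strategies:

* `exhaustive` — scores every unrooted topology; guaranteed optimal and
  refused above 9 taxa, where `(2n − 5)!!` explodes.
* `hillclimb` — `nStarts` addition-sequence replicates (the first in matrix
  row order, the rest in seeded random orders), each followed by
  steepest-descent nearest-neighbor interchange; the best result over
  replicates is kept. Addition-order replication is the standard way out of
  NNI local optima; with the default `nStarts = 5` the heuristic matched the
  exhaustive optimum on 100/100 random 7-taxon matrices in this package's
  acceptance suite, whereas a single start managed 76/100.
* `ratchet` — the hillclimb result is iteratively perturbed by reweighting a
  random 25% of characters to weight 2, re-optimized under the perturbed and
  then the original weights, and accepted when not worse, stopping after
  `nIdle = 5` idle rounds. The 25%/weight-2 setting is the canonical ratchet
  default; the original description leaves it unparameterized.

Ties are broken deterministically everywhere (lowest edge index, first
candidate found), so a fixed seed reproduces a search exactly.

For the 50-domain × 20-proteome pipeline runs used in the recovery analyses,
the package uses `hillclimb` with `nStarts = 1`: matrices of that shape carry
strong monotone signal and a single addition sequence already recovers birth
order with Spearman ρ ≈ 0.97, while five starts would quintuple the runtime
for no measurable gain. This problem size — 50 domains, 20 proteomes, 20
characters after encoding — is the package's standard synthetic study
condition.

## Lundberg rooting and node distances

`lundbergRoot()` attaches the hypothetical ancestor to every edge in turn,
scores the augmented tree, and roots at the attachment point of the
cost-minimizing edge (lowest index on ties). No outgroup taxa are required.
The rooted tree yields node distances: `computeNd()` counts the nodes on each
root-to-leaf path and rescales the counts so the earliest-diverging leaf gets
`nd = 0` and the deepest `nd = 1`. Normalizing by `(max − min)` rather than
by the maximum anchors the first-diverging lineage exactly at 0, where the
oldest structures should sit. A perfectly balanced tree has no depth
variation; all leaves are then reported at 0 with a warning rather than as an
error, since downstream code can still consume the degenerate timeline.

`clockAge()` maps nd to geological age with the fold-level clock
`t = −3.802·nd + 3.814` or the fold-superfamily clock
`t = −3.831·nd + 3.628` (Gy before present). Ages that would fall below zero
(possible near `nd = 1` under the FSF clock) are clamped to 0 with a warning:
negative geological ages are meaningless, and clock dispersion is known to
grow at high nd.

## Constraint analysis

The ancestrality statistic of a tRNA group is
`S = length(best tree with the group forced monophyletic) − length(best
unconstrained tree)`. Smaller S means the group is less disturbed by
recruitment, hence older. When the character matrix carries a hypothetical
ancestor it is included as an additional terminal during these searches, so
monophyly is judged on the rooted topology. Searches are exhaustive up to 9
effective taxa and constrained hillclimbs (attachments and rearrangements
that would break the group are skipped) above that. A group that is the full
taxon set, a single taxon, or — absent an ancestor — all but one taxon is
trivially monophyletic and gets S = 0 without a search.

## Coevolution regressions

`coevolutionRegression()` fits a constraint statistic on nd in two modes. The
through-origin mode implements the slope-only form (`slope = Σxy/Σx²`,
uncentered R², F on (1, n−1) df); the intercept mode is ordinary simple
regression on (1, n−2) df. Both are reported because published slope-only
fits mix df conventions: the printed combinations of R², F and p for the
editing-set regression are mutually inconsistent under any integer df for
standard least squares, so this package exposes both variants and asserts
neither against the printed statistics. The underlying (nd, S) data pairs
were never published, which also rules out recomputing them.

# Dipeptide and structure analyses

## The dipeptide universe

A protein of length `L` contains `L − 1` overlapping dipeptides.
`dipeptideCounts()` tallies them over the 400 ordered pairs of the 20
standard residues; pairs touching an ambiguous residue (X/Z) are counted in a
separate bucket so the `L − 1` conservation law still holds. A universe of
exactly 400 ordered pairs is the only self-consistent choice: published cell
counts that imply other universes (e.g. 408) are not reconcilable with any
standard combinatorial count, and keeping the ambiguous tally separate
preserves the information those variants try to capture.

## Enrichment

`hypergeomEnrichment()` compares an ancient sequence set (by default families
with `nd` below 0.2 — `ancientRecords()` implements both the strict and the
inclusive cutoff conventions) against the full set. For each item with
ancient proportion strictly above the global proportion (`k/n > M/N`), the
upper-tail hypergeometric probability `P(X ≥ k)` is computed by explicit
log-scale summation of `C(M,j)·C(N−M,n−j)/C(N,n)`. The tail includes the
observed `k` — the standard enrichment convention; the bare point-mass form
would understate the evidence. Items failing the strict filter carry no p.
Significance uses a fixed `α = 0.01` with no multiple-testing correction, the
convention of the analysis this package implements; a Benjamini–Hochberg
option exists but is off by default.

## Group contrasts, hydropathy, networks

`groupSetContrast()` maps counted dipeptides to the 9 cells of the age-group
partition (Groups 1/2/3 of the first × second residue) and contrasts observed
cell counts against the mean counts over free permutations of the residue
order of the concatenated sequences (chi-square, df = 8; zero-expectation
cells are dropped with a warning and df reduced). The permutation expectation
converges to the product of marginal group frequencies, which the tests use
as a closed-form check. `kdMean()` averages the Kyte-Doolittle index,
unweighted for residue sets and occurrence-weighted over residue slots for
dipeptide lists. `dipeptideNetwork()` renders an enriched set as an
undirected graph whose edges are weighted by the number of dipeptide types
joining two residues (AL and LA both feed the A–L edge).

## Region classes and bias tests

DSSP letters map to four region classes: h/g/i → H (helix), e/b → E
(strand), t/s → T (turn/bend), everything else including blank coil → Ω
(loop). Mapping the DSSP bend letter S into class T follows the class
definition by structural elements (turns *and bends* are the turn/bend
class); a reading that assigns bends elsewhere contradicts the DSSP alphabet
itself. A dipeptide's class is the unordered pair of its residues' classes,
so the turn/loop boundary T–Ω merges both orientations, matching how boundary
categories are reported.

`regionBiasTest()` uses per-sequence frequencies as the observation unit: for
each sequence, the fraction of enriched-dipeptide occurrences falling in a
class is compared with the fraction of all dipeptides in that class, and a
two-sided Mann-Whitney test is run across sequences per class. The test is
exact for group sizes up to 8 without ties and a tie-corrected normal
approximation otherwise. `tOmegaRatio()` summarizes loop rigidity per record
as the ratio of enriched dipeptides spanning a T/Ω boundary to enriched
dipeptides touching Ω elsewhere; a zero denominator is reported as undefined
with a flag rather than silently dropped.

`exchangeGroupAnalysis()` computes, per sequence and per DSSP letter class,
the frequency of each exchange group's residues (helix/turn/strand groups H,
T, E — a 5 + 8 + 7 partition of the alphabet), then runs a one-way ANOVA per
letter with Tukey HSD at α = 0.05 summarized as compact letters (groups
sharing a letter are indistinguishable). Helix subclasses (G, I) can be
pooled into H *before* the per-sequence averaging via `poolHelix = TRUE`;
pooling before averaging is pinned because the alternative (averaging then
pooling) would weight sparse π-helix observations equally with abundant
α-helix ones.

# The genetic code map

`complementCodon()` implements the reverse-complement pairing that underlies
the vis-à-vis representation: position 1 pairs with position 3, the pairing
is involutive, and it is fixed-point free (a self-complementary triplet would
need a self-pairing middle base), so the 64 codons form exactly 32 unordered
pairs. `buildVisAVis()` annotates each codon with its complement, a groove
mode and an expansion stage. Groove defaults follow synthetase class
membership (class II → major groove); the documented behavioural exceptions
(TyrRS, PheRS) are annotations for the reader, not pairing rules, and every
entry is caller-overridable. Stage labels encode the historical narrative —
`operational-1` (Tyr), `operational-2` (the Leu/Ser lineages), then
expansion groups A/B/C — as *labels on cells*, not as an executable
classifier: the decision criteria (N73 identity, N2 bias) come from curated
experimental tables that users supply, so the package annotates rather than
infers. `n2Composition()` summarizes those tables (N73 and N2 base
composition per group) and tallies coordinated C2-G72/G2-C72 complementarity
across codon pairs, reporting the exceptions.

# The synthetic-data generators

The generators exist because the original inputs — a SUPERFAMILY census of
hundreds of proteomes and a culled PDB snapshot — are external resources that
cannot ship with an R package. They emulate the *statistical structure* the
analyses assume, with known ground truth, and nothing more.

**Census** (`simulateCensus()`): domains are born in a ranked order at evenly
spaced times on `[0, 1)`; every proteome accumulates each domain at
`rate × elapsed time` with multiplicative log-normal noise (`noiseSd`,
default 0.3), rounded to integer counts. Per-proteome rates vary as geometric
Brownian motion along a random Yule organismal tree, giving proteomes
phylogenetically autocorrelated "genome sizes". Presence is deliberately not
restricted to descendants of a birth lineage: a descent-restricted model
makes noiseless row sums non-monotone whenever coverage varies, breaking the
generator's own contract that older domains are stochastically more abundant
*and* more widespread; under the chosen model occupancy still grows with age
because young domains' small expected counts round to zero in part of the
proteomes. The noise model is a design choice — any monotone-in-age
accumulation model is compatible with the stated assumption — and log-normal
multiplicative noise is the simplest one with positive support.

**Sequences** (`simulateSequences()`): each timeline family receives
sequences from a first-order residue chain, uniform over the 20 residues by
default (no external composition table is imported). Families with
`nd ≤ 0.2` use a chain whose transition weights for the planted dipeptides
are multiplied by `enrichmentFactor` (default 5). The default planted set has
33 members — the size of the enriched set the full-scale analysis reports —
built from Group 1/2 residues plus Gly/Glu with Ala/Gly/Val/Ile/Leu as hubs
and Ser absent, mirroring the qualitative structure of the reported set; it
is a synthetic stand-in, not the published list. A planted set of paper-like
size matters for the recovery properties: with only 2–3 planted dipeptides
the handful of chance flags among ~400 null items would dominate any
false-discovery proportion regardless of implementation quality. Secondary
structure is a three-class segment process (helix/strand/coil runs, DSSP
letters drawn per segment class) — sufficient because only region-class
statistics are consumed downstream.

**tRNA matrices** (`simulateTrnaMatrix()`): ordered characters drift upward
(`rpois(2·noiseSd) − rpois(0.5·noiseSd)` per edge, clamped to the state
range) along a random rooted tree from an all-zero ancestor, so `noiseSd = 0`
leaves all taxa ancestral. Isoacceptor-like groups are disjoint clades of the
generating tree, and each receives a small block of clade-marker characters —
a large shared derived state on the group's stem — emulating the diagnostic
substructural features that define isoacceptor families. Without such
markers, pure drift leaves small clades without synapomorphies and the
planted groups would not be recoverable by *any* method; with them, planted
groups are monophyletic in most parsimonious trees and their constraint
statistic is 0, which is the generator's contract.

**What passing tests do and do not show.** The recovery suites demonstrate
that the pipeline correctly inverts its own generative assumptions at desk
scale (50 domains, 20 proteomes; 400 sequences; 12 tRNAs). They do not
validate the assumptions themselves on real data, nor reproduce the
genome-scale results: the published 2,397-family tree, the specific
33-dipeptide list, the printed regression statistics and the full
significance pattern of the region-bias analysis all depend on a 2012 census
and PDB snapshot (and on unpublished data pairs) that are out of reach of a
desk-scale reimplementation.

# Numerical conventions and degenerate inputs

* Tie-breaking is lowest-index/first-candidate everywhere; all stochastic
  steps consume an explicit seed, and a fixed seed reproduces searches,
  bootstraps and simulations exactly.
* All-zero census columns → state 0; constant columns → top state.
* Balanced trees → all `nd = 0` with a warning; clock ages below 0 → clamped
  to 0 with a warning.
* Matrices without character variation → CI and RI reported as `NA` rather
  than 0/0.
* Chi-square cells with zero permutation expectation are dropped with a
  warning and df reduced; Mann-Whitney classes with no occurrences are
  skipped with a note.
* The identity cull compares sequences by ungapped sliding overlap (minimum
  overlap: half the shorter sequence); it is a lightweight stand-in for a
  full culling server — only the thresholds matter downstream.

# Known limitations

* Heuristic searches carry no optimality guarantee; the addition-sequence
  replicate count trades time for reliability, and very large or very noisy
  matrices may need more starts or the ratchet.
* The constraint search above 9 effective taxa is itself heuristic, so
  reported S values are upper bounds in that regime.
* `g1` uses uniformly random labeled topologies; its Monte-Carlo error scales
  as `n_random^{-1/2}`.
* The vis-à-vis stage labels are annotations driven by curated tables, not
  inferences; real acceptor-stem summaries require user-supplied per-tRNA
  data, which the original analyses did not publish in machine-readable form.
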