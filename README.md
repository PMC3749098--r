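# codechron

Phylogenomic timelines of protein domain structures, aaRS–tRNA coevolution
statistics, and the compositional signatures linking the origin of the
genetic code to protein flexibility.

## The problem

Aminoacyl-tRNA synthetases (aaRSs) implement the genetic code: their
catalytic domains charge amino acids onto tRNA, editing domains proofread the
charge, and anticodon-binding domains read the code itself. The relative ages
of these domains — and of the tRNA substructures they touch — can be
retrodicted from a *structural census*: a matrix **g** of genomic abundances
of domains (SCOP fold families) across proteomes. Under the assumption that
the popularity of a domain structure grows with its age, abundances become
linearly ordered phylogenetic characters, trees of domains become timelines,
and a molecular clock converts relative node distance into geological time.
The same timelines date compositional features of proteins, which is where
dipeptides (the `L − 1` overlapping residue pairs of a length-`L` protein)
enter: dipeptides enriched in the most ancient fold families carry the
imprint of archaic, pre-ribosomal peptide synthesis.

`codechron` implements that machinery end to end for analysts of molecular
evolution:

* **census coding** — `encodeCharacters()` rescales each proteome column of an
  abundance matrix (optionally `ln(g+1)`) and discretizes it into up to 24
  linearly ordered states (alphabet `0–9A–N`); `read/writeCharacterMatrix()`
  handle tab-separated and NEXUS files.
* **Wagner parsimony** — `wagnerLength()` scores trees by linear-cost
  (`|i − j|`) dynamic programming; `searchMP()` searches tree space
  (exhaustive ≤ 9 taxa, addition-sequence replicates + NNI, parsimony
  ratchet); `lundbergRoot()` roots trees by attaching a hypothetical ancestor
  to the length-minimizing edge, no outgroup needed; `bootstrapSupport()` and
  `treeStats()` (CI, RI, g1 skewness of random-tree lengths) assess signal;
  `constraintS()` measures the extra steps needed to force a tRNA group
  monophyletic — the ancestrality statistic S.
* **timelines** — `computeNd()` scales root-to-leaf node counts to the
  `[0, 1]` node-distance timeline; `clockAge()` applies the molecular clocks
  `t = −3.802·nd + 3.814` (fold level) and `t = −3.831·nd + 3.628`
  (fold-superfamily level), in Gy; `coevolutionRegression()` fits tRNA age
  (S) on domain age (nd), through the origin or with an intercept.
* **dipeptides** — `dipeptideCounts()`, per-fold-family signature profiles and
  evolutionary heat-map matrices (`buildProfiles()`), greedy identity culling
  (`cullSequences()`), hypergeometric enrichment of dipeptides in ancient
  families (`hypergeomEnrichment()`), age-group chi-square contrasts against
  permutation expectations (`groupSetContrast()`), Kyte-Doolittle hydropathy
  means (`kdMean()`), and enriched-dipeptide networks (`dipeptideNetwork()`).
* **structure** — DSSP parsing (`parseDssp()`), the H/E/T/Ω region classes
  (`classifyRegions()`), Mann-Whitney region-bias tests of enriched
  dipeptides (`regionBiasTest()`), the turn-boundary loop ratio
  (`tOmegaRatio()`), and exchange-group ANOVA with Tukey letters
  (`exchangeGroupAnalysis()`).
* **code map** — reverse-complement codon pairing (`complementCodon()`), the
  vis-à-vis complementarity table with groove modes and expansion stages
  (`buildVisAVis()`), and acceptor-stem N2/N73 composition summaries
  (`n2Composition()`).
* **synthetic data** — `simulateCensus()`, `simulateSequences()` and
  `simulateTrnaMatrix()` generate censuses, annotated sequence sets and tRNA
  character matrices with known ground truth, so every stage of the pipeline
  is exercisable and testable without external downloads.

## Worked example

A small synthetic census, encoded, searched, rooted and dated:

```r
library(codechron)

cfg <- simulationConfig(nDomains = 12, nProteomes = 8, seed = 42)
sim <- simulateCensus(cfg)                       # census + birth-order truth
cm  <- encodeCharacters(sim$census)              # 24 ordered states, ln(g+1)
res <- searchMP(cm, "hillclimb", seed = 42)      # most parsimonious trees
res$length
#> [1] 180
tl  <- buildTimeline(lundbergRoot(res$trees[[1]], cm))
head(tl, 5)
#>   domainId  nd  ageGy
#> 1    ff001 0.0 3.8140
#> 2    ff005 0.1 3.4338
#> 3    ff009 0.2 3.0536
#> 4    ff002 0.3 2.6734
#> 5    ff012 0.4 2.2932
cor(sim$truth$birthRank[tl$domainId], tl$nd, method = "spearman")
#> [1] 0.9562186
```

The tree length (180 steps) is the minimum Wagner cost over ancestral-state
assignments. In the timeline, `nd = 0` is the earliest-diverging (oldest)
domain and `ageGy` its clock age in billions of years before present — the
oldest synthetic domain dates to 3.81 Gy, the intercept of the fold-level
clock. The Spearman correlation of 0.96 between the generator's true birth
ranks and the recovered node distances shows the timeline machinery
recovering the planted history through noise. Tree statistics for the same
search (`treeStats(res$trees[[1]], cm, seed = 42)`) give CI = 0.75,
RI = 0.815 and g1 = −0.8; the strongly negative skewness indicates
phylogenetic signal well beyond random topologies.

Hydropathy summaries used throughout the compositional analyses:

```r
kdMean(aminoAcids())                                       # -0.49
kdMean(c("S","L","P","K","M","I","V","A","T","F"))         #  1.2 (editing-charged)
```

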