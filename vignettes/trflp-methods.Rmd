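---
title: "T-RFLP community analysis: models, parameters and validation"
author: "TRFLPtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{T-RFLP community analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TRFLPtools)
```

# The method

Terminal restriction fragment length polymorphism (T-RFLP) fingerprints a
microbial community by PCR-amplifying a marker gene (here the 16S rRNA
gene) with one fluorescently 5'-labelled primer, digesting the amplicons
with a restriction enzyme, and sizing only the labelled terminal fragment
of each template on a capillary sequencer. Each distinct terminal fragment
size (a *T-RF*, or operationally a *ribotype*) stands in for a community
member; peak areas measure its signal, and relative peak area within a
profile estimates relative abundance.

TRFLPtools implements the complete desk side of such a study:

1. **In-silico digestion** (`inSilicoPCR()`, `predictTRF()`,
   `ardraPattern()`): predicting, from reference 16S sequences, which
   fragment size each taxon should produce under each enzyme, so observed
   peaks can be assigned identities (`assignIdentity()`).
2. **Peak processing** (`readPeakTable()`, `filterSizeRange()`,
   `binTRFs()`, `mergeReplicates()`): turning sized electropherogram peak
   tables into a relative-abundance community matrix.
3. **Community statistics** (`diversityIndices()`, `classifyTRFs()`,
   `brayCurtis()`, `nmdsEmbed()`, `anosimTest()`, `upgmaCluster()`).
4. **A synthetic-data generator** (`generateScenario()`,
   `simulatePeakTables()`) with known ground truth, so every stage and
   every statistical claim is testable without instrument data.

# In-silico PCR and digestion

Primer matching is **exact under IUPAC degeneracy**: a degenerate code
matches any base in its set, and no mismatches are tolerated. T-RFLP
protocols specify no annealing mismatch model, and exactness keeps
predictions deterministic. The built-in registry carries
the degenerate eubacterial primer 27F-Degen (`AGRRTTYGATYMTGGYTYAG`), the
chloroplast-avoiding, 6FAM-labelled 799f (`AACMGGATTAGATACCCKG`) and the
universal 1492R (`GGTTACCTTGTTACGACTT`); 799f/1492R is the sized pair.
Amplicons run from the 5' base of a top-strand forward-primer match to the
end of the nearest downstream reverse-complemented reverse-primer match;
when several forward sites precede one reverse site, each pairs with its
nearest downstream reverse match and all (overlapping) amplicons are
reported. Coordinates are 0-based half-open; the labelled 5' base counts
as position 1 of a fragment.

Restriction sites are scanned on the top strand only. The shipped enzymes
— DdeI (`C^TNAG`), HaeIII (`GG^CC`), HhaI (`GCG^C`) — have
degeneracy-palindromic sites, so a top-strand scan finds every duplex
site; constructing a `RestrictionEnzyme` with a non-palindromic site
warns. The labelled T-RF is the first site occurrence plus the enzyme's
cut offset; an uncut amplicon reports its full length with
`cut_found = FALSE`. Full fingerprints (`ardraPattern()`) cut at every
non-overlapping occurrence left-to-right, and the fragments always
partition the amplicon exactly — a property the test suite checks against
an independent scanner that expands all degeneracy combinations.

One subtlety worth documenting: for blunt cutters (HaeIII) digesting the
reverse complement reverses the fragment list exactly; for enzymes that
leave overhangs (DdeI, HhaI) the top-strand fragment boundaries of the
reverse complement shift by the overhang length (the two strands of a
sticky cut have different terminal lengths). The tests assert exact
mirror symmetry for HaeIII and overhang-bounded deviations for the others.

Bacterial 16S amplicons from 799f/1492R run near 730 bp while plant
mitochondrial 18S co-amplicons run near 850 bp, so organellar products are
removed in silico with a length threshold of 800 bp (default
`organellarMax`), between the two.

Observed bins are linked to predicted taxa within ±1 bp by default
(`assignIdentity()`); in-silico prediction tools for T-RFLP do not
publish a canonical tolerance, so the value is configurable, and
multi-assignment (two taxa, one fragment size) is preserved rather than
broken arbitrarily.

# From peaks to a community matrix

Peak tables are delimited text with columns `sample`, `enzyme`, optional
`run`, `size` (bp), `height` and `area` (fluorescence units), the shape of
a GeneMapper-style export. Processing follows the conventional order:

* **Size filter**: keep `50 <= size <= min(500, 800)` bp by default — the
  reliable range of a 500-size internal standard, inclusive at both ends,
  with the organellar ceiling above.
* **Binning**: pooled sizes from all samples are sorted and chained by
  single linkage — a new bin starts where the gap to the previous size
  exceeds `gapTolerance` (default **0.5 bp**). Duplicate capillary runs
  drift by sub-bp amounts, and chaining absorbs that drift without fixed
  bin edges. The bin's representative size is the mean of its member
  sizes, labelled to one decimal.
* **Normalisation**: within a profile, relative abundance is peak area
  over total peak area; bins hit by several peaks of one sample are summed
  before normalising. Rows (samples) of the community matrix sum to 1.
* **Replicate merging**: duplicate runs are re-binned jointly (the merged
  bin set is the union) and a sample's merged abundance is the arithmetic
  mean of its run abundances with absences counted as zero. A
  presence-weighted alternative (`how = "presence"`) keeps full weight for
  bins detected in only some runs; the mean is the default because it
  damps run-to-run area noise while the union already preserves presence
  for richness.
* No relative-abundance floor is applied by default; `minAbundance` in
  `buildCommunityMatrix()` optionally zeroes rare bins (e.g. 0.5%) for
  instruments with unknown peak-calling thresholds.

The `TRFCommunity` container extends `SummarizedExperiment` with bins as
rows and samples as columns (the transpose of the samples-by-T-RFs
convention; columns sum to 1). Matrices round-trip through TSV at full
double precision.

# Diversity and ribotype classification

For a relative-abundance vector \(p\): richness \(S\) counts positive
entries; Shannon diversity \(H' = -\sum p_i \ln p_i\) (natural log,
nats); evenness \(J' = H'/\ln S\), defined as 0 when \(S = 1\) (the
formula is 0/0 there); dominance \(D = \sum p_i^2\). Both Simpson
variants are returned: the reciprocal \(1/D\) and the complement
\(1 - D\). Printed diversity tables in the T-RFLP literature sometimes
state the reciprocal formula while tabulating values in \([0, 1]\), which
can only be the complement; computing both sidesteps the ambiguity, and
the complement is the default for table-style reporting
(`diversityTable()` gives mean ± s.e. per group).

`classifyTRFs()` splits detected bins into a **core** (present in every
group — candidate core microbiota), **shared** (two or more but not all
groups) and **unique** (one group — genotype-specific ribotypes) — a
partition, which the tests verify on random matrices. The headline
percentage of genotype-specific ribotypes is
`percentUnique(unique, total)`, reported to one decimal.

# Ordination and inference

**Bray-Curtis**: \(d_{hi} = \sum_j |x_{hj} - x_{ij}| / \sum_j (x_{hj} +
x_{ij})\); percent similarity is \(100(1 - d)\). Ordination operates on
dissimilarities; results reported on the similarity scale use the
conversion above.

**NMDS** minimises Kruskal stress-1,
\(\sqrt{\sum_{h,i}(d_{hi} - \hat d_{hi})^2 / \sum_{h,i} d_{hi}^2}\),
where \(d\) are configuration distances and \(\hat d\) disparities from
least-squares monotone (pool-adjacent-violators) regression of \(d\)
against the dissimilarity ranks. Ties in the dissimilarities follow the
primary approach (tied blocks may be reordered to improve fit). Each
start alternates the monotone fit with a Guttman transform until the
stress change falls below `tol = 1e-7` or 300 iterations. Defaults:
`k = 2`, `nStarts = 100` (the conventional number of random starts for
T-RFLP ordinations). One numerical design choice: the first start is the
classical (metric) scaling solution rather than a random configuration.
Pure stress-1 admits degenerate "step-function" solutions in which points
collapse into a few clusters whose distances are still monotone in the
input ranks — near-zero stress, meaningless map. A metric start anchors
the search at the true configuration whenever the input is (nearly)
Euclidean, which is also the convention of the standard non-metric MDS
implementations. The remaining starts are uniform random; the best
(lowest-stress) solution is returned, centred and rotated to principal
axes. Stress is invariant under rigid motion and uniform scaling, and
the best-of-\(m\) stress is non-increasing in \(m\) for a fixed seed
stream — both tested.

**ANOSIM** ranks all off-diagonal dissimilarities (average ranks on ties)
and contrasts mean between- and within-group ranks:
\(R = (\bar r_B - \bar r_W) / (n(n-1)/4)\), in \([-1, 1]\). Significance
is by label permutation with \(p = (1 + \#\{R^* \ge R\}) / (1 + m)\),
avoiding zero p-values; when the number of distinct labelings
\(n!/\prod_g n_g!\) is no larger than the requested permutations the null
is enumerated exactly (for two groups of two: three distinct partitions,
so perfect separation gives exactly \(p = 1/3\)). Pairwise tests rerun
ANOSIM on each group pair. The default 999 permutations corresponds to
the conventional reporting floor of \(P(\%) = 0.1\). Because \(R\) is
rank-based it is invariant under any monotone transform of the
dissimilarities (tested).

**Clustering** is group-average (UPGMA) agglomeration via `hclust`,
exported as Newick with the ultrametric height/2 branch-length convention
and as percent-similarity merge levels.

# The synthetic-data generator

`generateScenario()` emulates the design of a multi-genotype seed
endophyte survey; the defaults are the study conditions, not tuning
knobs:

* **Design**: six genotype groups × three replicate samples, duplicate
  electrophoresis runs per sample, 24 taxa, all three enzymes.
* **Templates**: each taxon gets a concrete 799f instance, a random
  650-750 bp insert and the reverse complement of 1492R (amplicons of
  688-788 bp, bracketing the ~730 bp bacterial product), flanked by short
  random sequence. One recognition site per enzyme is planted so that the
  planted T-RFs are 60-600 bp, pairwise ≥ 2 bp apart within an enzyme
  (`allowCollisions = TRUE` instead plants one shared fragment to
  exercise multi-assignment). All unintended site occurrences are
  scrubbed, and the generator verifies its own plants by running the
  package's digest machinery on every template.
* **Abundances**: a log-normal base profile (log-SD 1 — the right-skewed
  dominance structure typical of endophyte communities); per group, a
  random half of the taxa get a log-abundance shift of magnitude
  `effectSize` with random sign (`effectSize = 0` leaves all groups
  sharing one generating profile); per sample, log-normal
  replicate-to-replicate variability with `sampleLogSD = 0.25`.
* **Measurement**: peak area = total signal (10^4) × abundance ×
  multiplicative log-normal noise with mean 1 and CV `areaCV = 0.2`
  (fluorescence scales multiplicatively); fragment size = predicted T-RF
  + Gaussian jitter with SD `sizeJitterSD = 0.15` bp (sub-bp sizing
  drift); peaks below `detectionFloor = 50` fluorescence units are
  dropped. Everything is deterministic under the configuration seed, and
  seeded functions restore the caller's RNG state.

What the generator does **not** emulate: pseudo-T-RFs and chimeras,
partial digestion, PCR efficiency differences between templates,
size-calling bias (sizes are taken as called), and taxon-specific 16S
copy-number variation. Passing tests therefore demonstrate the
correctness of the analysis machinery under a clean generative model,
not robustness to every artefact of real electropherograms.

# Validation strategy and problem sizes

The test suite validates each stage against an independent route: the
degeneracy-expansion scanner for PCR/digestion (1,000 random templates),
closed forms for diversity, `stats::isoreg` for monotone regression and
vegan for Bray-Curtis/ANOSIM cross-checks, hand-computed UPGMA merges and
the ultrametric three-point condition, and the generator's ground truth
for the pipeline. Statistical calibration uses 500 zero-effect
simulations (ANOSIM rejection rate at α = 0.05 must sit in 0.05 ± 0.02
with 199 permutations, two groups of five samples) and 50
strong-effect simulations (three groups of three, `effectSize = 2`, mean
R ≥ 0.9, median p ≤ 0.005 at 999 permutations — with nine samples a
random permutation occasionally reproduces the true partition, so the
attainable p is a few multiples of 1/1000). NMDS recovery uses a
20-sample perfectly embeddable configuration and 100 starts. A noiseless
scenario must round-trip through filter → bin → normalise → diversity to
within 10⁻¹².

# Worked example

```{r example, eval = FALSE}
cfg <- scenarioConfig(nTaxa = 12, groups = c(A = 3, B = 3), seed = 1)
truth <- generateScenario(cfg)
peaks <- simulatePeakTables(truth)
grouping <- setNames(as.character(truthGroups(truth)),
                     names(truthGroups(truth)))
res <- runTRFLP(peaks[peaks$enzyme == "DdeI", ], grouping,
                outDir = "run1", nStarts = 100, seed = 1)
res$diversity
res$anosim
```

# Known limitations

* Enzymes with non-palindromic sites are scanned on the top strand only
  (with a warning); bottom-strand sites of such enzymes are missed.
* Exact ANOSIM enumeration is limited to designs with at most the
  requested number of distinct labelings; beyond that the sampled null is
  used.
* NMDS on very few samples (n ≤ 5) can be rank-deficient; results are
  returned but stress near zero is then uninformative.
* The organellar filter is purely length-based; a bacterial fragment
  above the threshold would be removed with the organellar signal.
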