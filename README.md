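# TRFLPtools

Terminal restriction fragment length polymorphism (T-RFLP) remains a
workhorse for fingerprinting bacterial communities — for example the
endophytes inside surface-sterilised rice seeds — when amplicon sequencing
is overkill or unavailable. A 16S rRNA gene amplicon carrying one
5'-fluorescent primer (799f, 6FAM-labelled, paired with 1492R) is digested
with a restriction enzyme (DdeI, HaeIII or HhaI), and only the labelled
terminal fragment of each template is sized on a capillary sequencer. Each
distinct terminal fragment size (T-RF, a "ribotype") acts as a community
member; its relative peak area acts as relative abundance.

TRFLPtools is an R package for everything that happens after the
sequencer, plus the in-silico work before it:

* **In-silico PCR and digestion** — exact degeneracy-aware primer matching
  (`inSilicoPCR`), labelled T-RF prediction (`predictTRF`), full ARDRA
  fingerprints (`ardraPattern`) and taxon assignment of observed bins
  (`assignIdentity`).
* **Peak processing** — GeneMapper-style peak tables (`readPeakTable`),
  size-standard and organellar filtering (`filterSizeRange`),
  single-linkage cross-sample binning (`binTRFs`), duplicate-run merging
  (`mergeReplicates`), all landing in a `TRFCommunity`
  (SummarizedExperiment) whose samples sum to 1.
* **Community statistics** — richness, Shannon H′ (nats), evenness
  J′ = H′/ln S, Simpson (complement and reciprocal) via
  `diversityIndices`; core / shared / genotype-specific ribotype
  classification (`classifyTRFs`, `percentUnique`).
* **Ordination and inference** — Bray-Curtis dissimilarity
  (Σ|x−y| / Σ(x+y)), non-metric multidimensional scaling minimising
  Kruskal stress-1 `sqrt(Σ(d−ď)² / Σd²)` by pool-adjacent-violators
  monotone regression with 100 starts (`nmdsEmbed`), ANOSIM
  `R = (r̄_between − r̄_within)/(n(n−1)/4)` with exact or sampled
  permutation p-values (`anosimTest`), and UPGMA clustering with Newick
  export (`upgmaCluster`, `exportNewick`).
* **Synthetic ground truth** — `generateScenario` builds 16S-like
  templates with planted primer and restriction sites, group-structured
  log-normal abundances and a tunable between-group effect;
  `simulatePeakTables` adds multiplicative area noise, sub-bp size jitter
  and a detection floor. Every pipeline stage is validated against this
  known truth and against independent oracles.

## Worked example

Simulate a two-genotype community, run the full pipeline on its DdeI
profile, and test the genotype effect:

```r
library(TRFLPtools)

cfg   <- scenarioConfig(nTaxa = 12, groups = c(A = 3, B = 3), seed = 1)
truth <- generateScenario(cfg)
peaks <- simulatePeakTables(truth)
grouping <- setNames(as.character(truthGroups(truth)),
                     names(truthGroups(truth)))

res <- runTRFLP(peaks[peaks$enzyme == "DdeI", ], grouping,
                nStarts = 100, seed = 1)
round(res$diversity, 3)
#>      S shannon evenness dominance simpson_complement simpson_reciprocal
#> A_1  9   1.677    0.763     0.234              0.766              4.282
#> A_2  9   1.639    0.746     0.245              0.755              4.073
#> A_3  8   1.672    0.804     0.233              0.767              4.301
#> B_1 11   1.838    0.767     0.207              0.793              4.841
#> B_2 11   1.933    0.806     0.186              0.814              5.369
#> B_3 11   1.634    0.681     0.279              0.721              3.581

res$nmds
#> NMDS ordination: 6 samples in 2 dimensions
#>   Kruskal stress-1 = 0.00000 (best of 100 starts, converged)

res$anosim
#> ANOSIM: R = 1.0000, p = 0.1 (exact, 20 distinct labelings)

res$classification
#> Ribotype classification over 2 groups
#>   core (all groups): 132.0, 216.0, 228.0, 236.0, 316.0, 426.1, 432.0, ...
#>   unique to B: 388.0, 392.0
```

Reading: group B samples carry 11 detectable ribotypes against 8–9 in
group A; the two groups separate perfectly (ANOSIM R = 1, and p = 0.1 is
the smallest value an exact test on 3+3 samples can produce — 20 distinct
labelings, two of which reproduce the observed partition). Nine ribotypes
form the shared core; two are specific to genotype B. Passing
`outDir = "run1"` additionally writes `matrix.tsv`, `diversity.tsv`,
`nmds.tsv`, `anosim.json`, `dendrogram.nwk`, `heatmap.tsv` (bins ordered
by decreasing total abundance) and `provenance.json`.

The methods vignette (`vignettes/trflp-methods.Rmd`) documents the models,
defaults, numerical choices and what the synthetic generator does and does
not emulate.

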