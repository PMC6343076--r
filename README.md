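# RiboRatio

Cell-level microbial metabolic activity from paired 16S rRNA/rDNA
amplicon sequencing, with a population-genome cross-validation arm.

## The problem

Sequencing a community's 16S rRNA *genes* (rDNA) profiles who is there;
sequencing its 16S rRNA *transcripts* (rRNA) profiles who is active,
because active cells amplify their ribosome content. For taxon *t* with
cell abundance *p*, 16S copy number *c* and per-cell ribosomal
amplification *a*, the expected pool fractions are

    f_rDNA ∝ p·c        f_rRNA ∝ p·c·a

so the **rRNA/rDNA ratio** — a unit's relative rRNA abundance divided by
its relative rDNA abundance — estimates *a* up to one community-wide
constant (the abundance-weighted mean amplification). Ratios above 1 mark
taxa more active than average; rDNA-only units (ratio 0) look dormant or
dead; rRNA-only units are *phantom taxa*, artifacts of undersampling or
nucleotide error that must be excluded from ratio analyses.

The package implements the full pipeline under both taxonomic-unit
conventions and quantifies how the choice affects the biology read off
the data:

* **amplicon units** — expected-error quality filtering (≥230 bp, ≤1
  expected error), dereplication, greedy 97% OTU clustering,
  abundance-skew ZOTU denoising (merge when
  `size(u)/size(c) ≤ 2^-(αd+1)`, α = 2, minsize 8), read mapping at
  97%/100% identity, >5%-in-negative-controls contaminant removal,
  ZOTU→OTU cross-mapping;
* **activity profiles** — paired per-sample profiles, phantom/dormant
  accounting, rRNA/rDNA ratios, cumulative production curves,
  abundance–activity log-log correlations, rare-but-active quadrant
  statistics;
* **diversity** — rarefaction-normalized richness/Shannon/Faith's PD,
  weighted and unweighted UniFrac, PCoA, PERMANOVA;
* **genome activity** — coverage-based relative abundance, TPM-based
  relative transcription, transcription/abundance ratios, and iRep
  replication rates from the log2 gradient of sorted window coverage;
* **synthetic communities** — a fully seeded generator (known taxa,
  abundances, activity factors, tree, error rates, coverage gradients)
  providing ground truth for every stage.

## A worked example

Simulate a 40-taxon community, sequence both pools at 20,000 reads, run
the ZOTU pipeline, and look at the most active units:

```r
library(RiboRatio)
sc  <- simScenario(n_taxa = 40, depth_rdna = 20000, depth_rrna = 20000,
                   seed = 7)
com <- simulateCommunity(sc)
res <- runActivityPipeline(com, sc, method = "ZOTU")
head(res$profile[order(-res$profile$ratio), ], 5)
#>     unit_id rdna_count rrna_count rel_rdna rel_rrna ratio presence_class
#> 9  ZOTU0009        160        965  0.00810  0.04965  6.13         shared
#> 1  ZOTU0001       3406       9888  0.17242  0.50875  2.95         shared
#> 6  ZOTU0006        753       1270  0.03812  0.06534  1.71         shared
#> 25 ZOTU0025         61         98  0.00309  0.00504  1.63         shared
#> 16 ZOTU0016        214        300  0.01083  0.01544  1.42         shared
```

ZOTU0009 holds under 1% of the community's cells but delivers ~5% of its
rRNA — a rare-but-active taxon (estimated amplification 6× the community
mean). The community-level abundance/activity coupling and the overlap
between pools:

```r
logLogCorrelation(res$profile)
#> $rho       0.8201553
#> $p_value   1.672445e-10
#> $n         39
overlapSummary(res$profile)$per_sample
#>   sample n_shared n_phantom n_dna_only ...
#> 1     S1       39         0          0
rareActiveSummary(res$profile)$rare_active
#> 4    # of 10 units with ratio > 1, 4 sit below 1% abundance
```

At these depths with zero injected error there are no phantom units; they
appear once depth drops or substitution error rises, and harder for
ZOTUs than OTUs — compare `method = "OTU"` on the same scenario.
Rarefied alpha diversity works off the same count table:

```r
rarefyMeanAlpha(unitCounts(res$table), "shannon", depth = 5000, seed = 1)
#>  S1|rDNA  S1|rRNA
#> 4.152736 3.040969   # bits; the active community is less even
```

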