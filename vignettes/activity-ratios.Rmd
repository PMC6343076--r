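---
title: "Inferring cell-level microbial activity from paired rRNA/rDNA amplicons"
author: "RiboRatio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-level microbial activity from paired rRNA/rDNA amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RiboRatio)
```

## The model

Sequencing the same sample's 16S rRNA *genes* (rDNA, from extracted DNA)
and 16S rRNA *transcripts* (rRNA, from reverse-transcribed RNA) probes two
different communities: the total community and its metabolically active
part. A cell of taxon $t$ contributes $c_t$ gene copies to the rDNA pool
but roughly $c_t a_t$ transcripts to the rRNA pool, where $a_t$ is the
taxon's per-cell ribosomal amplification — the latent activity factor this
package estimates. With cell abundances $p_t$, the expected read fractions
are

$$
f^{\mathrm{rDNA}}_t \propto p_t c_t, \qquad
f^{\mathrm{rRNA}}_t \propto p_t c_t a_t,
$$

so the per-taxon ratio of relative abundances,

$$
r_t \;=\; \frac{f^{\mathrm{rRNA}}_t}{f^{\mathrm{rDNA}}_t}
      \;=\; \frac{a_t}{\sum_u p_u c_u a_u / \sum_u p_u c_u},
$$

recovers $a_t$ up to one community-wide constant (the abundance-weighted
mean amplification). Ratios above 1 mark taxa more active than the
community average; a ratio of 0 (detected in rDNA only) is the
dormant-or-dead signal; units detected **only** in the rRNA pool —
*phantom taxa* — have no defined ratio and are the main methodological
casualty the package quantifies.

The same logic applies genome-side: relative genome abundance from
metagenomic coverage, relative transcription from summed TPM of the
genome's ORFs, and their ratio; iRep adds an orthogonal activity readout
from the coverage gradient between replication origin and terminus.

## Taxonomic units: OTUs versus ZOTUs

Reads are quality-filtered (length $\ge$ 230 bp, expected errors
$\sum_i 10^{-Q_i/10} \le 1$), dereplicated across all samples and pools,
and formed into units two ways:

* **OTUs** — greedy centroid clustering in decreasing-abundance order at
  97% identity; a unique founds a centroid only with pooled size $\ge$ 8.
* **ZOTUs** — abundance-skew denoising: after dropping uniques below
  size 8, a unique $u$ merges into an accepted centroid $c$ when
  $\mathrm{size}(u)/\mathrm{size}(c) \le \beta(d) = 2^{-(\alpha d + 1)}$
  with $d$ the Levenshtein distance and $\alpha = 2$. The skew rule
  captures the fact that error variants of an abundant sequence are
  common, while genuinely distinct rare taxa are not *that* rare relative
  to their neighbours.

Reads are then mapped back to unit representatives at 97% (OTU) or 100%
(ZOTU) identity; units above 5% mean relative abundance in negative
controls are removed everywhere; ZOTUs are cross-mapped onto OTUs at 97%.

**Identity convention.** One convention is used everywhere (clustering,
mapping, cross-mapping): end-gap-free (overlap) alignment under unit
scores (match $+1$, mismatch $-1$, gap $-1$), ties resolved toward more
matches; identity is matches over alignment columns excluding terminal
gaps. A consequence worth knowing: mismatches in the last few bases can be
absorbed by the free end gaps. A pure edit-distance objective was rejected
because an empty overlap has zero edits and would always "win". Mapping
uses a banded variant of the same dynamic program whose band is sized from
the identity threshold, so every hit at or above the threshold is scored
exactly; `pairwiseIdentity()` exposes the unbanded program.

## What the synthetic generator emulates — and what it does not

`simulateCommunity()` and `sampleAmpliconReads()` generate ground-truthed
data with the statistical structure the analysis assumes:

* reference sequences evolved on a random bifurcating tree, rescaled so
  the mean pairwise divergence matches `mean_divergence` (default 0.05);
* lognormal cell abundances (`abundance_sigma`, default 1.5) and
  lognormal activity factors (`activity_sigma`, default 1.0);
* the `kill_the_winner` option assigns the activity draws anti-ranked
  against abundance (most abundant taxon gets the smallest activity),
  a deterministic coupling with Spearman $= -1$ that represents the
  hypothesis that fast growers are preferentially lysed and kept rare;
* multinomial read sampling per pool at configurable depth, per-base
  substitution error (default $1/20{,}000$, mid-range of published Taq
  estimates) plus an extra reverse-transcription rate on rRNA reads only
  (default $1/15{,}000$), constant Phred quality (default Q30), truth
  labels hidden behind a reserved `;truth=` header delimiter;
* genome-side: per-window read counts following the
  $2^{\log_2(\mathrm{iRep})(1-x)}$ origin-terminus density, reported as
  per-base depth, and length-proportional multinomial ORF transcript
  counts so that TPM recovers the configured transcription weights.

Two modelling choices deserve emphasis. First, errors are
substitution-only by default (`indel_rate = 0`) and always change the
base, so the realized per-base mismatch rate equals the nominal rate and
the edit-distance-1 structure the denoiser relies on stays clean. Second,
taxa are modelled as **well-separated lineages**: terminal branches are
re-evolved until every pair of references differs by at least
`min_taxon_dist` edits (default 8). Without that floor, random trees put
sister taxa 1–2 substitutions apart, where no frequency-based denoiser
can distinguish a true rare taxon from an error variant of its abundant
sibling — the skew rule then (correctly, by its own lights) absorbs it.
Strain-level microdiversity within a taxon is explicitly out of scope.
Consequently, passing tests demonstrate recovery of well-separated taxa
under multinomial sampling with simple error; they do not demonstrate
robustness to chimeras, indel-rich platforms, quality-correlated errors,
primer bias, or fine strain structure, none of which the generator
emulates.

What the defaults mean in practice: at the default depths ($5\times10^4$
per pool) and error 0, every taxon with pooled count $\ge 8$ is recovered
exactly as a ZOTU; at shallow depth ($10^4$) with realistic-to-pessimistic
error rates, phantom taxa appear and hit ZOTUs harder than OTUs — the
directional effect the unit-method comparison is about.

## Diversity machinery

* **Shannon** uses $\log_2$ (bits) by default; natural log by flag.
* **Faith's PD** is root-inclusive: the branch sum of the minimal subtree
  connecting the observed tips *and the root*, so a single tip scores its
  full root path. This matches the convention of the pipeline families
  that popularized the metric and shifts all values relative to
  root-exclusive implementations; tests pin it against an explicit
  edge-union oracle and against `picante::pd(include.root = TRUE)`.
* **Rarefaction** subsamples without replacement to a common depth and
  averages the metric over `n_reps` draws (default 10), matching the
  subsample-and-average normalization protocol; the hypergeometric
  closed form for two-unit columns anchors the tests.
* **UniFrac**: unweighted is the unique-branch-length fraction; weighted
  is the non-normalized variant $\sum_b l_b |A_b - B_b|$ (a
  `normalized` flag divides by $\sum_b l_b (A_b + B_b)$).
* **Trees**: when no curated phylogeny is supplied, `buildUnitTree()`
  computes 1 − cosine similarity of k-mer profiles (k = 6),
  neighbor-joining, midpoint rooting, negative branch lengths clamped to
  0. This is a pragmatic substrate for PD/UniFrac over unit
  representatives, not a phylogenetic inference method; any rooted newick
  can be supplied instead.
* **PCoA** reports negative eigenvalues rather than correcting them;
  variance shares are over positive eigenvalues only.
* **PERMANOVA** delegates to `vegan::adonis2` (free permutations,
  add-one p-value, seeded stream).

## Numerical and edge-case decisions

* Relative abundances are computed over **mapped** reads per pool and
  sample, not filtered reads, so rDNA and rRNA stay comparable between
  methods with different mapping rates.
* Phantom units are excluded from ratio statistics and correlations
  (ratio undefined) rather than pseudo-counted; `dna_only` units carry
  ratio 0. `ratioDistributionStats()` reports the distribution both with
  and without the ratio-0 units because conventions differ on whether
  "fraction below 1" should include them.
* A negative control with zero mapped reads contributes 0 to the
  contaminant average (conservative reading of "average over controls");
  the removal rule is strictly greater than 5%.
* `irepEstimate()` sorts non-zero window coverages, assigns normalized
  ranks on the *full* sorted set, trims 5% of windows from each end, and
  fits OLS of $\log_2$ coverage on rank; iRep $= 2^{\mathrm{slope}}$.
  Ranks are deliberately not renormalized after trimming — doing so
  compresses the fitted span by $1 - 2\,\mathrm{trim}$ and biases the
  estimate toward 1 by a factor $\mathrm{iRep}^{-0.1}$ at the default
  trim. All-equal coverages return exactly 1.
* Genome relative abundances are normalized across a sample's genomes by
  default (fraction-over-fraction ratios, comparable to the amplicon
  side); the raw coverage-per-total-reads value is kept alongside.
* Ties everywhere are deterministic: dereplication breaks size ties
  lexicographically; clustering joins the highest-identity centroid, then
  the larger founding size, then the earlier centroid; the denoiser
  prefers the smallest distance, then the largest centroid; mapping
  prefers the larger unit total size.

## Problem sizes used by the test suite

The suite exercises the full pipeline at 150 taxa with $5\times10^4$
reads per pool (ratio recovery, exact denoiser recovery), $10^4$ reads
per pool across error rates 0–0.005 (phantom accounting), $10^5$ reads
per pool (rare-but-active structure), 400 coverage windows at 20× for
iRep, and 200 null datasets at 199 permutations for PERMANOVA
calibration. These sizes were chosen so that every stochastic assertion
has comfortable Monte-Carlo margin while a full run stays convenient on a
single CPU.

## A worked example

```{r example, eval = FALSE}
sc <- simScenario(n_taxa = 40, depth_rdna = 20000, depth_rrna = 20000,
                  seed = 7)
com <- simulateCommunity(sc)
res <- runActivityPipeline(com, sc, method = "ZOTU")
head(res$profile)
overlapSummary(res$profile)$per_sample
logLogCorrelation(res$profile)
tree <- buildUnitTree(unitRepresentatives(res$units))
rarefyMeanAlpha(unitCounts(res$table), "pd", depth = 5000, tree = tree,
                seed = 1)
```

## Known limitations

* Chimera formation and removal are out of scope; `removeContaminants()`
  plus an externally produced blacklist is the only sequence-hygiene
  hook.
* The k-mer/NJ unit tree is a rough substrate; PD and UniFrac values on
  it should be compared *between* methods or samples, not read as
  absolute phylogenetic quantities.
* The rRNA/rDNA ratio itself inherits the field's caveats: ribosomal
  amplification is not uniformly proportional to growth rate across
  lineages, and shallow rDNA sampling inflates apparent ratio extremes —
  the phantom accounting quantifies, but cannot remove, that effect.
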