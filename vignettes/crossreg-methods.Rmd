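---
title: "Projecting, filtering and scoring regulatory regions across genomes"
author: "crossreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting, filtering and scoring regulatory regions across genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossreg)
```

# The problem

Regulatory DNA — promoters, enhancers, transcription-factor binding sites —
controls when and where genes are expressed, and harbours the large
majority of trait-associated noncoding variants. For most mammals almost no
genome-wide experimental maps of these elements exist, while for the human
genome thousands of assays (CAGE transcription-start profiling, H3K27Ac and
H3K4me3 histone-mark maps, TF ChIP) have been aggregated into comprehensive
catalogues. `crossreg` transfers that knowledge: it projects human
regulatory elements onto a target assembly through whole-genome alignment
chains, pools the projections, and filters them with whatever limited
species-specific data are available.

The package deliberately separates three concerns, mirroring how the
analysis is run in practice:

1. **chain model and projector** — coordinate transfer with explicit
   quality control;
2. **dataset operations, features and filters** — building and refining the
   universal dataset;
3. **variant scoring** — a sequence model for prioritising noncoding
   variants inside the predicted regions.

A fourth, first-class component is the **synthetic-data generator**: every
stage of the pipeline is exercised against miniature genomes with exact
ground truth, so correctness does not depend on downloading any external
dataset.

# Coordinate model and projection

A UCSC chain is an ordered list of gapless aligned blocks `size dt dq`
between a source assembly (header `tName`, always `+` strand) and a target
assembly (`qName`, either strand). All coordinates are 0-based half-open.
For a `-`-strand chain the stored target coordinates live on the reversed
sequence; every public answer is converted to forward coordinates
(`size - end, size - start`) with a strand flag, which avoids
double-reversal bugs. Block sums are validated against the header spans on
both sides when a file is parsed, and `invert_chains()` exactly reverses
the per-base map (a property tested by enumeration).

Projection of a region of length $L$ through a chain with $b$ of its bases
inside aligned blocks has coverage $b/L$; the chain passes when coverage
$\ge$ `minMatch`. The projected span runs from the projection of the first
to the last aligned base of the region — not the chain ends — matching the
behaviour of the standard liftOver tool whose thresholds the defaults were
tuned on.

Two-stage mapping (`hprs_map()`):

* **Stage 1 (primary):** `minMatch = 0.2`, single mapping only. A region
  with two or more passing chains is *deferred*, not resolved by picking a
  best chain — strict one-to-one forward mapping is the point of this
  stage. Accepted projections must also back-project (through the reverse
  chains, same 0.2 threshold by default) to within **25 bp of both
  original borders**.
* **Stage 2 (rescue):** everything unmapped, ambiguous or reciprocally
  failed is re-projected allowing multiple targets at `minMatchMulti =
  0.8`. This recovers tandem-duplicated loci: each duplicate copy lies on
  its own chain with full coverage, so stage 1 necessarily calls the
  region ambiguous, and only the stringent multi-mapping round can return
  both copies.

Defaults (0.2, 0.8, 25 bp) are the optimised operating point of the
original mapping protocol; all three are exposed in
`projection_params()`. Two points were genuinely open and are decided
here: the reciprocal back-projection reuses `min_match_main` (one
reciprocal rule, least-surprise reading; `recip_min_match` overrides it),
and rescue hits are *not* themselves reciprocally checked — they are
retained as declared multi-mapping hits.

Multi-mapping output is ordered by coverage, then chain score, then chain
id (descending), so results are byte-reproducible.

# Universal dataset, features and filters

`merge_datasets()` unions regions overlapping by at least one base;
book-ended regions (gap 0) merge too, the common default for interval
merging, exposed as `merge_distance`. Contributing names are collapsed
comma-separated with a dataset-label prefix and counted into
`annotation_count` — the provenance doubles as a filter feature.
"Overlap" throughout the package means one or more shared bases, with no
minimum-fraction requirement.

Per-region features and their aggregation rules:

| feature | source | rule |
|---|---|---|
| `cage_count` | peak BED | peaks sharing >= 1 base |
| `h3k27ac_signal`, `rnaseq_signal` | bedGraph | sum of overlap-length x value (`mean` selectable) |
| `phastcons` | per-base bedGraph | mean over *scored* bases only; 0 + flag when none |
| `annotation_count` | merge provenance | count of contributing regions |
| `tfbs_count` | PWM scan | log2-odds hits on both strands |
| `svm_score` | gapped k-mer model | sequence score (optional) |

Signal thresholds are computed on the `log2(x + 1)` scale because read
counts can be zero; quantiles use linear interpolation between order
statistics (R type 7), fixed and documented because the resolved
thresholds depend on the convention. PWM scanning scores every window with
`log2((p + eps)/(bg + eps))`, `eps = 1e-4` to avoid infinities; a hit
scores at least `rel_threshold = 0.8` of the PWM's maximum achievable
score, and overlapping hits of one PWM on one strand collapse to the best
window. This per-PWM hit counting replaces an HMM-based cluster scorer;
the downstream filter consumes a count either way, and the substitution is
recorded in the filter report column names.

The seven filters and their default parameterisations:

* CAGE: >= 2 peaks, or exactly 1 peak with RNA-seq above the *raw* mean of
  the reference set;
* H3K27Ac: `log2p1` signal >= reference median;
* RNA-seq: `log2p1` signal >= reference 3rd quartile;
* model score: region length strictly < 3000 bp and score >= reference
  median;
* annotation count >= reference 3rd quartile;
* conservation >= reference 95th percentile;
* motif count >= reference **mean** (the median degenerates on real
  reference sets, retaining almost nothing, so the mean is the default).

Filters combine as a **union**: a region is kept if any enabled filter
passes. The released per-filter statistics are always computed
independently against the same input (the `optimize_filter_params()`
protocol); the union reproduces the observed behaviour that the final
filtered set is larger than any single filter's retention. A sequential /
intersection mode is available for sensitivity analysis. Enrichment is
judged by Ratio_E and Ratio_P — reference enhancers (promoters) overlapped
per Mb of retained length — reported to 1 decimal, with fold-vs-genome
baselines rounded to integers, matching the conventions of the source
tables. Whether signals should be length-normalised before thresholding is
left to the caller (`signal_mode = "mean"`); raw sums are the default.

# The gapped k-mer model and deltaSVM

Sequences are represented by counts of gapped words: every $l$-length
window (default $l = 10$) contributes one word for each of the
$\binom{l}{k}$ subsets of $k = 6$ informative positions. Feature ids are
canonicalised under reverse complement by default, since regulatory
activity is strand-symmetric. Windows are scanned on the forward strand
only — with RC canonicalisation this already identifies a motif with its
reverse complement, and it keeps the exact closed form used to test the
extractor: the total feature mass of an N-free length-$L$ sequence is
$(L - l + 1)\binom{l}{k}$.

The classifier is a dual-form ridge model: with sparse feature matrix $X$
and labels $y \in \{\pm 1\}$, the dual coefficients are
$\alpha = (XX^\top + \lambda I)^{-1} y$ with $\lambda = 1/C$. This is a
regularized linear classifier solved in closed form — exactly
deterministic, with no iterative optimiser to seed — and the linear kernel
$XX^\top$ *is* the gapped k-mer kernel, so cross-validation on the
precomputed kernel is essentially free. Stratified 5-fold CV AUC is
reported with every fit. The weight of an l-mer is the model score of its
feature vector; the full $4^l$ table is never materialised — weights are
derived lazily for the l-mers a query needs, which keeps $l = 10$
practical.

deltaSVM of a variant is the sum of l-mer weights over all windows
overlapping the variant in the alternate minus the reference sequence. The
reference context must have length $2(l-1) + |\mathrm{ref}|$ with the
reference allele starting at position $l$; because a sequence's model
score *is* the sum of its window weights, the implementation scores the
two context sequences and subtracts, which makes identity
(`delta(ref→ref) = 0`) and SNV antisymmetry exact by construction. Indels
are handled by the same window-set definition (all l-mers intersecting the
edited span), a generalisation beyond SNVs that reduces to the standard
definition for substitutions.

Training sets pair each positive region with a same-length genomic
placement sampled uniformly among valid positions (excluding positives and
any exclusion set, resampling N-containing draws up to 100 times), so the
negative length multiset equals the positives' exactly. GC-matched
sampling is deliberately not the default: on the uniform-background
fixtures it is unnecessary, and on real genomes the choice should be the
analyst's.

Significance of a deltaSVM score against a genome-wide score distribution
uses the two-sided central-range reading by default: a score at or beyond
the 2.5th/97.5th percentile is flagged, so 5% of a null distribution is
significant. The alternative one-sided |score| reading is available
(`two_sided = FALSE`); which of the two a given published threshold meant
is ambiguous, so both are exposed.

# The synthetic-data generator

`generate_fixture()` builds a source genome of i.i.d. uniform bases
(default two 1 Mb chromosomes), applies a rearrangement plan
(translocation, inversion, deletion, insertion, tandem duplication; by
default one of each per chromosome, 2-6 kb each), and emits the target
genome together with forward/reverse chains *derived from the coordinate
map itself* — never re-aligned — so the ground truth is exact by
construction. Deletions and insertions become `dt`/`dq` gaps inside the
main colinear chain; inversions, duplicate copies and translocations
become chains of their own. Target chromosomes are named `chr1T`,
`chr2T`, ….

Planted regulatory regions (promoter-, enhancer- and TFBS-like; lengths
150-600 bp) avoid event boundaries except where a scenario is being
exercised: one enhancer inside every inversion (expected `-` strand), every
duplication (expected rescue, two targets) and every deletion (expected
unmapped). Half the promoters/enhancers are "active": they receive a
planted 8-bp motif consensus, clustered CAGE peaks, and H3K27Ac / RNA-seq
signal elevated 8-fold over an exponential-noise background; conservation
is elevated over all planted regions. Half of the active regions per class
form the species-specific "reference" sets used to resolve filter
thresholds, playing the role a liver histone-mark reference plays on real
data. The SNP table plants motif-disrupting SNVs inside active enhancers
(small p-values) on a neutral background.

What the generator does **not** emulate: realistic base composition,
substitution/indel evolution within aligned blocks (aligned segments are
identical up to strand), repeat structure, GC heterogeneity, tissue
specificity, and any correlation structure between assays beyond the
planted activity flag. Passing tests therefore demonstrate that the
*algorithms* are correct and that parameter recovery works when the signal
matches the model's assumptions — not that the defaults are optimal for
any particular real genome pair.

Everything is a deterministic function of the configuration seed;
regeneration is byte-identical, which the tests assert file by file.

# Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7) everywhere.
* PWM log-odds pseudo-frequency `eps = 1e-4`.
* Regions with no scored conservation base get 0 and a flag rather than
  NA, so filters treat them as failing conservation.
* Zero-length intervals and unknown chromosomes are errors at the
  projection boundary; rejection during reciprocal validation is a result
  (with a reason), never an error.
* Multi-map ties are broken by coverage, then chain score, then chain id.
* SNP positions are 1-based on input and converted at the boundary;
  BED/bedGraph/chain coordinates are 0-based half-open on disk. In memory,
  region containers are `GRanges` (1-based closed, the Bioconductor
  convention) and the projection layer works in 0-based half-open
  coordinates; conversions happen only at these two boundaries.
* Training requires at least 20 sequences per class and errors on
  single-class input; the `C` parameter maps to ridge penalty `1/C`.

# Problem sizes used by the test and acceptance runs

The shipped test suite uses a 2 x 200 kb fixture genome for projection and
filtering checks, a seed-7 fixture of 2 x 2.5 Mb with 2,000 planted
regions for the enrichment-recovery benchmark, and a seed-11 planted-motif
benchmark of 200 positive + 200 negative 100-bp sequences (an 8-bp
consensus planted uniformly at random in positives) for the classifier.
These sizes were chosen so that every planted effect is comfortably
detectable while the whole suite stays desk-scale; the same conditions are
recomputed end-to-end by `scripts/acceptance.R`.

# Known limitations

* Results depend entirely on the chain set supplied; the package accepts
  any chain file and does not build or net chains itself. Whether to use
  reciprocal-best-filtered chains is the caller's decision.
* The filter cascade requires a species-specific reference set; with a
  poor or tiny reference the resolved thresholds are noisy, and the
  95th-percentile conservation filter in particular becomes erratic below
  a few dozen reference regions.
* Genome-scale runs (hundreds of thousands of regions through megabase
  chain sets) are beyond the intended desk-scale envelope of this pure-R
  implementation; the per-region projection loop is linear in the number
  of overlapping chains.
* The gapped k-mer model is trained on counts through an exact kernel;
  for training sets far beyond ~10^3 sequences the dense kernel solve
  would need replacing with an iterative solver.
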