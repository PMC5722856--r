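---
title: "Methods: windowed methylation blocks, isochores, and accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed methylation blocks, isochores, and accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models, the tunable parameters and why their defaults are what they
are, the numerical conventions, what the synthetic-data generator does and
does not emulate, and the design choices made where more than one
reasonable reading existed.

## Coordinates and the window grid

All coordinates are 0-based, half-open (BED convention); readers convert
1-based inputs at the boundary. A genome layout (chromosome names and
lengths) deterministically induces the analysis grid of consecutive,
non-overlapping 100-bp windows. The trailing partial window of each
chromosome *is* emitted (ceiling tiling), as genome-tiling tools do; with
GRCm38/mm10 lengths this yields about 27.26 million windows, and the choice
between ceiling and floor tiling is immaterial to the three-significant-
figure value of the analytic ratio bound below. The TSS of a '+' gene is
its annotated start; for a '−' gene it is `end − 1` (the last transcribed
base), a convention the annotation itself does not force and which is
therefore documented and tested. The TSS regulatory window spans 1500 bp
upstream to 500 bp downstream, oriented by strand and clipped at chromosome
ends.

## The windowed differential count test

The per-window (and per-gene, per-isochore) two-group test is deliberately
self-contained rather than a wrapper around an external fitter, so its
behavior is fully specified here:

1. Features with total raw count below `min_row_sum = 10` across all
   samples are removed (inclusive boundary).
2. Samples are quantile-normalized: every column receives the mean of the
   per-sample sorted values; ties get the mean of the reference values over
   their rank span, so tied inputs stay tied. The transform is idempotent
   on tie-free data.
3. A single common negative-binomial dispersion φ (variance μ + φμ²) is
   moment-estimated: per feature, φᵢ = (pooled within-group variance −
   μ)/μ², floored at 0, averaged across features. A common dispersion is
   the right bias/variance trade-off at n = 4 per group; tagwise shrinkage
   is out of scope.
4. Each feature is scored with the exact conditional NB test: with n
   samples per group, the group sum is NB(nμ, size n/φ); conditional on the
   total, the treatment sum has a distribution free of the NB probability
   parameter, evaluated by direct enumeration of the support (cached per
   distinct total, since the conditional law depends only on the total,
   the group sizes and φ).
5. Two-sided p-values double the smaller **mid-p** tail (half of the
   observed outcome's probability in each tail), capped at 1. Plain tail
   doubling is measurably conservative at these counts — on null data a
   Kolmogorov–Smirnov test against the uniform rejects it — while the
   mid-p version passes the package's calibration tests and leaves a
   feature with identical counts in every sample at exactly p = 1.

p-values are **not** multiplicity-adjusted anywhere in the chain; the
methodology thresholds raw p (0.001 for methylation windows, 0.05 for
genes and isochores), and the block/permutation machinery downstream is
what controls interpretation.

## DMRs, mDMRs, the ratio curve, and isoDMBs

DMRs are grid windows with `p < α`, tagged hyper (treatment coverage above
control) or hypo. A window significant with an exactly zero normalized mean
difference is rejected as inconsistent input rather than silently tagged.
Merging grid-adjacent same-direction DMRs gives mDMRs. The ratio
`R(p) = |mDMR|/|DMR|` is bounded below by
(number of chromosomes)/(number of windows) — every window significant in
one direction per chromosome — which is `8.07e-7` on the mouse grid.

"The ratio starts to decrease consistently" is operationalized as: walking
from the largest grid p downward, p\* is the end of the longest run over
which R strictly decreases at every step; if the very first step is not a
decrease the smallest grid p is returned with a warning. The original
choice was made by inspection, so the full curve is always returned for
human review and the threshold is overridable in the pipeline
configuration. The default grid {0.1, 0.05, 0.01, 0.005, 0.001} is ours;
only its endpoints are anchored.

isoDMBs are maximal same-direction runs of DMRs along a chromosome,
regardless of gaps; a block spans from the start of its first DMR to the
end of its last. We do not extend spans beyond the terminal DMRs (e.g. to
midpoints between blocks): the definition reads as DNA *comprised by* the
member DMRs, and terminal-DMR spans make |isoDMB| ≤ |mDMR| ≤ |DMR| and the
direction-alternation invariant exact.

## Expression integration

Expressed genes are those with nonzero counts in at least three replicates
of *each* group; abundance is counts per million of library size. Subset I
genes have a DMR overlapping the TSS window; Subset II genes have a DMR in
the gene body, or are one of the two nearest genes bounding the intergenic
interval containing a DMR ("flank" is otherwise undefined in the
methodology; the two-bounding-genes reading is minimal, and a fixed-width
alternative can be layered on by callers); Subset III genes overlap an
isoDMB. Subsets I and II are computed independently — neither contains the
other by construction.

The bias index ranks |treatment − control| differences within the subset
(not genome-wide), signs the ranks, sums them and normalizes by n(n+1)/2.
Ties get average ranks. Zero differences keep zero-signed average ranks —
they stay in n and in the normalizer — rather than being dropped as in the
classic Wilcoxon procedure; both conventions are exposed
(`drop_zeros`) and covered by tests, and the default preserves the
"fraction of the maximum possible bias" reading of B. The permutation null
redraws, independently within each chromosome, the same number of subset
genes uniformly without replacement from that chromosome's expressed
genes; `p_upper`/`p_lower` are the fractions of permuted indices at least/
at most the observed one (no +1 smoothing — the published definition is
reported as stated, so a Monte Carlo zero is printed as 0).

The coherence test asks whether isoDMBs holding ≥ 2 DEGs have
direction-consistent DEG sets: observed fractions per block direction, and
a null that relocates the DEG tags (up/down kept attached) among expressed
genes within chromosomes. Gene-set enrichment is the upper-tail
hypergeometric with BH correction across sets; ontology data is
caller-supplied (GMT), never queried from a service.

## Isochores

Input is a 1-kb percent-GC track (from FASTA via `gc_track_from_fasta()`,
N bases excluded from the denominator, or any equivalent table). Recursive
binary segmentation evaluates, within each segment, the cut maximizing the
pooled-variance two-sample t statistic between left and right bin means.
Because that cut is a maximizer over all admissible positions, its naive
p-value is Šidák-corrected for the number of candidate cuts scanned before
comparison with `split_alpha = 0.05`; without this correction homogeneous
DNA is split almost surely, with it a homogeneous chromosome stays whole.
Cuts must leave both children ≥ 10 kb and ≥ 2 bins. This is a simplified
stand-in for full isochore-calling recipes (no coarse-graining filters);
class boundaries follow the standard five-class convention
L1 < 37 ≤ L2 < 41 ≤ H1 < 46 ≤ H2 ≤ 53 < H3 (% GC), of which only the H2
range is anchored in the methodology being reproduced — the others are the
field's convention, not recovered values.

## Interval overlap

The Jaccard index is base-pair intersection over union after merging each
set internally, hence invariant to fragmentation. The Monte Carlo null
relocates each query interval to an independent uniform start on its own
chromosome, preserving lengths and chromosome assignment; only the query
set is shuffled by default (an option shuffles both), and shuffled
intervals may overlap one another — rejection sampling for non-overlap is
deliberately not the default since nothing in the methodology forbids
overlap among randomized locations.

## Isochore-guided accessibility

Samples fail QC when in-region depth is below 1500 reads or efficiency
(in-region/total reads) is below 0.15 — strict inequalities, so the
boundary values pass. DAIs are isochores significant at raw p < 0.05,
accessible when treatment coverage is higher, inaccessible when lower.
Class-fraction significance permutes direction tags among significant DAIs
with class labels fixed; the cross-generation shared-DAI fraction counts
isochores significant in both generations with equal direction over
isochores significant in both (the denominator is ambiguous in the source
methodology; the union alternative is an option), with tags permuted
within each generation independently.

Sample clustering replaces a chromVar-style deviation analysis with a
documented simplification: library-size-normalized counts; a per-feature
variability score sd/sqrt(mean) (≈ 1 under Poisson noise) thresholded at
1.5; greedy pruning of feature pairs with |r| > 0.9 (keep the lower
index); per-feature z-scores; sample–sample Pearson correlations with the
diagonal set to 0; average-linkage clustering on 1 − r cut at two
clusters; chi-square without continuity correction (df = 1) for treatment
× cluster, with Fisher's exact p reported alongside because the tables are
small; generation subcluster tests when the first test is significant.
At the simulator's sequencing depths the NB overdispersion keeps every
feature above the variability threshold, so the filter only bites on
flatter real data — an acknowledged difference from the bias-corrected
chromVar deviations, which are not recoverable from the methodology text.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions under which the pipeline is validated. Defaults: 3 chromosomes
of 5 Mb; isochore segments with exponential lengths (mean 300 kb, min
10 kb) and class probabilities (.18, .27, .25, .20, .10) for L1..H3 —
roughly mammal-like with enough H2 footprint to guide the accessibility
analyses; per-segment GC means (32, 39, 44, 49.5, 56)% with 1.5% bin noise;
800 non-overlapping genes (lognormal lengths, median 10 kb) placed with
per-class density weights 1:2:4:6:8 from L1 to H3; methylome NB mean 10
per window times a monotone GC proxy g(GC) = 0.5 + GC/100, dispersion 0.1,
4 replicates per group; planted methylation domains of 500–800 kb, two per
direction per chromosome, anchored (85%) on AT-rich segments for
hypermethylation and GC-rich segments for hypomethylation, with treatment
means ×2 (hyper) or ×0.5 (hypo); RNA counts with lognormal baselines,
dispersion 0.05, and +1 (hypo) or −1 (hyper) log2 fold changes planted
with probability 0.6 for genes inside blocks; ATAC counts of 5 reads/kb
per isochore, dispersion 0.01, 6 replicates per group per generation, with
60% of each class's isochores affected (×0.7 for H2/H3, ×1.3 for L1/L2)
and half of each generation's affected set shared with the other.

Two scale-driven choices deserve their reasoning spelled out. First, the
planted blocks are domain-sized (500–800 kb) because false-positive DMRs
at α = 0.001 occur about every 100 kb on a 15-Mb genome, and a recovered
block's span extends to the last same-direction false positive before an
opposing DMR; domains must dominate that length scale for span recovery to
be meaningful, which also matches the domain-scale reading of the block
concept. Second, the ATAC dispersion (0.01) and depth (5 reads/kb) are at
the clean end of what replicate concordance can look like, because with
only ~60 isochores a desk-scale genome offers far fewer features than the
thousands a genome-scale analysis aggregates; the per-feature
signal-to-noise has to carry what feature count otherwise would.

What the generator does *not* emulate: read-level artifacts (GC
amplification bias beyond the monotone proxy, duplicates, fragment-size
structure), CpG-density-dependent MBD capture, correlated window noise
within fragments, batch effects, and biological heterogeneity between
animals beyond NB dispersion. Passing recovery tests therefore demonstrate
that the machinery is correct and calibrated under its assumed model — not
that the assumptions hold on any particular real dataset. One realistic
artifact it *does* reproduce: quantile normalization under an asymmetric
global shift (hyper ×2 adds more mass than hypo ×0.5 removes) biases null
windows slightly toward hypomethylation calls, which is why hypomethylated
block recovery is consistently the weaker direction in the tests.

## Power analysis

Two-sample t-test power uses the noncentral t exactly: df = 2n − 2,
noncentrality d√(n/2), power = P(T′ > t₁₋α/tails); the wrong-tail mass of
the two-tailed test is ignored (it is negligible for the d values of
interest). The minimum n is found by integer search from 2. The source
methodology's power text is internally inconsistent (it fixes β = 0.05 yet
quotes a power of 0.8 in the same breath) and never states the tails
convention; power and tails are therefore explicit parameters, defaulting
to two-tailed. At d = 1.47, α = 0.05, power 0.8 the one-tailed search
gives 7 per group — matching the printed "≥ 7" — and the two-tailed
default gives 9, consistent with the printed bound.

## Determinism, seeds and problem sizes

Every randomized routine takes an explicit seed; the pipeline derives one
RNG stream per stage from (global seed, stage name), so stages rerun
independently and a rerun of the same configuration is byte-identical.
Monte Carlo defaults are 10,000 permutations; the test suite uses 2,000 to
5,000 where the quantities compared have standard errors well inside the
asserted margins, and the calibration checks use 200 p-values per test, as
stated in their assertions. The default synthetic dataset (seed 1) is the
configuration on which all recovery checks run.

## Known limitations

* The common-dispersion exact test is slightly conservative for features
  with very large counts when dispersion is moment-estimated from few
  features (the DAI calibration check sits closest to that edge).
* `select_threshold()` encodes one reading of "starts to decrease
  consistently"; on low-power data the ratio curve can rise toward strict
  thresholds, in which case the fallback (smallest grid p, with a warning)
  applies and the curve itself is the deliverable.
* Isochore segmentation is not a reimplementation of any published caller;
  it recovers planted class structure but makes no claim of coordinate
  agreement with published mouse isochore maps.
* The clustering scheme is a transparent stand-in for chromVar's
  bias-corrected deviations, adequate for the assortment chi-square tests
  it feeds, not for fine-grained deviation scores.
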