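---
title: "Methods: fragment-resolution TAD analysis with planted-truth validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-resolution TAD analysis with planted-truth validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`tadscape` analyses restriction-fragment-resolution Hi-C maps of compact
genomes (the motivating system is *Drosophila melanogaster* S2R+ cells
digested with DpnII, whose fragments have a median length of about
194 bp). It covers the full path from fragment-level contact lists to:

* ICE-balanced sparse contact matrices with map-resolution and
  replicate-correlation QC;
* dynamic-programming annotation of topologically associating domains
  (TADs) at fragment resolution and of super-TADs at 20 kb, with a
  read-desert fallback;
* insulator-protein enrichment at TAD borders against a shuffled
  background, and pair-site (BEAF-32/CP190, BEAF-32/Chromator)
  co-localization;
* logistic-regression prediction of border fragments with ROC/AUC;
* k-means chromatin-state typing of TADs and the super-TAD localization
  contrast;
* distance-normalised intra- and inter-TAD contact metrics
  (condensation, neighbour enrichment, super-TAD contrast).

Because the source data for such a study are hundreds of millions of read
pairs, validation is built on a seeded synthetic generator
(`synthetic_design()` and friends) that plants known nested domain
structure, boundary-bound insulator peaks and typed chromatin marks, and
on small closed-form or brute-force oracles.

# The contact-matrix layer

Coordinates are 0-based and half-open throughout, as in BED. A
`fragment_map` partitions each chromosome into restriction fragments;
`digest_genome()` produces one from sequence by cutting 5' of each motif
occurrence (the DpnII convention for GATC; any consistent convention
shifts all fragments identically). Contacts are binned onto fragments by
position, and onto fixed bins by fragment midpoint — midpoint assignment
is unambiguous for fragments straddling bin edges.

ICE balancing estimates a positive weight per row such that balanced rows
have equal sums; we iterate the classical correction (divide by the
normalised row-sum vector) until the maximal relative deviation falls
below `tol` (default 1e-5, at most 200 iterations). Rows with zero
coverage are masked; no additional low-coverage filter is applied by
default, so at full fragment resolution the iteration may stop at the cap
with a per-mille-level residual spread — this is flagged (`converged`
attribute and a warning), never silent, and is the expected behaviour for
unfiltered fragment-level matrices containing many single-count rows.
On filtered or binned matrices convergence is fast; planted
multiplicative biases drawn log-uniform on [0.5, 2] are recovered to
r > 0.999.

Map resolution follows the convention of the highest-resolution in situ
Hi-C studies: the smallest bin size at which at least 80% of bins
accumulate at least 1000 contacts.

# Domain annotation

## The quality score

For an interval `[k, l]` of one chromosome the scaled density is

$$q_\gamma(k,l) \;=\; \frac{z(k,l)}{(l-k)^\gamma},$$

where `z` is the sum of balanced contacts with both ends in the interval,
excluding the diagonal. Self-ligation (diagonal) counts are excluded
deliberately: they carry no information about cross-locus structure, and
because every covering segmentation contains the same diagonal mass,
including them only rewards dividing that mass by the smallest possible
span — i.e. arbitrarily fine tiling. `domain_quality()` also reports
`mu(d)`, the exact mean of `q` over all intervals of span `d`, and the
mean-centred score `q - mu`.

## The segmentation DP and the two scorings

`call_domains_dp()` maximises, over non-overlapping intervals with gaps
allowed, the sum of positive interval scores. Two scores are available:

* `centering = "none"` (default): the raw scaled density `q`. All
  candidate intervals score positive, so the optimum tiles the covered
  genome and `gamma` alone sets the scale — small `gamma` merges
  (at `gamma = 0` a whole chromosome is one domain, since the cross term
  always favours merging), large `gamma` splits. Cut points lock onto
  contact-depletion boundaries.
* `centering = "mean"`: the mean-centred score `q - mu`. This is the
  classical quality normalisation and is what the package reports per
  domain; as a *sum* objective, however, it rewards selecting
  above-average intervals and skipping the rest. On noisy or
  heterogeneous data the optimal solution cherry-picks fluctuation
  maxima: on the default synthetic design it fragments the annotation to
  ~60% coverage with contiguity ~0.3 at any gamma, and even at
  `gamma = 0` it never merges into chromosome-scale domains. It remains
  available because on strongly block-structured, low-noise matrices it
  recovers exactly the dense blocks.

Both modes are verified against exhaustive enumeration of all valid
segmentations on random dense matrices (n <= 12): the DP objective equals
the enumeration maximum exactly. Ties are broken towards fewer domains,
then leftmost starts; the score is invariant under global scaling of the
matrix.

## Gamma and scale

The gamma that yields domains of a given physical size depends on the
shape of the contact distance decay. Real restriction-fragment fly maps
have a shallow short-range decay and are annotated at TAD scale
(median 13 kb) near `gamma = 0.9`, which is the `caller_config()`
default. The synthetic generator uses a pure power law `d^-1` (the
classical mid-range regime), under which the TAD-scale window sits near
`gamma = 0.15`; `run_config()` therefore defaults to 0.15 for the
synthetic pipeline. At `gamma = 0.9` on synthetic data the optimal tiling
is finer than the planted TADs, but its cut points still lock onto every
planted boundary (exact-match recovery ~0.94 against a ~0.47 chance
density) and the annotation is near-contiguous — validation at the
study's gamma therefore probes boundary recovery, while scale-matched
gamma probes the size geometry.

`min_domain_bins` is 2; `max_span_bins` defaults to 600 (about 120 kb at
fragment resolution) to bound the quadratic memory of the interval
table, and can be lifted for small matrices.

## Read-desert fallback

Fragment-resolution maps contain runs of zero-coverage fragments whose
edges can masquerade as domain borders. When any called boundary lies
within one bin of a run of at least `desert_min = 3` masked bins, the
whole chromosome is re-annotated at `gamma_fallback = 0.6` (a coarser
scale less prone to desert-edge cuts) and the annotation replaced; the
triggering regions are reported.

## Super-TADs

At 20 kb resolution the map decomposes into super-TADs (dense blocks of
several TADs with elevated cross-TAD contact) separated by
inter-super-TAD regions. `call_supertads()` tiles the balanced 20 kb
matrix with the same DP, then classifies each tile by its internal
distance-normalised enrichment — super-TAD tiles sit above the
genome-wide expectation at matched separations — splitting the clearly
bimodal tile-enrichment distribution by 1-d 2-means on the log scale,
and merges adjacent super tiles. The segmentation DP alone, in either
scoring, does not localise super-TADs on the synthetic data (the 20 kb
contrast after balancing is only ~1.3-1.5-fold), whereas the
tile-then-classify route recovers the planted super/inter partition for
~85% of in-super TADs. TADs are then assigned to super-TADs or
inter-super-TAD regions when at least 75% of their length overlaps the
region (`nest_domains()`).

# Boundary statistics

Boundary centers are junction midpoints between adjacent domains. The
enrichment of an occupancy track at boundaries is the per-window mean
over +-4 kb of each center (80 bp windows, 100 windows) divided by the
same profile for centers re-drawn uniformly over each chromosome
(per-chromosome counts preserved; 100 shuffles by default, seeded).
Windows with zero background are flagged rather than infinite. With
uniformly random peaks the central-window ratio is calibrated (within
[0.8, 1.25] in >= 95% of seeded simulations at 200 borders / 1000 peaks /
10 Mb).

Pair sites are anchor-protein peaks lying within `max_gap = 200` bp of a
partner-protein peak (the spatial definition of a "pair" is not fixed by
convention; 200 bp is fragment-scale co-occurrence and is exposed as a
parameter). Co-localization uses the 2 kb rule in both directions —
borders with a site within 2 kb, and sites within 2 kb of a border — each
border counting once however many sites qualify. Enrichment over the
shuffled expectation is tested with a two-sided Fisher exact test on the
hit/miss table (verified in tests against direct hypergeometric
enumeration).

# Border prediction

Per-fragment marker signals (mean of a track over the fragment) are
Z-transformed per column with the population-SD convention — dividing by
the root-mean-squared deviation, so that `(1, 2, 3)` maps to
`(-1.2247, 0, 1.2247)`. Fragments containing a boundary center are
labelled 1, all others 0. Because border fragments are ~1-2% of all
fragments, negatives are subsampled to the positive count by default
(seeded) before an equal random train/test split. The model is
maximum-likelihood logistic regression with a weak ridge penalty
(`lambda = 1e-3` via glmnet) for stability on separable data; AUC is the
normalised Mann-Whitney statistic with half-credit for ties, which makes
it invariant under strictly increasing transforms of the scores and
exactly reproducible.

# Chromatin typing and interaction metrics

Per-TAD mark enrichment is the mean of the genome-wide Z-scored track
(weighted by interval width) over the TAD. TADs are clustered with
k-means (k = 8, k-means++ initialisation, 10 restarts, fixed seed; the
within-cluster sum of squares is recorded each Lloyd iteration and is
non-increasing by construction — this per-iteration trace is why the
algorithm is implemented in the package rather than delegated, with
`stats::kmeans` as an independent cross-check in the tests). A cluster's
major type is the mark group (active / inactive / polycomb) with the
highest mean centroid Z if that mean exceeds `tau = 0.5`; ties and
sub-threshold clusters are "undetermined". The default 15-mark panel and
grouping are conventional stand-ins; users supply their own mapping.

The distance-decay expectation is the mean balanced contact over all
unmasked same-chromosome fragment pairs in 200 bp separation bins,
computed per chromosome (chromosome arms decay differently). Intra-TAD
condensation is the mean balanced contact over intra-TAD fragment pairs,
excluding zero-ligation fragments; cross-type comparisons are restricted
to TADs of 5-20 kb. Pair enrichment between two domains is the mean of
observed/expected over their fragment pairs; on a matrix whose entries
equal their distance expectation this returns exactly 1, and a planted
2-fold cross-block boost is recovered within sampling error.

# The synthetic generator

`synthetic_design()` fixes the study conditions; every generator is a
pure function of the design and a seed.

* **Genome and fragments.** 10 Mb over two chromosomes; fragment lengths
  geometric with median 194 bp, truncated to tile each chromosome.
* **Domain geometry.** Chromosomes are tiled by alternating super-TAD
  blocks (5-10 TADs, log-normal sizes, median 16 kb) and inter-super-TAD
  strings (2-5 TADs, median 9 kb), every edge snapped to a fragment
  boundary. This reproduces the published size medians of the motivating
  system: super-TADs ~140 kb, inter-super-TADs ~40 kb, TADs ~13 kb
  overall, near-complete genome coverage. (The alternative reading of
  the published per-super TAD counts — 2-4 TADs of 16 kb per super-TAD —
  is arithmetically incompatible with a 140 kb super-TAD median and was
  dropped.)
* **Contacts.** Pair intensity is `d^-alpha` (alpha = 1) times a 4-fold
  within-TAD boost, a 2-fold within-super-TAD (cross-TAD) boost, and
  type-pair boosts for adjacent TADs (inactive-inactive and
  polycomb-polycomb 1.5, active-active 0.67 by default — the directions
  reported for the motivating system). Counts are independent Poisson
  draws scaled to an expected depth of 2e7 (2 contacts per Mb of genome
  per million, matching the per-Mb depth of the study's 353 M valid
  pairs over 130 Mb). Pairs beyond 300 kb are not sampled: under `d^-1`
  their intensity is negligible for domain-scale analyses and no
  reported quantity depends on them. An optional multiplicative
  fragment bias (log-uniform [0.5, 2]) exercises ICE.
* **Peaks.** Each planted boundary carries a border element — a BEAF-32
  peak plus a CP190 or Chromator partner — with probability 0.77 (the
  published pair co-localization rate), plus, with probability 0.65, a
  lone peak of one protein (so that >91% of borders carry at least one
  protein without manufacturing spurious pairs), plus uniform background
  peaks at 100 per Mb per protein. Border peaks are jittered (sd 100 bp);
  occupancy tracks are boxcar-smoothed peak densities (3 kb half-width,
  a realistic occupancy-smoothing scale that also gives the
  enrichment-null calibration its intended sampling precision at the
  stated 200-border / 1000-peak design).
* **Marks.** 500 bp bins; inside a TAD of type T the marks of T's group
  have mean `mark_effect = 3` Z units, all others 0, unit noise.

What the generator does *not* emulate: ligation-noise structure
(trans contacts, self-circles), coverage-dependent mappability, the
shallow short-range decay of real fragment maps (see the gamma
discussion), replicate-level overdispersion beyond Poisson, and peak
width/intensity distributions of real ChIP data. Passing the planted
tests therefore demonstrates the correctness and calibration of the
machinery, not the biological accuracy of any default parameter.

A note on the condensation-parity check: in the default geometry the
chromatin type is correlated with TAD size by construction (super-TADs
are inactive-rich with 16 kb TADs; inter-super-TADs active-rich with
9 kb). Since condensation declines with domain size through the decay,
a type contrast within the 5-20 kb band is then a true positive. The
calibration check for equal planted boosts therefore uses a design with
type frequencies balanced across block kinds, making type
size-exchangeable under the null.

# Numerical choices and limitations

* DP tie-breaking: fewer domains, then leftmost starts, with a relative
  tolerance of 1e-9 of the score scale, preserving scale invariance.
* ICE: tolerance 1e-5 on the relative row-sum deviation, 200 iterations,
  non-convergence flagged; masked rows get `NA` bias.
* Shuffled backgrounds, subsampling, splits, k-means, bootstraps and
  permutation tests all require explicit seeds; re-running the pipeline
  with the same configuration reproduces the report bit-for-bit on one
  platform.
* Problem sizes in the validation suite: the planted-recovery runs use
  the full default 10 Mb design; calibration loops (enrichment null,
  feature-ranking, parity) use 1.5 Mb genomes with proportional depth,
  which keeps every planted effect several standard errors wide.
* The package does not call corner peaks/loops (reported absent in the
  motivating system), compartments, or anything requiring read-level
  processing — input starts at fragment-level contact lists.
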