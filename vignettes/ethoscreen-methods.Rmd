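---
title: "Methods: behavioral stratification of fly disease models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral stratification of fly disease models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoscreen)
```

`ethoscreen` implements a full behavioral-phenomics stratification
pipeline for *Drosophila* disease models: multi-day positional traces are
annotated into movement and sleep states, summarized as
sleep-architecture features and per-minute ethograms, decomposed by
non-negative matrix factorization (NMF) into shared temporal components,
and clustered into genotype groups. An independent electroretinogram
(ERG) based genetic-interaction (GI) screen is scored under a
multiplicative non-interacting model, both with a frequentist threshold
rule and with a Bayesian highest-density-interval (HDI) rule, and the
concordance between behavior-defined and interaction-defined groupings is
quantified by Jaccard similarity against a permutation null. A
synthetic-data generator with known ground truth makes every stage
testable without recordings.

## Sleep annotation and features

Recordings are expected at a fixed frame rate (2 frames/s by default)
over several light:dark days. The annotation grid is 10 s, half-open
`[start, start + 10 s)`, anchored at experiment start. A window is
*moving* when any frame-to-frame Euclidean displacement inside it is at
least 0.25 mm; immobility is "less than 0.25 mm". The dimensionless
corrected velocity `v = displacement / (dt * fps * a)` with the
empirical correction factor `a = 0.0042` is carried per window; a zero
displacement maps to `v = 0` by convention since its log-distance is
undefined. Windows without frames (tracking gaps longer than one
interval) are marked missing and excluded from every denominator — never
interpolated.

Sleep follows the 5-min rule: a maximal run of immobile windows longer
than 300 s is a sleep bout, and all of it counts as sleep, including the
first five minutes. Flies immobile continuously from some onset to the
end of the recording for at least 24 h are flagged dead and censored
from the onset; the first recording day is always discarded as
habituation. The 24-h death window is the conventional choice of
sleep-analysis frameworks for this assay; it is a parameter of
`detect_death()`.

Per-fly features are pooled over the retained light and dark cycles:
sleep fraction per light condition, latency from lights-off (ZT12) to
the onset of the night's longest bout, bout count and mean bout length
per night (bouts clipped to each dark period, so a bout spanning
midnight contributes one segment per night), mean speed over moving
windows, and total distance per 24 h. Pooling across nights weights each
night by the fraction of it retained after quality control; the
alternative (unweighted night means) differs only when nights are
censored asymmetrically. Latency for a night without any bout is
censored at the full night length (720 min in 12:12). Morning
anticipation is the activity (moving-window count) in the final 3 h of
darkness divided by the activity in the final 6 h: 0.5 is flat, above
0.5 indicates an anticipatory ramp. This last-3/last-6 index is one of
several conventions in circadian work; it is isolated in
`morning_anticipation()` so it can be swapped.

## Temporal ethograms and NMF

`build_vector()` summarizes each fly as 1440 one-minute clock bins
(24 h x 60 min). A window contributes the indicator that its *strictly
preceding* 5-min period was at least 99% immobile — with 30 windows of
10 s per 5 min this requires all 30 preceding windows immobile — and
each bin holds the mean indicator over the retained days ("time spent
sleeping" aggregation). A discrete Gaussian blur with `sigma = 5` bins
smooths adjacent bins. Edge handling reflects by default, matching the
common image-filter implementation; a periodic option is available since
clock time wraps at midnight and conserves total mass exactly.

The blurred vectors of all flies form a non-negative matrix
`M (1440 x l)` factorized as `M ~ W H` with `W >= 0` (temporal
components) and `H >= 0` (per-fly encodings). The factorization uses
Lee–Seung multiplicative updates under the Frobenius objective, with a
deterministic NNDSVD initialization plus five seeded random restarts
(best objective kept), 500 iterations maximum and a relative objective
tolerance of `1e-6`. Explained variance is reported as
`1 - RSS / TSS` with the total sum of squares taken around column
(per-fly) means; the scale of the vectors (fractions in `[0, 1]`) is
irrelevant to the factorization up to a factor. The number of
components is chosen by an operationalized elbow: the k maximizing the
curvature (most negative discrete second difference) of the
explained-variance curve; a curve with no concavity beyond `0.005`
falls back, with a warning, to the smallest k whose marginal gain is
below 0.02. The Calinski–Harabasz index evaluates the clustering
obtained by assigning each fly to the largest entry of its encoding
column; assigning by encoding (a column of `H`) rather than by a time
bin of `W` is the only reading under which the cluster rule is
well-formed, since `W`'s rows index time bins.

## Genotype clustering, PCA and stability

Per-genotype means of the behavioral features and of the NMF encodings
are joined; morning anticipation is excluded from clustering because it
is strongly correlated with the temporal components by construction.
Columns are z-scored with the sample (n-1) standard deviation — a
zero-variance column is an error, not silently dropped. Genotypes are
clustered on correlation distance `1 - Pearson` with WPGMA (McQuitty)
linkage, via `stats::hclust`; the profile matrix of the GI screen is
clustered the same way but on Euclidean distance. PCA is computed on
the already-scaled matrix with centering only, so scaling is applied
exactly once; variance fractions are the squared singular values over
their total, and each feature's `cor^2` with each PC is reported.

Cluster stability is assessed leave-one-feature-out: drop a column,
re-scale, re-cluster, cut at the reference number of subgroups, and
record each reference subgroup's best-match Jaccard similarity with the
new groups (the matching rule is max over new groups, the natural
choice when no correspondence is given). Similarities are binned into
0–0.34, 0.35–0.69 and 0.7–1, with 0.35 the threshold for substantial
overlap.

## Genetic-interaction scoring

ERG depolarization amplitudes are normalized to the mean control
amplitude of their batch, cancelling batch gain. The non-interacting
expectation for a double mutant is the product of the two normalized
single-mutant means; the GI strength is the observed normalized double
amplitude minus this expectation (per replicate, averaged per pair). A
pair interacts when `|strength| >= 0.3`; positive strengths (milder
phenotype than expected) are *alleviating*, negative ones (lower
depolarization, worse phenotype) *aggravating*. The sign convention is
stated explicitly because the classes are otherwise only defined
pictorially. Classification uses the pair's mean strength; replicate
strengths are retained for the Bayesian analysis. Untested self-pairs
sit on the profile-matrix diagonal and are set to 0 for clustering
(`NA` to exclude them is available).

## Bayesian interaction model

Per pair, the single-mutant fractions have scaled-Beta priors
`alpha, beta ~ 1.05 * Beta(2, 5)`: support just above 1 allows minor
increases over control, and the asymmetry favors fractions nearer 1;
the prior mean is 0.30. The additive interaction term has a
`Normal(0, 1)` prior — weak information about whether the pair
interacts. The double mutant contributes `alpha * beta + iota`. The
observation model is a package decision: replicates are Normal around
their genotype's contribution with per-genotype `HalfNormal(0.2)` scale
priors, weakly informative on the normalized scale; it is isolated in
`build_gi_model()` so it can be swapped. Sampling uses JAGS with, by
default, 4 chains of 2000 post-warmup draws after 1000
warmup/adaptation iterations; chain seeds derive from one user seed and
a split-R-hat above 1.01 triggers a warning. The 95% HDI is the
narrowest interval containing 95% of the pooled post-warmup draws
(sliding window over the sorted sample); the pair is called interacting
when 0 falls outside it.

## Partition concordance

Jaccard similarity (intersection over union) compares gene groups. The
permutation test asks how often a behavior-defined group resembles a
random gene set at least as much as it resembles a real GI group: each
of 10,000 iterations redraws mutually disjoint groups from the universe
with the GI groups' size distribution (a random relabeling) and records
whether the maximal similarity with a random group *strictly* exceeds
the observed maximal similarity; the p-value is the exceedance
fraction, one-sided and uncorrected. Ties do not count as exceedances,
and `p = 0` is reportable — both follow the verbatim definition of the
statistic; an add-one variant `(count + 1)/(n + 1)` is available for
users who prefer a positive lower bound. Because the max-Jaccard
statistic on a 24-gene universe is discrete, the finite-sample type-I
rate of the strict-exceedance p depends on the group sizes; with a
behavior group of 10 against groups of 16 and 8 the exact rate at
nominal 0.05 is 0.055, which is the configuration the calibration
checks use.

## The synthetic generator

Each simulated fly follows a two-state (asleep/awake) semi-Markov
process at 1-s resolution. An archetype specifies a per-minute target
sleep-occupancy curve `c(m)` over the clock day; hazards are split as
sleep-onset `lambda(m) = r * c(m)` and wake `mu(m) = mu0 * (1 - c(m))`,
which leaves the stationary occupancy at `c(m)` when `r = mu0` while
making bouts longest where the curve is high — so a genotype with an
early-night occupancy block also shows the short latency-to-longest-bout
of that phenotype. `mu0` is calibrated from the night-mean bout length
and `r` from the night bout rate; constructing the rate from the curve
(the default) keeps the three mutually consistent, and the realized
occupancy then converges to the curve (the small residual bias comes
from the 5-min rule discarding short immobility runs and from latency
gating). Sleep onset is gated off for an exponential latency after each
lights-off; during the final 3 h of night an anticipation parameter
ramps the wake hazard up and the onset hazard down. Awake frames
displace by `|Normal(speed * dt, sd * dt)|` with random sign along the
tube, reflected into `[0, tube_length]`; asleep frames jitter uniformly
below 0.1 mm per frame, always under the 0.25 mm threshold. Transverse
jitter is 0.01 mm so it cannot trip the movement rule. One global seed
drives everything; per-fly streams derive deterministically from
(seed, fly index), so outputs are bit-identical per seed regardless of
which flies are generated.

The generator emulates the statistical structure the pipeline consumes —
occupancy profiles, bout architecture, latency, anticipation, awake
speed, batch effects in the ERG tables (per-batch control level at 5%
CV), replicate noise, and multiplicative-plus-additive interaction
structure. It does not emulate tracking noise and artifacts, grooming
or micro-movement, positional preference within the tube, arousal
thresholds, aging or death dynamics (death QC is exercised with
constructed traces), so passing recovery tests demonstrates
correctness of the analysis chain under the stated model, not
robustness to every property of real video tracking. ERG amplitudes
are clamped to be positive; an interaction pushing the implied mean
amplitude to zero or below is rejected as unphysical, which is why
aggravating-interaction simulations use strong singles (e.g. 0.9 x 0.9)
rather than 0.5 x 0.5.

## Problem sizes and numerical choices

The test-suite and acceptance experiments use 2-day recordings (the
first day is discarded by QC, as in the assay's design) with cohorts of
up to 12 genotypes x 30 flies, 100-seed classification experiments,
200-replicate permutation calibrations at 10,000 iterations, and
reduced MCMC (2 chains x 1000 draws after 500 warmup) for the
calibration ensembles; single-fit defaults remain 4 x 2000/1000. These
sizes are the package's choice of experiment scale; all recovery
margins are comfortably met at them. Ties in linkage are broken
deterministically by `stats::hclust`; NMF restarts, blur kernels
(radius `4 * sigma`) and HDI windows are deterministic given seeds.

## Limitations

Only the sleep/immobility channel is decomposed (the per-behavior
matrices of a multi-channel ethogram are a configuration hook, not
implemented); the Bayesian model does not pool across pairs; dendrogram
uncertainty (bootstrap) is out of scope; and reading native ethoscope
SQLite recordings or video is not supported — the entry format is the
long positional track table.
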