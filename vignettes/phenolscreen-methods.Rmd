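---
title: "Methods: growth-score screening of deletion libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-score screening of deletion libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolscreen)
```

## The screening problem

Chemical-genomic screens expose a genome-wide deletion library — one strain
per nonessential gene — to a compound at a carefully chosen dose and ask
which deletions change fitness. Strains are pinned or spotted on agar in a
regular grid, grown in parallel on a treated plate and a solvent-only
control plate, and the plates are scanned. Everything downstream of the
scanner is arithmetic, and that arithmetic is what this package implements:
densitometry, normalization, calling, overlap accounting, profile
clustering, gene-set enrichment, and dose selection.

## The growth score value (GSV)

The central statistic is the growth score value of a strain under a
compound:

$$\mathrm{GSV} \;=\; \frac{d_T / d_U}{wt_T / wt_U},$$

the strain's treated/untreated colony-density ratio normalized by the
wild-type treated/untreated ratio on the same pair of plates. The score is
dimensionless and scale-free: any global rescaling of either plate's
densities — scanner gain, exposure, agar batch — cancels exactly, which is
why the densitometry stage only ever needs to be accurate *up to a plate-wide
constant*. GSV = 1 is wild-type-like growth. Calls use inclusive
boundaries: GSV $\le$ 0.5 is SENSITIVE, GSV $\ge$ 2.0 is RESISTANT,
anything between is NORMAL. The defaults live in `screen_config()` and both
cutoffs are configurable, but 0.5/2.0 is the symmetric two-fold convention
of focused spot screens, where observed scores span roughly 0.1 to 25.

Replicates are averaged arithmetically (`aggregate_replicates()`), and the
averaged GSV is the primary caller. A separate consensus caller
(`consensus_call()`) implements the m-of-t rule used when trials are to be
counted rather than averaged: a category must be reached in at least *m* of
*t* evaluable trials, ties and shortfalls break to NO_CALL. Genome-scale
screens conventionally run 2-of-2, focused rescreens 3-of-4; both are
config options rather than hard-wired rules. When a table carries fewer
trials than *m*, `score_screen()` caps *m* at the trial count instead of
erroring — the alternative (every strain NO_CALL) reports nothing useful.

A strain whose *untreated* density is zero has no defined GSV. These are
surfaced as NO_CALL with a warning; the package never stores or silently
drops an undefined score. A plate whose wild-type densities are
non-positive cannot be normalized at all and is rejected. When several
wild-type positions exist on a plate their mean is used — positional noise
on the reference shrinks with the number of reference spots, and nothing
in the GSV definition privileges any single position.

## Plate digitization

`detect_grid()` finds the spot lattice from the marginal intensity
projections of the image: a plate's row and column structure shows up as
regularly spaced peaks in the row/column means. Peaks are called above an
adaptive threshold, pruned by non-maximum suppression at half the expected
pitch, refined by local centroids, and accepted only when the expected
count is found on both axes *and* the spacing is regular (coefficient of
variation of successive gaps at most 15%). If the straight-on detection
fails, an exhaustive rotation search (default $\pm 2°$ in 0.5° steps)
re-projects the image at each candidate angle; a plate rotated beyond the
tolerance therefore fails loudly rather than quantifying garbage. On
synthetic plates at default geometry the recovered centers sit within a
few hundredths of a pixel of truth.

`quantify_spots()` integrates pixel intensity over a disk (radius 0.35
pitch by default) at each grid point and subtracts a local background
estimated as the median of the surrounding annulus (1–1.6 radii). The
annulus median tracks smooth gradients — the dominant artifact of flatbed
scans — without being dragged by the spot itself, whose smoothed edge has
decayed to under a percent of peak by the annulus. Integrals are clipped
at zero. Four flags qualify each spot: SATURATED (any disk pixel at the
sensor ceiling), EDGE (disk truncated by the border — quantified on the
available pixels, flagged rather than fatal), CONTAMINATED (optional
annulus-spread criterion), and EMPTY. The empty criterion is a per-spot
detection limit, three times the annulus MAD scaled by the square root of
the disk area: the integration noise floor. A fixed fraction of the plate
maximum was rejected as the default because a strongly resistant strain
stretches the maximum and would mislabel faint — but real, and maximally
informative — colonies of sensitive strains as empty.

Serial-dilution series collapse to one density per strain by summation
over the usable (unflagged) spots. Summation uses all the information in
the series, is monotone in fitness, and reduces to the identity for
single-spot pin assays. A strain whose every spot is flagged becomes a
missing-data error (NA with a warning in the table path), never a zero.

## The synthetic-data generator

Every stage is tested against `simulate_screen()`,
`render_plate_image()`, `simulate_annotation_universe()` and
`simulate_dose_response()`, which generate data with known ground truth.
All are pure functions of their parameters and a seed.

The screen generator plants a true relative fitness $\rho$ per strain and
compound: $\rho = 1$ neutral, sensitive effects drawn uniformly from
[0.1, 0.4], resistant from [2.5, 6] — intervals chosen so that planted
GSVs span the range focused screens report (roughly 0.1–25) and sit
decisively beyond the 0.5/2.0 cutoffs. Default rates are 10% sensitive
and 2% resistant per compound, a typical hit rate for a genome-wide
screen at a well-chosen dose. Measurement noise is multiplicative
lognormal with mean exactly 1 and coefficient of variation 0.15:
densitometry errors scale with intensity, and 15% per-spot CV is a
realistic figure for colony integrals on scanned agar. Three replicates
is the default trial count.

The renderer draws spots as hard disks with Gaussian edge smoothing
($\sigma = r/4$), on a smooth linear background gradient plus i.i.d.
Gaussian pixel noise, clipped at a 16-bit saturation ceiling. The profile
is identical for every spot, so integrated intensity is proportional to
requested density by one global constant — exactly the contract the
scale-free GSV needs, and the reason the render→quantify round trip can
be tested to a 5% per-spot tolerance.

What the generator deliberately does *not* emulate: colony morphology
(rings, sectors, translucency), agar texture, inter-colony competition,
pinning volume variation, and spatial plate effects beyond a smooth
gradient. Passing tests demonstrate that the arithmetic of the pipeline
is correct and well-conditioned under a realistic noise model; they do
not certify performance on pathological real scans.

## Overlap accounting

`overlap_analysis()` does exact set arithmetic over per-compound sensitive
sets. Pairwise intersection counts are reported *inclusive* of the triple
intersection — the convention under which per-set unique counts follow by
inclusion-exclusion ($|A\,\mathrm{only}| = |A| - |A\cap B| - |A\cap C| +
|A\cap B\cap C|$), and the identity
$|A\cup B\cup C| = \sum|X| - \sum|X\cap Y| + |A\cap B\cap C|$ is asserted
on every summary built from real sets. `overlap_from_counts()` solves the
inverse problem — published marginal counts without the gene lists — and
reports any quantity the supplied counts do not determine as `NA` rather
than guessing.

## Profile clustering

Fitness profiles are clustered on converted scores: $\log_2$ GSV clipped
below at a floor of 0.05. The log makes the two call directions symmetric
(0.5 → −1, 2.0 → +1); the floor keeps fully inhibited strains finite at
$\log_2 0.05 \approx -4.3$, about twice the magnitude of the strongest
planted sensitive effects, so total inhibition remains visibly extreme
without dominating every distance. Clustering is average-linkage on
Euclidean distances — the classic expression-profile recipe — delegated
to `stats::hclust`, whose deterministic tie handling is adopted as-is;
the package's test fixtures use distinct distances, where every
average-linkage implementation agrees. Trees export as Newick via `ape`.

## Gene-set enrichment

The enrichment statistic is the upper-tail hypergeometric probability of
the observed query∩term overlap, tail inclusive of the observed count —
the standard over-representation convention (the pmf-style routine the
field's tooling names is a point mass; a test needs the tail). The sum is
accumulated in log space (log-binomial coefficients combined by
log-sum-exp), which keeps it stable at genome scale; it is verified
against exhaustive draw enumeration at small N and against the
independent survival-function implementation in `stats` at large N.
Correction is Bonferroni by default (matching the conservative default of
the GO tooling this stage replaces) with Benjamini–Hochberg available;
terms and binary flags are corrected as separate families since they
answer different questions. Significance is `p_corrected < 0.05`. The
choice of universe — screened genes versus whole genome — materially
changes K and N and is deliberately a required input, not a default.

One calibration subtlety: the inclusive upper tail of a discrete
statistic is *super-uniform* under the null — $P(p \le t) \le t$ with
deficits the size of the local point masses. A two-sided uniformity test
on hundreds of null terms will therefore reject any faithful
implementation on the conservative side. The calibration that matters for
error control is the anti-conservative direction, so the package's null
check is the one-sided Kolmogorov–Smirnov test that the empirical CDF
does not sit significantly above the uniform; on 500 null terms the
anti-conservative deviation is below 0.01.

The bubble display places each significant term as a circle whose radius
and radial distance from the center are the same linear function of its
gene count (two separate scale constants, 0.6 and 3 per gene by default),
color-binned by corrected p. Angles are assigned by gene-count rank and
then relaxed by an angular-repulsion pass until no two circle boundaries
intersect; angular placement is otherwise arbitrary, and rank order plus
repulsion makes it reproducible.

## Dose-response and dose selection

`simulate_dose_response()` and `estimate_ic()` share the two-parameter
logistic $g(c) = 1/(1 + (c/\mathrm{IC50})^h)$, so the generator/estimator
round trip is exact in the noiseless limit. The interpolating estimator
works on inhibition versus $\log_{10}$ concentration between the
bracketing observations (linear near a zero-dose bracket), because
dose-response is conventionally log-linear near its midpoint; it refuses
to extrapolate. The fitting estimator is Levenberg–Marquardt least
squares (`minpack.lm`), inverted analytically at the requested level.
Screening doses are then chosen by the 10% rule
(`select_screening_concentration()`): among doses leaving more than 10%
of mutants able to grow, take the one where the fraction still growing
like wild type is closest to 10% — strong enough that sensitivity
differences show, weak enough that most of the library stays scorable.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at the sizes
the statistics need and no larger: the planted-recovery check uses 1,000
strains × 3 compounds × 3 replicates; null calibration uses 500 terms in
a 2,000-gene universe with a 300-gene query; the digitization round trip
uses one 96-position plate at default geometry (341 × 501 px); seed-driven
frequency properties (planted-term ranking, two-regime clustering) use 20
seeds against a 95% frequency bound. Tolerances mirror the contracts
stated above: 1 px on grid centers, 5% per spot after one global
rescaling, 1% on noiseless IC50s, $10^{-12}$ against hypergeometric
enumeration.

## Known limitations

Grid detection assumes a roughly axis-aligned lattice and a smoothly
varying background; it will not rescue barrel distortion or severe
vignetting. Visual sensitivity calling — the primary caller in manual
screening practice — is out of scope; the GSV path is the quantitative
replacement. Enrichment treats terms as flat sets: no ontology-graph
propagation, no redundancy collapsing between nested terms. The
dose-response stage fits only the two-parameter logistic; curves with
partial plateaus or biphasic kill need a richer model than this stage
provides.
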