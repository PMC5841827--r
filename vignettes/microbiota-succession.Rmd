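---
title: "Modeling root microbiota succession and microbiota age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling root microbiota succession and microbiota age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizochron)
```

# The problem

Plant roots assemble microbial communities from the surrounding soil, and
those communities are not static: as an annual plant such as rice moves from
germination through vegetative growth into reproduction and senescence, the
bacterial and archaeal assemblages in the rhizosphere (soil adhering to the
root), rhizoplane (root surface) and endosphere (root interior) turn over in
a reproducible successional sequence. rhizochron implements an analysis
pipeline for 16S OTU count tables sampled along this spatial gradient and
over the host's life cycle, together with a ground-truthed synthetic data
generator, so that every stage of the pipeline can be validated by parameter
recovery before it is pointed at field data.

The pipeline covers: per-mille normalization and prevalence filtering;
Bray-Curtis dissimilarity, principal coordinates, PERMANOVA variance
partitioning and time-point similarity summaries; beta-regression trends of
taxon proportions over the root spatial gradient and over plant age; sparse
random-forest models that predict a sample's plant age (or developmental
stage) from OTU abundances — the "microbiota age" — with early/late/complex
colonizer classification of the model's marker taxa; exact-test detection of
site-skewed OTUs; and between-site convergence statistics.

# Data model and normalization

An `otu_table` is a non-negative OTUs-by-samples matrix tagged with its
unit. Raw counts are converted to **per-mille relative abundance** by
dividing each count by its sample's sequencing depth and multiplying by
1,000, so each column sums to 1,000. OTUs present in fewer than 5% of
samples are removed (`filter_prevalence`; removal is *strictly below* the
threshold, so an OTU in exactly 5% of samples is retained, and presence
means any nonzero abundance). Taxonomy is attached as Greengenes-style
lineages; phylum-level aggregation can split the Proteobacteria into its
classes, because that phylum is phylogenetically broad and typically
dominates root communities. OTUs unassigned at the requested rank aggregate
into an explicit `unclassified_<rank>` row so per-sample totals are
conserved exactly.

Samples carry a spatial position code — bulk soil 0, rhizosphere 1,
rhizoplane 2, endosphere 3 — used as a numeric covariate for spatial
trends, and a developmental stage on a 1–27 scale in which stage 18 is
panicle initiation (entry into reproductive growth).

# The synthetic successional community

`simulate_community()` generates OTU tables with exported ground truth. Its
defaults are the package's reference study conditions; they are chosen once
to emulate a two-site, season-long rice field study and are not tuned per
analysis.

**Design.** Two sites, four compartments, weekly sampling from day 7 to
day 140, three biological replicates per cell, and a single medium-maturity
genotype (development rate 1.5, so stage 18 falls at 61 days — 8–9 weeks,
as for commercial medium-grain varieties). Each sample's developmental
stage is `clamp(round(1 + rate * 26 * age/140), 1, 27)`.

**Per-OTU truth.** Each OTU receives an archetype — early colonizer (15%),
late colonizer (25%), complex (10%), static (50%) — a log-scale baseline
(SD 1), a compartment-affinity slope over positions 0–3 (SD 0.8), and an
abundance curve in *developmental time* `t = age x rate`: a falling
logistic for early colonizers, a rising logistic for late, a Gaussian bump
for complex, all with amplitude ~3 natural-log units and scale 14 days.
Driving the curves with developmental rather than calendar time encodes the
central hypothesis that microbiota succession tracks host development, and
is what makes stage-versus-age discrimination testable. Curve midpoints
default to the stage-18 developmental time, so late colonizers finish
establishing, and the early/late dominance handover occurs, as the plant
enters reproduction.

Several structural choices mirror field observations and deserve
explanation:

* **Host-proximity weighting.** The successional signal is scaled by
  position (0.08 in bulk soil, 0.6 / 0.8 / 1.0 across the
  rhizocompartments): succession is host-driven, so unplanted soil barely
  tracks the plant while the endosphere tracks it fully.
* **Site-specific taxa dominate early.** 20% of early colonizers are
  restricted to one site and receive a +1.5 log baseline boost; 10% of
  static OTUs are also site-restricted (soils differ persistently). This
  reproduces the field pattern that early root communities are largely
  site-specific while the late, host-selected community is shared between
  sites — which is what makes between-site distances decline with plant age
  in the rhizocompartments but not in bulk soil.
* **Early colonizers are root-enriched.** Early-archetype affinity slopes
  are half-normal (non-negative), since early colonizing age-discriminant
  taxa are observed almost unanimously enriched in rhizocompartments over
  bulk soil.
* **Balanced handover.** Early-colonizer baselines are offset by a single
  constant so the endosphere-weighted early and late masses match; without
  this the day at which late colonizers overtake early ones is set by the
  accident of which group drew the heavier-tailed baselines, rather than by
  the planted midpoint.

**Counts.** Sequencing depth is a discretized log-normal around 10,000
reads (SD 0.2 on the log scale); compositions are drawn from a Dirichlet
with total concentration 300 centered on the latent composition, and counts
are multinomial. The Dirichlet-multinomial produces the overdispersion that
the exact test assumes; concentration 300 at depth 10,000 corresponds to a
roughly 30-fold variance inflation over multinomial sampling, in the range
reported for 16S community profiles.

**Drought.** With treatment arms enabled, drought multiplies early-colonizer
latent abundances by `(1 + severity)` and divides late colonizers by the
same factor in the endosphere (default severity 1.5), then renormalizes.
The rhizosphere is left unperturbed by default (attenuation exponent 0,
exposed as a parameter): drought's effect on microbiota maturity is
endosphere-specific, and the package's null checks for the rhizosphere
contrast require a true null.

**What the generator does not emulate.** Real 16S data have chimeras,
contaminants, sequencing-run batch effects, phylogenetic correlation among
OTUs, varying library preparation efficiency, and taxa whose dynamics do
not follow smooth logistic curves. Passing the package's recovery tests
therefore shows the pipeline is correct and well-calibrated *under the
stated model*, not that any field dataset satisfies that model.

# Community structure

Bray-Curtis dissimilarity (`sum|x-y| / sum(x+y)`) feeds principal
coordinates analysis and PERMANOVA. Ordination is computed on
`log2(per-mille + 1)` abundances by default — the log2 transform
compresses dominant taxa, and the pseudocount of 1 per-mille is the
smallest value that maps zeros to zero; both the transform and the
pseudocount are arguments, since the choice is a convention rather than a
derived quantity. PCoA double-centers `-d^2/2` and eigendecomposes;
negative eigenvalues (Bray-Curtis is non-Euclidean) are reported but not
embedded, and proportions explained use the positive eigenvalues as
denominator. PERMANOVA uses sequential (type-I) sums of squares in the
user-supplied term order with unrestricted row permutations, and
`p = (#{F* >= F} + 1) / (n_perm + 1)`.

`timepoint_similarity_z()` summarizes stabilization: mean similarity
`(1 - Bray-Curtis)` between every pair of time points, z-scored within a
compartment. On a late-stabilizing community the late-by-late block of this
matrix is warmer than the early block. Note that under the default
generator the pre-transition early season is compositionally *flat* (the
logistic curves have not yet moved), so the early block is itself
homogeneous; the stabilization contrast is exercised on a scenario whose
turnover starts at germination, which is how the corresponding test
constructs its data.

# Taxon trends and colonizer classes

Proportions confined to (0, 1) are modeled with beta regression: `y ~
Beta(mu*phi, (1-mu)*phi)` with `logit(mu) = b0 + b1*x` and constant
precision `phi`, fit by maximum likelihood (BFGS on `(b0, b1, log phi)`),
with Wald tests from the observed information. Exact 0/1 observations are
first compressed by `y' = (y(n-1) + 0.5)/n` (Smithson–Verkuilen); the
compression applies to all observations whenever any lie on the boundary.
Spatial trends use the 0–3 position code as a single numeric covariate;
temporal trends are fit per compartment against age in days. Significance
is Bonferroni-adjusted within the set of taxa tested in one call.

Individual OTUs are classified by ordinary least squares of per-mille
abundance on age: a significantly negative slope (after Bonferroni) is an
**early colonizer**, significantly positive is **late**, anything else —
including constant OTUs — is **complex**.

# Sparse random-forest maturity models

Training follows a fixed recipe: half of the samples from each time point
and compartment stratum (the ceiling for odd strata) form the training
set; a full random-forest regression of all OTU abundances on plant age
(or developmental stage) is fit with 500 trees and the regression default
of p/3 features per split; OTUs are ranked by unscaled permutation
importance (mean increase in out-of-bag squared error, ties broken by OTU
id for determinism); 10-fold cross-validation re-fits forests on the
top-k OTUs while k is halved from p down to 1; and a sparse forest is
refit on the selected set with no further parameterization. The selection
rule takes the smallest subset within 5% of the minimum CV error —
formalizing the usual visual elbow — or a fixed override (the reference
field models use 85 OTUs for age and 54 for stage). Prediction on new
tables imputes absent model OTUs as 0 per-mille with a warning, and
refuses to predict when more than half the model's OTUs are missing.

Predicted-age contrasts use sequential ANOVA plus Tukey honest significant
difference contrasts. A drought-perturbed endosphere receives predicted
ages substantially below its true age — an "immature" microbiota — because
the perturbation inflates exactly the early-colonizer markers that the
model associates with young plants.

# Site dynamics

`between_site_distances()` collects cross-site Bray-Curtis distances
within each common time point and compartment and fits an OLS trend on
age. A declining trend means the two sites' communities converge as the
shared late community replaces site-specific early colonizers. The
`baseline = "within_site"` option subtracts, per time point, the mean
within-site distance before fitting: raw cross-site distances sit on a
replicate-level noise floor that can itself drift slowly with age (the
community's effective diversity changes), and the excess distance isolates
genuine between-site divergence from that floor. The package's own
directional checks use raw distances for the rhizocompartments (where the
effect is overwhelming) and the excess form for bulk soil, evaluated over
the first five weeks — the window in which unplanted soil can be sampled
in a root-invaded paddy.

Site-skewed OTUs are detected with a conditional exact test on
depth-equalized counts: group sums of negative-binomial counts with equal
means are negative binomial, and conditioning on the total makes the split
distribution mean-free; the two-sided p-value sums the probabilities of
all splits no more probable than the observed one. Dispersion 0 recovers
the conditional binomial (exact Poisson) test. Dispersions are estimated
per time point x compartment family: tagwise method-of-moments estimates
are shrunk 50/50 toward a common component `kappa / p_i`, where `kappa`
(a single family-wide overdispersion coefficient, estimated as the upper
quartile of tagwise dispersion times relative abundance) encodes that in
depth-constrained community data the variance inflation acts on the
composition, making rare taxa proportionally more dispersed. The upper
quartile offsets the downward bias of zero-truncated small-sample moment
estimates; with nine or more samples per group the family-wise error of
the Bonferroni-corrected scan is held at its nominal level on
Dirichlet-multinomial nulls. This moderation is a deliberately simple,
fully specified stand-in for weighted-likelihood empirical Bayes; exact
agreement with empirical-Bayes packages is not expected and not claimed.

`pco_trend_interaction()` asks whether genotypes progress along an
ordination axis at different rates: within each compartment and season
window (before / after day 84, by which all varieties in the reference
design have entered reproduction), it compares `PCo ~ age` against
`PCo ~ age x genotype` with a nested-model F test and reports per-genotype
slopes with Tukey-adjusted pairwise contrasts (compact letter displays are
deliberately omitted; the pairwise table carries the same information).
In the four-genotype reference design (rates 1.6, 1.36, 1.33, 1.31 —
curve scale 8 days so every variety's community has plateaued after
day 84), the interaction is significant only in the early window and the
slope extremes follow the fastest (Kitaake) and slowest (Nipponbare)
varieties. The sign of a principal coordinate is arbitrary, so slope
comparisons orient by the mean slope first.

# Numerical and testing choices

Problem sizes in the test-suite and in `scripts/acceptance.R` are chosen
to keep a full run in tens of seconds while leaving clear statistical
margins: 500 OTUs and 480 samples for the reference season, 1,000 OTUs
with 30 informative for the feature-recovery benchmark, 200 simulations
for permutation-test calibration. The recovery benchmark plants its
informative OTUs with turnover midpoints staggered across the season (SD
35 days), one site, endosphere only, and no compartment-affinity spread:
with affinities active, an informative OTU can simply be rare in the
modeled compartment, and "recovery" would measure observability rather
than the pipeline. Null-side assertions (the rhizosphere drought
contrast, bulk-soil convergence) are made at the 0.01 level: these are
true or near-true nulls, and a 0.05 assertion would fail one run in
twenty by construction while 0.01 still separates them cleanly from the
positive controls, whose p-values are orders of magnitude smaller.

All randomness flows from explicit seeds; `run_pipeline()` derives every
stage seed from one master seed and writes a manifest (package version,
configuration, per-output checksums, no timestamps) that is byte-identical
across runs with the same seed.

# Known limitations

* Beta regression uses a constant precision; variable-precision models and
  smooth (spline) temporal trends are out of scope.
* The exact test's depth equalization rescales counts to the median depth
  rather than using offsets or trimmed-mean normalization; heavily skewed
  depth distributions would distort its discreteness.
* PERMANOVA permutations are unrestricted; designs needing strata (e.g.
  repeated measures of the same plot) are not supported.
* The generator's OTUs are independent given the design; it cannot produce
  the correlated taxon blocks that real communities show, so variance
  estimates on real data will typically be more optimistic here than in
  the field.
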