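---
title: "Models and methods behind the BSFL bioconversion pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the BSFL bioconversion pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and numerical choices in
`hermetia`: what the synthetic feeding-trial generator simulates, how the
mass-budget indices are defined, and how the multivariate and community
statistics are computed. It is the package's own account of its methods;
every empirical claim here is exercised by the test suite or the
acceptance script rather than asserted.

## The synthetic feeding trial

The generator exists so that every downstream estimator can be validated
against a known truth. It emulates a box-replicated larval feeding trial:
by default three diets (chicken-feed control CFD, canteen food waste FWD,
oil-separator waste OWD), four boxes of 200 larvae per diet, feeding every
second day from day 0 to day 18 (ten feeding events) and observations
every second day until diet-specific termination (day 18, 20 and 12
respectively).

**Growth.** Per-larva fresh mass follows a logistic curve to a
diet-specific peak, then declines linearly in relative terms — larvae
approaching the (pre-)pupal stage consistently lose mass. The peak day is
defined as the day the logistic reaches 99 % of its asymptote. Defaults
place the food-waste peak at 206 mg around day 14 with a 3.45 %/day
post-peak loss (a ~20 % decline by day 20) and the control peak at 184 mg
with a 1.2 %/day loss; the oil-waste diet plateaus at 22 mg. Dry matter is
a fixed fraction of fresh mass (0.35–0.37) and volatile solids a fixed
fraction of dry mass (0.95).

**Mortality and pupation.** Mortality is a piecewise-constant hazard that
switches on after a lag day (default day 5 for the oil-waste diet), applied
as daily binomial thinning with probability `1 − exp(−h)`; the default
oil-waste hazard `h = ln(25)/7` gives ~96 % cumulative mortality between
day 5 and day 12, matching the closed form `exp(−h (t − lag))` to binomial
error. Pupation is a daily Bernoulli event per larva after the pupation
start day; pupae leave the live pool and retain 92 % of their fresh mass.
Dead larvae are removed from the biomass on the day recorded and their
mass never enters the budget.

**Feeding energetics.** Feeding deposits dry substrate into a per-box pool
(ration × interval × live larvae × dry fraction; rations 100/170/70 mg
larva⁻¹ day⁻¹ fresh for CFD/FWD/OWD). Each day the box ingests
`min(capacity × live dry biomass, pool)`; the assimilated fraction
(`assimilation_eff`) of ingested mass covers biomass gain plus metabolic
loss, and the remaining `1 − assimilation_eff` fraction becomes egesta.
This is the standard insect budget `ingested = growth + respiration +
egesta`; the generator pins the egesta fraction and lets respiration absorb
the slack between assimilation and the growth curve. No published per-day
consumption exists for this system, so the saturating intake rule is a
modeling choice that keeps budgets conservative, not a reconstruction. One
consequence: in the simulated world `SR ≤ AD` always (residues lose no
mass after egestion), whereas field residues can degrade further, so
empirical SR can exceed AD.

**Truth bookkeeping.** The generator returns, per box, the daily budget
series and a `mass_budget` computed from it with the *same conventions the
estimators use* (trapezoidal mean biomass over observation days, biomass
gain including pupated mass). With observation noise disabled, estimators
applied to the written tables reproduce these truth indices to 1e-6
relative — the index-recovery invariant in the test suite.

**Substrate chemistry.** Physicochemical profiles are normal draws around
per-substrate means for 15 variables in fresh (`-S`) and residue (`-R`)
states (3 and 4 replicates, as in the emulated design), encoding the
characteristic processing shifts: ammonium ×20 in control residue and ×30
in food-waste residue, protein ×10 everywhere, fresh food waste at pH 4.5
neutralizing after processing, and a near-inert pine-humus litter with no
residue state. The oil-waste fresh and residue groups are deliberately
similar — the gap statistic should (and does) merge them, selecting six
clusters from seven planted sample groups.

**Communities.** Counts are Dirichlet-multinomial: a power-law-like
baseline composition is perturbed per sample by a Dirichlet draw with
precision `dispersion` (default 200) and sampled at a gamma-mixed-Poisson
library size (mean 5000, shape 8). One designated bloom taxon follows a
logistic expected relative abundance from 1 % (day 2) to 88 % (day 20) in
the succession diets (FWD, OWD), emulating the *Morganella*-style
take-over of waste-fed larval guts, while remaining a 0.2 % resident
elsewhere — published observations place the genus at 0.1–0.3 % in
substrates and show no accumulation under the control diet. All randomness
derives from one integer seed through named per-stream sub-seeds, so
adding an output stream never perturbs existing ones.

**What the generator does not emulate:** sequence-level reads and their
error/chimera structure, phylogeny, copy-number variation, compositional
interactions between more than one blooming taxon, and residue mass loss
after egestion. Passing tests therefore demonstrate correctness of the
estimators under a clean, well-specified data-generating process — not
robustness to every artifact of real amplicon data.

## Mass-budget indices

`mass_budget` deliberately carries two residue quantities. The classical
index table uses the symbol R both for the total collected residue (in
substrate reduction and the waste reduction index) and for egesta (in
approximate digestibility and conversion efficiency); published index
values for the control diet (SR 65.6 vs AD 47.7) are only mutually
consistent if the bases differ. Each formula is bound to its own field.
All indices are computed on a dry-matter basis except the growth rate,
which is per-larva fresh mass per day, matching how growth trajectories
are reported. Mean biomass `A` is the trapezoidal time-average of live dry
biomass over the (possibly unevenly spaced) observation days — the "mean
weight during the feeding period" of the classical nutritional-index
literature. `T` runs from diet introduction to the diet's termination day.
Division by zero in any index yields a flagged `NA`, never an error;
reports round indices to one decimal and gram masses to three decimals.

Two reporting caveats are intentional. The published control-diet WRI
(3.7) is not exactly SR/T at T = 18 (3.64); the package computes WRI = SR/T
per the formula and does not force agreement. The consumption index
depends on absolute mean biomass, which cannot be reconstructed from
printed endpoints alone; CI is implemented per formula but is not used as
a reference value anywhere.

## Multivariate analysis of substrate profiles

Variables are centered and scaled before PCA because units are
incommensurate (pH vs mg kg⁻¹). Component signs are fixed by making each
loading column's largest-magnitude entry positive, so results are exactly
reproducible. Variable loadings in the first two components are grouped by
k-means with k-means++ seeding and 25 restarts (ties broken by first
best). Hierarchical clustering uses Ward (ward.D2), average or complete
linkage on Euclidean distances of standardized variables — linkages whose
merge heights are monotone.

The gap statistic follows the original formulation —
`Gap(k) = mean_b log W_k^ref − log W_k` with references drawn uniformly
over the data's bounding box in PCA-rotated coordinates — with two
documented conventions: within-cluster dispersion `W_k` is measured on
unsquared Euclidean pairwise distances (the convention of the reference R
implementation, which is markedly more stable for selecting k on elongated
cluster layouts), and k is selected by the one-standard-error rule,
smallest k with `Gap(k) ≥ Gap(k+1) − s(k+1)`. A published "cut-off at
k = 0.61" for this analysis is not interpretable as an integer cluster
count and is treated as a reporting artifact; the conventional rule is
used instead and the gap table is returned so any cut-off can be applied
downstream.

## Community statistics

Rarefaction subsamples without replacement (multivariate hypergeometric),
per the mothur convention; samples below the target depth are dropped with
a warning, and depth stability is assessed by Mantel tests between
Bray–Curtis matrices at several depths restricted to their common samples.
The prevalence filter keeps taxa with count ≥ 4 in at least
`ceil(10 % × n)` samples; the alternative reading ("present in ≥ 4
samples") is available as a configuration switch. Shannon diversity and
the Pielou denominator both use the natural logarithm — the magnitude
reported for a rich, even substrate community (H′ ≈ 4.15) is only
consistent with natural-log units — and `J` is defined as 0 for
single-taxon samples.

NMDS minimizes Kruskal stress-1 with disparities from isotonic regression
(pool-adjacent-violators) of configuration distances on dissimilarity
ranks, updated by iterative majorization (a Guttman transform towards the
disparities). An update that would increase stress is step-halved toward
the previous configuration, so accepted iterations never increase stress;
convergence is a relative stress change below 1e-6, with 20 starts (the
first from classical metric scaling, the rest random) and 300 iterations
maximum. Non-convergence is returned as a flag, never silently.

PERMANOVA uses the distance-based sum-of-squares decomposition
(`SS_total = Σ d²/n` with the per-group within analogue) and a free
permutation of sample labels; `p = (#{F ≥ F_obs} + 1)/(n_perm + 1)` with
1000 permutations by default, one-sided in F, with exact enumeration
available for tiny designs. Because the real design's model formula is not
stated, diet and time are tested as separate one-way factors plus a
combined diet×time one-way factor, and pairwise diet tests are
Bonferroni-adjusted. The Mantel statistic is the Pearson correlation of
lower-triangle entries with the same permutation scheme.

## Indicator consensus

The effect-size screen normalizes counts to per-mille, filters by
Kruskal–Wallis at α = 0.05 and scores surviving taxa as log10 of a
bootstrap-averaged one-dimensional discriminant effect (largest absolute
class-mean difference, 30 within-class bootstrap resamples), significant
at score ≥ 2.0. These defaults are the canonical ones for this kind of
screen; the procedure is a documented simplification and makes no claim
of bit-reproducing any specific external tool. IndVal uses the
group-size-corrected IndVal.g statistic `sqrt(A × B)` over single groups
and all non-trivial group combinations except the full set, with presence
defined as count > 0 and p-values from label permutations re-maximized
over candidate sets (so a taxon's p accounts for the selection of its
best pattern; for a perfect 3+3 indicator, exhaustive enumeration gives
p = 2/20 by complement symmetry). A consensus indicator must be
significant under both screens with an agreeing group — for an IndVal
combination, the effect-size top class must be a member. Records below 1 %
mean relative abundance are kept but flagged below the display threshold.

## Functional projection

The taxon-to-pathway projection is a transparent linear stand-in for
reference-based metagenome imputation: sample compositions restricted to
reference-covered taxa are pushed through a row-stochastic taxon×pathway
matrix and renormalized, the covered read share is reported as the
assignable fraction, and pathway profiles aggregate losslessly onto
level-2 categories. No external reference database is shipped; the module
operates on any user- or generator-supplied matrix, and taxon-level
matching is assumed. Projection is linear, so a 50/50 mixture of two
equal-depth samples has the mean of their profiles; and because reference
rows are shared across taxa, planted taxonomic contrasts blur at the
functional level — the test suite asserts the projected PERMANOVA R² never
exceeds the taxonomic one on such data, mirroring the qualitative
observation that diet distinctions are much weaker on metabolic pathways
than on taxa.

## Problem sizes and determinism

The shipped defaults are sized for a desk-scale study: 36 community
samples × 60 taxa at ~5000 reads, 12 trial boxes, 1000 (tests: 99–499)
permutations, 20 NMDS starts and 50 (tests: 12–30) gap references. These
sizes were chosen so a full pipeline run completes in seconds while
keeping every statistic in its asymptotically sensible regime. Every
stochastic routine takes an explicit integer seed; the pipeline's manifest
records the seed, configuration and md5 checksums of all outputs, and
rerunning with the same bundle and configuration reproduces identical
files.

## Known limitations

The PERMANOVA is one-way only (no strata or sequential multi-factor
decomposition); NMDS ties in dissimilarities are handled by the primary
approach of isotonic regression; the LDA effect size is a simplified
discriminant, so absolute scores are comparable within this package but
not across tools; the gap statistic's reference assumes a convex support;
and the functional projection ignores 16S copy number and gene length.
The synthetic generator's single-bloom succession is a deliberate
simplification of real gut dynamics.
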