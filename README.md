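# hermetia

Analysis toolkit for black soldier fly (*Hermetia illucens*) larvae (BSFL)
feeding trials on organic waste substrates. BSFL are used to bioconvert food
waste into insect biomass; evaluating how well a waste stream performs as a
diet requires (i) mass-budget bioconversion indices from the feeding trial,
(ii) multivariate analysis of the substrate physicochemistry before and after
processing, and (iii) 16S rRNA amplicon statistics for the larval gut
microbiome, including indicator taxa and imputed functional profiles. This
package implements that full pipeline, together with a synthetic-trial
generator with known ground truth so every estimator can be validated
offline, without sequencing data.

It is aimed at entomology / waste-valorization researchers who want the
classical Waldbauer-family indices and the standard microbiome test battery
(rarefaction, Bray–Curtis, NMDS, PERMANOVA, Mantel, indicator-species
consensus) in one reproducible, scriptable place.

## The core quantities

For each replicate box, a dry-matter budget is assembled: `I` substrate
offered, `R` total residue (uneaten + egesta), `E` feed ingested, `R_e`
egesta, `B` larval biomass gained, `A` time-averaged larval biomass, `T`
trial duration, and `L` per-larva fresh mass. The seven indices are

- growth rate `GR = (L_end − L_initial) / T` (mg d⁻¹, fresh),
- substrate reduction `SR = (I − R) / I × 100` (%),
- consumption index `CI = E / (T · A)`,
- waste reduction index `WRI = SR / T`,
- approximate digestibility `AD = (E − R_e) / E × 100` (%),
- efficiency of conversion of ingested food `ECI = B / E × 100` (%),
- efficiency of conversion of digested food `ECD = B / (E − R_e) × 100` (%).

Note the two distinct residue bases: `R` (total residue) in SR/WRI and `R_e`
(egesta only) in AD/ECD. The identities `ECI = ECD × AD / 100` and
`WRI = SR / T` hold for every valid budget and are enforced by tests.

Community statistics are built from scratch on an `abundance_table`
(samples × taxa counts + taxonomy + metadata): hypergeometric rarefaction,
abundance–prevalence filtering (count ≥ 4 in ≥ 10 % of samples), Shannon
`H′` and Pielou `J = H′/ln S`, Bray–Curtis `Σ|x−y| / Σ(x+y)`, Kruskal-stress
NMDS via isotonic regression + majorization, one-way PERMANOVA and Mantel
permutation tests, an IndVal.g multi-level pattern analysis, a
Kruskal–Wallis + discriminant effect-size screen, and their consensus.

## Worked example

```r
library(hermetia)

b <- mass_budget(I_offered_dry = 160000, R_residue_dry = 55000,
                 E_ingested_dry = 120000, R_egesta_dry = 62000,
                 B_gain_dry = 21000, A_mean_biomass = 8000, T_days = 18,
                 L_initial_fresh = 9.6, L_end_fresh = 171)
str(compute_indices(b)[1:7])
#> $ GR : num 8.97
#> $ SR : num 65.6
#> $ CI : num 0.833
#> $ WRI: num 3.65
#> $ AD : num 48.3
#> $ ECI: num 17.5
#> $ ECD: num 36.2
```

A box that ingested 120 g dry feed and gained 21 g dry biomass over 18 days
converted 17.5 % of ingested (36.2 % of digested) feed into biomass while
reducing the offered substrate by 65.6 %.

The full pipeline runs on a generated study bundle (three diets × four
boxes × 200 larvae, 36 gut communities with a planted *Morganella*-style
succession from 1 % to 88 % relative abundance on the waste diets):

```r
dir <- tempfile()
make_fixture_bundle(dir, seed = 1)
res <- run_pipeline(dir, out_dir = file.path(dir, "out"),
                    config = pipeline_config(seed = 1))

res$nmds$stress                      # 0.054 — well below the 0.2 rule
res$permanova_diet[c("statistic", "R2", "p_value")]
#> F = 5.22, R2 = 0.328, p ~ 0.005   — diet shapes the gut community
res$indicators[res$indicators$consensus, ]
#> Otu0001 (Morganella) — LDA 2.65, IndVal 0.99, group FWD+OWD
res$gap$optimal_k                    # 6 clusters from 7 sample groups
mean(res$functions$fraction_assigned)  # ~0.75 of reads functionally assignable
```

The consensus table recovers the planted bloom taxon as an indicator of the
two waste diets; the gap statistic merges the two overlapping oil-waste
sample groups, and the endpoint/index tables carry per-diet means ± sd with
Tukey letters.

A thin CLI wraps the same functions:

```sh
exec/hermetia simulate --seed 7 --out bundle/
exec/hermetia run-all --in bundle/ --out bundle/out
```

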