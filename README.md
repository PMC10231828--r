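# natalscape

Natal-origin assignment of migratory marine fish from otolith stable
isotopes and oxygen isoscapes.

Populations of migratory fish such as Northwest Atlantic mackerel are
often mixtures of sub-units ("contingents") that spawn in separate
nursery regions — e.g. a northern contingent in the Gulf of St.
Lawrence and a southern contingent on the US shelf — but overlap on the
fishing grounds. Assessing each unit requires estimating, for every
sampled adult, where it was born. The chemistry of the otolith's first
annulus preserves that information: aragonite δ¹⁸O (‰ VPDB) decreases
with water temperature and increases with salinity-linked seawater
δ¹⁸O, and δ¹³C adds a second discriminating axis.

`natalscape` implements a two-stage framework for fisheries and
movement ecologists:

1. **Nominal assignment.** A registry of probabilistic classifiers
   (LR, MELR, LDA, QDA, ANN, DT, kNN, NB, RF, SVM, plus a null
   benchmark) is 10-fold cross-validated on a balanced, standardized
   known-origin baseline (otolith δ¹⁸O, δ¹³C, year-class). The top
   performers are combined by model averaging with weights proportional
   to cross-validated accuracy,
   `w_k = Acc_k / Σ_j Acc_j`, `p = Σ_k w_k p_k`,
   and an adult is assigned *northern* when `p > τ`, *southern* when
   `1 − p > τ` (τ = 0.7), and abstains otherwise.
2. **Continuous assignment.** Per-year, per-contingent otolith-δ¹⁸O
   isoscapes are built from gridded temperature and salinity through
   water-mass mixing lines (`δ¹⁸O_sw = 0.55·S − 18.98` offshore,
   `0.27·S − 10.3` in the estuarine plume region) and the linear
   aragonite fractionation model `δ¹⁸O_oto = −0.25·T + 4.46 + δ¹⁸O_sw`,
   seasonally averaged over each contingent's first growing season.
   Bayes' rule with the combined measurement SD
   `σ = √(σ_analytical² + σ_within-pop²) = √(0.1² + 0.29²) ≈ 0.307 ‰`
   converts each fish's δ¹⁸O into a posterior probability-of-origin
   surface; rank-based binarization at the 75th percentile marks
   "likely" natal cells, per-cohort averages of the binary maps give
   nursery heat maps, and an accuracy–precision sweep over thresholds
   0.05–0.95 calibrates the binarization against known-origin fish.

A seeded synthetic module generates baselines, monthly ocean grids,
region masks, and known-origin validation fish with the statistical
structure the framework assumes, so the entire workflow runs with no
external data. Real gridded inputs (e.g. 1° monthly temperature and
salinity at 5 m depth) can be supplied as netCDF.

## Worked example

```r
library(natalscape)

cfg      <- synthetic_config(seed = 7, year_classes = 2013:2016)
baseline <- gen_baseline(cfg)
ds       <- standardize_baseline(oversample_balance(baseline, seed = 7))
model    <- fit_ensemble(ds, seed = 7, rule = list(top_k = 5))
model
#> <ensemble_model> 5 members, tau = 0.70
#>   weights: LR=0.203, LDA=0.202, SVM=0.200, ANN=0.198, QDA=0.197
#>   cross-validated: accuracy 0.871, AUC 0.911, log-loss 0.413
```

The five best members are weighted almost equally because their
cross-validated accuracies are similar; the averaged classifier
reaches 87% out-of-fold accuracy on this synthetic baseline.

```r
adults      <- prepare_adults(ds, gen_adults(cfg, 20))
assignments <- classify_adults(model, adults)
head(assignments, 4)
#>      fish_id year_class p_northern   decision
#> 1 a_2013_001       2013      0.964   northern
#> 2 a_2013_002       2013      0.510 unassigned
#> 3 a_2013_003       2013      0.987   northern
#> 4 a_2013_004       2013      0.096   southern
composition_report(assignments)
#>   year_class  n n_northern n_southern n_unassigned pct_northern pct_unassigned
#> 1       2013 20         11          6            3         64.7             15
#> 2       2014 20          7          9            4         43.8             20
#> 3       2015 20          4         12            4         25.0             20
#> 4       2016 20          0         16            4          0.0             20
```

Fish with membership probability in (0.3, 0.7] abstain and are excluded
from the geographic stage; `pct_northern` is computed among assigned
fish only. Next, the continuous stage on the same synthetic ocean:

```r
masks <- gen_masks(cfg)
ocean <- gen_ocean(cfg, 2016)
iso   <- build_isoscape(ocean$temperature, ocean$salinity, 2016, "southern",
                        lines = masks$mixing_lines,
                        domain_mask = masks$full, shelf_mask = masks$shelf)
iso
#> <isoscape> southern 2016 (months 5-6-7): 193 defined cells,
#>            range -2.19 .. 1.33 permil VPDB

fish  <- gen_known_origin_fish(cfg, iso, 200, masks$subregions)
curve <- threshold_sweep(fish, setNames(list(iso), "2016"),
                         variance_model(), masks$subregions,
                         q_grid = seq(0.15, 0.95, 0.2))
curve
#> <validation_curve> 5 thresholds, chosen q = 0.75 (floor 0.70)
#>     q accuracy
#>  0.15    1.000
#>  0.35    1.000
#>  0.55    1.000
#>  0.75    0.990
#>  0.95    0.675
```

The isoscape spans 3.5 ‰ across the shelf, so a measurement SD of
0.307 ‰ localizes fish well: 99% of 200 known-origin fish are
recovered to their collection subregion at the 75th-percentile
threshold, and accuracy degrades only at the most restrictive
threshold — the accuracy–precision trade-off the sweep is designed to
expose. `posterior_surface()`, `binarize()`, and
`summarize_surfaces()` expose the per-fish surfaces and per-cohort
heat maps; each object has a `plot()` method.

`run_pipeline(default_config(), "run/")` executes the whole chain and
writes CSV/JSON/netCDF outputs plus a manifest with seeds, timings, and
file digests. A thin command-line wrapper with subcommands `simulate`,
`classify`, `isoscape`, `validate`, and `pipeline` is installed at
`inst/cli/natalscape.R`.

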