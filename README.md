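# twogenfit

Two-generation fitness projection for gregarious egg parasitoids.

## The problem

Gregarious idiobiont egg parasitoids lay 1–7 offspring into a single host
egg. The host egg is a fixed food supply, so larger clutches produce
smaller adults, and smaller females are less fecund. A female's fitness is
therefore not captured by counting her offspring (F1): two females with
identical F1 fertility can leave very different numbers of grand-offspring
(F2) depending on how they packed their eggs into hosts. This matters when
a wasp follows its herbivore host onto a novel plant, where it may also
waste eggs on "fictitious" hosts — beetle eggs it accepts for oviposition
but in which its larvae cannot complete development.

`twogenfit` is for ecologists modelling clutch-size decisions in such
systems. It provides:

* the clutch-size → fertility mapping
  `fertility(c) = round(20 − √c)`, `c = 1..7`, and the enumeration of all
  35 clutch configurations (size × female count);
* the two-generation projection
  `F2 = Σ_hosts females_h × fertility(size_h)` over parasitized native
  hosts, with eggs in fictitious hosts counted as spent but sterile;
* deterministic and stochastic allocation of offspring over host eggs from
  clutch-size frequency tables, and sex assignment at the species' 3:1
  male:female ratio;
* a synthetic-data generator reproducing the structure of the underlying
  factorial experiments (no-choice / choice / fictitious-host designs,
  dish-level overdispersion, 22% vs 94% fictitious-host-egg emergence);
* the matching statistical battery: LM, binomial GLM, binomial/Poisson
  mixed models with a dish random intercept (via lme4, ML), compared by
  likelihood-ratio tests, plus exact Clopper–Pearson and Poisson
  confidence intervals.

## Worked example

Two founders each lay 8 offspring, 2 of them female: one spreads them over
8 singleton clutches, the other packs them into two clutches of four.

```r
library(twogenfit)

a <- founder_from_profile("spread", total_offspring = 8, n_hosts = 8,
                          dist = clutch_dist(c(`1` = 1)))
b <- founder_from_profile("packed", total_offspring = 8, n_hosts = 2,
                          dist = clutch_dist(c(`4` = 1)))
cmp <- compare_scenarios(rbind(a, b))
cmp$groups
#>    group n_founders mean_f1_fertility mean_clutch mean_f2_fertility
#> 1 packed          1                 8           4                36
#> 2 spread          1                 8           1                38
#>   total_f1_females per_offspring_f2
#> 1                2               18
#> 2                2               19
cmp$percent_diff
#>   group_a group_b percent_diff
#> 1  spread  packed         5.56
#> 2  packed  spread        -5.26
```

Same F1 fertility, but the spreading founder's daughters each carry
fertility 19 (singleton clutch) instead of 18 (clutch of four): a 5.6%
per-offspring F2 advantage. This is the mechanism by which choice-test
females — who lay fewer offspring in smaller clutches — gain F2 fertility
relative to no-choice females.

Simulating an experiment and projecting it:

```r
tab  <- generate_trials(scenario_spec("fict_host_mix"),
                        generator_params(), seed = 11)
head(project_f2(tab), 3)
#>          founder_id         group f1_eggs_laid f1_fertility f1_females
#> 1 fict_host_mix_001 fict_host_mix           18            6          1
#> 2 fict_host_mix_002 fict_host_mix           24           10          1
#> 3 fict_host_mix_003 fict_host_mix           32           13          2
#>   mean_clutch f2_fertility mean_offspring_fertility
#> 1       2.000           19                       19
#> 2       2.500           18                       18
#> 3       2.167           38                       19
```

Founder 001 laid 18 eggs but only 6 offspring emerged: the rest went into
fictitious hosts, where development fails.

## The analysis workflow

The `analysis/` scripts run the full study on synthetic data and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # all seven experimental arms -> CSVs + manifests
Rscript analysis/02_project.R    # per-founder F2 projection + scenario comparison
Rscript analysis/03_stats.R      # the LRT contrast grid
Rscript analysis/04_profiles.R   # deterministic choice vs no-choice profiles
```

Observed clutch-size frequency tables (not shipped; the originals are not
publicly deposited) can be supplied via `read_clutch_freqs()` to replace
the synthetic defaults in `04_profiles.R`.

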