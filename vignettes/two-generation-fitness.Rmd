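---
title: "Two-generation fitness projection for gregarious egg parasitoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-generation fitness projection for gregarious egg parasitoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twogenfit)
```

## The biological problem

A gregarious idiobiont egg parasitoid lays one to several offspring into a
single host egg. Because the host stops developing at parasitization, the
egg is a fixed food supply: every extra larva in a clutch leaves less for
each, so offspring from large clutches emerge smaller, and smaller females
are less fecund. A female's clutch-size decision therefore trades her own
offspring count (F1 fertility) against the future fertility of each
daughter (F2 fertility). Evaluating fitness by counting F1 offspring alone
misses this; the two-generation approach scores a founder by her projected
grand-offspring.

The model species is a wasp that parasitizes leaf-beetle eggs on a cereal
crop. When the herbivore colonises a novel plant, the wasp following it
encounters both an unfamiliar substrate and, potentially, eggs of other
beetles ("fictitious hosts") that it accepts for oviposition although its
larvae cannot complete development in them. Both situations change clutch
size in F1 and thus fertility in F2.

## The fertility mapping

The package collapses the causal chain clutch size → body size →
fertility into the direct mapping

$$\mathrm{fertility}(c) = \mathrm{round}\,(\,20 - \sqrt{c}\,),\qquad
  c = 1,\dots,7,$$

implemented by `fertility_model()` / `fertility_of_clutch()`. The base
(20) and the square-root decay are the fitted description of measured
per-clutch-size fertility means; the measured means themselves are not
re-derivable inside this package, so the mapping is taken as given and is
parameterizable (`base`, `max_clutch`) for other systems. Rounding is to
the nearest integer; exact halves round away from zero. That tie rule
never fires under the defaults (the square roots of 2, 3, 5, 6, 7 are
irrational) but must be fixed for configurability. The mapping is
non-increasing over the support, which is what drives every qualitative
result downstream: moving offspring into smaller clutches can only raise
per-offspring F2 fertility.

With sizes 1–7 and any sex partition, a female chooses among
`nrow(enumerate_clutch_configs(7))` = 35 clutch configurations.

## Projection and scenario comparison

`project_f2()` scores each founder from a tidy per-host-egg table:

* F1 eggs laid — all eggs, including those wasted in fictitious hosts;
* F1 fertility — offspring emerging from native hosts;
* F2 fertility — \(\sum_h \mathrm{females}_h \times
  \mathrm{fertility}(\mathrm{size}_h)\) over parasitized native hosts.

Fictitious-host clutches contribute to egg expenditure only: the founder
is treated as pro-ovigenic (fixed egg complement), so eggs laid there are
lost from the budget but produce no emerging offspring.

`compare_scenarios()` pools founders by group and reports the
per-offspring F2 mean as a ratio of sums (total F2 over total emerged
females) rather than a mean of per-founder ratios. The ratio of sums is
defined even when individual founders have no emerged daughters and
weights founders by their contribution; groups with zero emerged females
overall are excluded from percent differences with a warning. Percent
differences are printed in both directions, \((a-b)/b \times 100\),
because "group A exceeds B by x%" and "B falls short of A by y%" differ.

Representative founders for deterministic scenario comparisons are built
by `founder_from_profile()` from a clutch-size frequency table:
expected-mode allocation followed by expected-mode sex assignment at the
species' 3:1 male:female ratio (`p_female = 0.25`).

## Distributing offspring over hosts

`allocate_offspring()` splits a fixed offspring total into clutches
following a frequency distribution.

*Expected mode* is deterministic: the expected clutch count is the total
divided by the distribution mean; per-size counts are rounded by the
largest-remainder method (ties toward smaller sizes); and a repair loop
then walks to exact feasibility — shrinking the largest clutch while the
allocation overshoots, growing the smallest under-cap clutch or adding a
singleton while it undershoots, and merging the two smallest clutches
when too many hosts are used. Every step is deterministic, so expected
mode is bit-reproducible, which is what makes it usable as a test anchor.

*Sampled mode* draws clutch sizes i.i.d. from the distribution and
accepts a sequence only if it hits the total exactly within the host
limit. Rejection sampling keeps the sampling distribution clean: each
feasible multiset appears with probability proportional to its
multinomial weight under the frequency distribution (verified against a
brute-force enumeration oracle in the tests). After 10,000 rejections the
deterministic allocation is returned with a warning; in the regimes the
package simulates (totals up to a few tens, hosts up to twelve) rejection
rates are far below that bound.

Expected-mode sex assignment places `round(p_female × total)` females one
per clutch in descending clutch-size order, wrapping until exhausted, so
females are spread across hosts; the convention is arbitrary but
deterministic and documented. Sampled mode is an independent binomial per
clutch.

## What the synthetic generator emulates

The observed per-egg records behind the study exist only as
non-machine-readable supplementary media, so `generate_trials()` supplies
data with the same structure:

* **Designs.** The built-in scenarios reproduce the experimental arms:
  three no-choice arms (12 native eggs on the usual plant, the novel
  plant, or filter paper; 20 founders each), the choice arm (4 eggs on
  each of the three substrates simultaneously; 20 founders), and the
  fictitious-host arms (6 native + 6 fictitious eggs on the novel plant,
  15 founders; 6 native, 11 founders; 12 native, 19 founders).
* **Parasitism.** Bernoulli per offered egg with a substrate-specific
  probability on the logit scale plus a founder-level Normal intercept
  (`dish_sd`, default 0.5) — the Petri-dish overdispersion that the dish
  random factor in the mixed models is designed to absorb. With
  `dish_sd = 0` the marginal rate equals the configured probability; with
  `dish_sd > 0` the marginal rate is attenuated relative to the
  conditional one, which is why the parameter-recovery calibration runs
  at `dish_sd = 0`, where the method-of-moments estimator is unbiased.
* **Clutches.** Per parasitized egg, a draw from the substrate's
  clutch-size distribution truncated and renormalised to the remaining
  egg budget (`egg_budget`, default 32). Truncation is generator
  semantics, not biology: it preserves support validity when the budget
  runs low. The species' true egg complement is not printed in the
  source study; 32 is a package default sized so that a 12-egg arm
  rarely exhausts it, and it is configurable.
* **Sexes.** Binomial at `p_female = 0.25` (3:1 male:female).
* **Fictitious hosts.** Parasitoid offspring never emerge there. The
  host beetle's own emergence is an independent Bernoulli — 0.22 if the
  egg was parasitized, 0.94 if not — matching the reported rates for
  parasitized and untouched fictitious eggs.

The default clutch-size frequency table (`default_clutch_dist()`, mode at
2–3) is synthetic: the observed frequency tables are not publicly
deposited. Because of that, deterministic profile comparisons run on
these defaults show the *direction* of the choice-test F2 gain (smaller
clutches → higher per-offspring F2) but not its published magnitude
(about 13%); reproducing the magnitude requires supplying the observed
frequency tables through `read_clutch_freqs()`. Passing tests therefore
demonstrate correctness of the machinery on data with the right
structure, not agreement with the unpublished measurements.

`recover_params()` closes the loop: method-of-moments estimates of the
parasitism probability (Clopper–Pearson 95% CI), clutch mean (t CI) and
female proportion (Clopper–Pearson) recover the generating values, with
CI coverage checked over 100 seeded replicates in the acceptance tests.

## The statistical battery

`fit_model()`/`lrt_compare()`/`run_paper_battery()` mirror the study's
conventions per response:

| response | model | notes |
|---|---|---|
| per-dish offspring total | LM | dish-level aggregation; no random effect (one row per dish) |
| parasitism (per egg) | GLM-b | binomial, logit link |
| offspring sex ratio | GLMM-b | `cbind(females, males)`, dish random intercept |
| clutch size | GLMM-p / LMM | Poisson on `clutch − 1`, dish random intercept |

Mixed models are fitted by Laplace approximation via lme4 with ML (not
REML) so that likelihood-ratio comparisons against null models holding
only the random factor are valid. The minus-one shift moves clutch-size
support onto 0, 1, 2, … where a Poisson family is meaningful; predictions
shift back for reporting. Likelihood-ratio statistics are clamped at zero
(with a warning) when optimizer noise makes them marginally negative;
degrees of freedom are parameter-count differences. Non-convergence is
flagged on the handle, never silent. No multiple-testing correction is
applied by default, matching the per-contrast presentation; `holm = TRUE`
adds Holm-adjusted p-values. One published contrast is reported with an F
statistic amid the chi-square comparisons; the battery uses the LRT
uniformly.

The published chi-square and p values were computed on the unpublished
raw data and are not desk-reproducible, so the battery's correctness is
established by calibration instead: on null simulations (no substrate
effect, 20 founders × 12 eggs, 1,000 replicates) the parasitism LRT
rejects at close to the nominal 5%, and the Wald 95% CI for a simulated
substrate log-odds ratio of log 3 covers the truth at close to 95% (500
replicates). Those replicate counts keep the whole test suite around a
minute of fitting while leaving Monte-Carlo error well inside the
asserted bands.

## Numerical and design choices

* Seeds: every stochastic stage takes an explicit seed;
  `derive_seed(global, stage)` gives each pipeline stage an independent
  deterministic stream. RNG state is saved and restored around seeded
  calls so library functions do not perturb the caller's stream.
* Degenerate inputs: zero offspring allocate to an empty vector; a
  founder with no parasitized hosts projects F2 = 0 with an undefined
  per-offspring mean; probabilities of exactly 0 or 1 bypass the logit
  jitter so degenerate scenarios stay exact.
* `total_offspring` with a dish random intercept is refused: with one
  row per dish the intercept is not identifiable.
* Clutch distributions are validated (support ≥ 1, at least one positive
  weight) and normalised once at construction; normalisation tolerance
  is exact up to floating-point summation.

## Known limitations

* The fertility mapping is deterministic; no residual variation around
  the fitted curve is simulated, so projected F2 variances understate
  real ones.
* Substrate preference enters only through substrate-specific parasitism
  probabilities; no learning or sequential choice dynamics.
* No F3 projection, and no optimal-clutch-size search: the package
  evaluates given strategies.
* The generator's dish effect is Normal on the logit scale only;
  alternative overdispersion shapes (e.g. beta-binomial) are not
  implemented.
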