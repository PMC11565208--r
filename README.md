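# c4wue

Leaf- and whole-plant water-use-efficiency analysis for C4 crops.

C4 leaves concentrate CO2 at the site of fixation, so their A/ci response —
net assimilation *A*<sub>N</sub> against intercellular CO2 *c*<sub>i</sub> —
rises steeply and then saturates sharply. At today's atmospheric CO2 the
operating *c*<sub>i</sub> of a well-watered C4 leaf usually sits *above* that
inflection point, which means stomatal conductance (*g*<sub>s</sub>) can be
reduced — for example by engineering lower stomatal density — to save water
with little or no cost to carbon gain. `c4wue` packages the quantitative
machinery needed to test that idea in a greenhouse phenotyping experiment:

- **A/ci model and fitting.** The reduced enzyme-limited C4 model
  *A*(*c*<sub>i</sub>) = min(*V*<sub>pmax</sub>·*c*<sub>i</sub>/(*c*<sub>i</sub>+*K*<sub>p</sub>), *V*<sub>max</sub>) − *R*<sub>d</sub>,
  least-squares estimation of *V*<sub>pmax</sub> (apparent maximum PEPC
  carboxylation) and *V*<sub>max</sub> (the CO2-saturated asymptote) from
  stepped-CO2 curves, and replicate mean curves ± SE.
- **Stomatal limitation and iWUE.** The coupled supply–demand operating
  point (*A* = *g*<sub>s,CO2</sub>·(*c*<sub>a</sub> − *c*<sub>i</sub>)),
  stomatal limitation SL = (*A*(*c*<sub>a</sub>) − *A*(*c*<sub>i,op</sub>))/*A*(*c*<sub>a</sub>),
  the inflection *c*<sub>i</sub>\* = *V*<sub>max</sub>*K*<sub>p</sub>/(*V*<sub>pmax</sub> − *V*<sub>max</sub>),
  and intrinsic water-use efficiency iWUE = *A*<sub>N</sub>/*g*<sub>s</sub>.
- **Gravimetric water budgets.** Relative soil water content (rSWC) and
  daily water use from pot-mass series over a dry-down.
- **Stomatal patterning summaries.** Field-of-view densities, complex
  sizes, and surface/leaf-position tables.
- **The statistical layer.** One-way, two-way (Type-III) and
  repeated-measures ANOVA, Tukey HSD with compact letter displays,
  least-squares means ± SE, planned contrasts, per-day post-hoc flags.
- **A seeded synthetic-data generator** that emulates the whole experiment
  (stepped-CO2 gas exchange, a bucket-model dry-down, Poisson stomatal
  counts), so every stage is testable end to end without raw data.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted objects have `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a five-plants-per-genotype experiment (a wild type plus a strong
and a moderate low-stomatal-density line), run the full analysis, and look
at the headline traits:

```r
library(c4wue)

dir <- tempfile("expt")
simulate_experiment(dir, seed = 7, config = sim_config(n_plants = 5))
res <- analyze_experiment(dir, file.path(dir, "out"))

res$genotype_means          # Vpmax least-squares means by genotype
#> # A tibble: 3 × 4
#>   genotype     lsmean    se    df
#>   <fct>         <dbl> <dbl> <dbl>
#> 1 epf_moderate   94.7  1.08    12
#> 2 epf_strong     82.4  1.08    12
#> 3 WT            121.   1.08    12

res$limitation |>
  dplyr::group_by(genotype) |>
  dplyr::summarise(sl = mean(sl), iwue = mean(iwue), gs = mean(gs))
#> # A tibble: 3 × 4
#>   genotype        sl  iwue    gs
#>   <chr>        <dbl> <dbl> <dbl>
#> 1 WT               0  134. 0.321
#> 2 epf_moderate     0  178. 0.242
#> 3 epf_strong       0  167. 0.205
```

The generator imposed lower *g*<sub>s</sub> (−18% and −32%) and lower
photosynthetic capacity on the engineered lines; the fits recover the
*V*<sub>pmax</sub> scaling (121 → 94.7 and 82.4), iWUE rises in both
low-conductance lines (134 → 167–178 µmol mol⁻¹), and stomatal limitation
stays at zero because every operating point remains above the A/ci
inflection. The dry-down stage flags on which days the genotypes' soil
water content separates (`res$rswc_tukey`), and `report.txt` in the output
directory collects all stages in plain text.

The central theoretical question — what does a conductance reduction cost
in stomatal limitation? — has a one-line answer:

```r
sl_scenario(c4_params(vpmax = 120, vmax = 45, kp = 80, rd = 2),
            ca = 400, target_ci = 160, reduction = 0.2)
#> # A tibble: 1 × 6
#>   gs_co2 ci_before ci_after sl_before sl_after delta_sl
#>    <dbl>     <dbl>    <dbl>     <dbl>    <dbl>    <dbl>
#> 1  0.179       160      100         0        0        0
```

Starting from an operating *c*<sub>i</sub> of 160 µmol mol⁻¹ (inflection at
48), a 20% cut in conductance drops *c*<sub>i</sub> to 100 but changes SL by
exactly zero: both operating points sit on the CO2-saturated branch.

A thin command-line front end over the same functions is installed at
`inst/cli/c4wue.R` (subcommands `simulate`, `analyze`, `sl-scenario`,
`fit-aci`, `drydown`, `stomata`).

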