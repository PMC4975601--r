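# biocogs

Cost-of-goods modelling and uncertainty analysis for recombinant protein
bioprocesses, built around the manufacture of Royalactin (major royal
jelly protein 1) by *Pichia pastoris* fermentation with aqueous two-phase
extraction (ATPS) and ultrafiltration/diafiltration (UF/DF) recovery.

A beekeeper recovers roughly 35 g of Royalactin a year from royal jelly;
any real application needs recombinant manufacture, and the question for a
process developer is what a gram would cost at scale and which parameter —
fermentation titer, annual target output, material prices, DSP yield,
wages — most controls that cost. `biocogs` is an open, configuration-
driven implementation of that analysis: a flowsheet mass balance and batch
schedule, an annual cost engine, one-at-a-time (tornado) scenario
sensitivity, joint Monte Carlo uncertainty analysis with triangular input
distributions, and a linear sensitivity meta-model with an α-level
significance screen.

## The model in brief

Per-batch product mass is `m = titer × V_ferm × y_DSP`; the plant runs
`B = ⌈T/m⌉` batches to meet the annual target `T`, capacity permitting.
Annual cost sums amortized facility capital, per-batch consumables and
materials (a ±% deviation applies only to the dominant items: fermentation
medium and UF/DF membranes), labor (sized to 13% of total cost via a
closed-form fixed point), and QC/overheads; `CoG/g = total cost / annual
mass`. The uncertain inputs are described by triangular (min, mode, max)
distributions; the meta-model is OLS of CoG/g on titer, target output and
material cost with two-sided t-tests on `n − 4` df.

Free cost constants (equipment scale, two dominant prices, QC per batch,
fermenter volume) are calibrated by bounded Nelder–Mead search to the
published anchors: base CoG/g within 1% of $843, labor at 13%, capital the
largest cost category, UF/DF the dominant consumables operation.

## Worked example

```r
library(biocogs)

cal <- calibrated_model(seed = 1)
cal$costs
#> Annual cost breakdown (55 batches, 471.2 g/batch):
#>   capital           7,427,883  (34.0%)
#>   consumables       6,258,729  (28.7%)
#>   materials         2,546,515  (11.7%)
#>   labor             2,845,829  (13.0%)
#>   other             2,748,750  (12.6%)
#>   total            21,827,705
#> CoG/g: 842.30 (basis: actual mass 25915 g/yr)
```

The calibrated base case makes 25.6 kg/yr in 55 batches at $842.30/g, with
capital the largest category and labor held at 13%. One-at-a-time
perturbation to the worst/best scenario values ranks the cost drivers:

```r
tornado(cal$params, build_scenarios(cal$params), cal$flowsheet,
        cal$prices, cal$staffing)
#> Tornado analysis (base CoG/g = 842.30)
#>           parameter   worst   best impact feasible
#>  fermentation_titer 1387.48 691.52 545.19
#>       target_output 1234.01 641.05 391.71
#>       material_cost  915.97 768.63  73.67
#>       operator_wage  874.52 841.08  32.22
#>           dsp_yield  852.08 840.17   9.78
```

Titer leads, and its downside (+545) outweighs its upside (−151): CoG/g is
convex in 1/titer. Joint Monte Carlo (300 runs) before and after a
22.5-fold titer optimization (0.242 → 5.44 g/L), followed by the linear
meta-model:

```r
before <- run_monte_carlo(mc_config_before(seed = 1), cal$params,
                          cal$flowsheet, cal$prices, cal$staffing)
after  <- run_monte_carlo(mc_config_after(seed = 1), cal$params,
                          cal$flowsheet, cal$prices, cal$staffing)
before$summary
#>      mean    median     range        sd
#>  829.1592  802.1906  748.5643  148.1879
after$summary
#>      mean    median     range        sd
#>  334.0694  318.9960  369.0896   79.2236

fb <- fit_ols(before); fa <- fit_ols(after)
significance_screen(fb, alpha = 0.01)
#>     intercept         titer target_output material_cost
#>          TRUE          TRUE          TRUE          TRUE
significance_screen(fa, alpha = 0.01)
#>     intercept         titer target_output material_cost
#>          TRUE          TRUE          TRUE         FALSE
```

Optimizing titer cuts both the level and the spread of CoG/g, and the
material-cost term loses significance at α = 0.01. Ranking drivers by
|coefficient| × sampled span shows the strategic consequence:

```r
spans <- function(cfg) vapply(cfg$distributions,
                              function(d) d$max - d$min, numeric(1))
strategy_shift_report(fb, fa, spans(mc_config_before(1)),
                      spans(mc_config_after(1)))
#> Driver ranking (influence = |coefficient| x span):
#>   before: titer > target_output > material_cost
#>   after:  target_output > titer > material_cost
#> Lost significance at alpha = 0.01: material_cost
#> Strategy: titer-driven before, target_output-driven after
```

A low-titer process is *process-oriented* — improve the fermentation; an
optimized one is *product-oriented* — the annual target output (market
capture) dominates the cost of goods.

All analyses are also reachable from the shell via the thin CLI
(`inst/cli/biocogs.R`) with subcommands `fixtures`, `validate`, `size`,
`run`, `tornado`, `mc`, `fit` and `calibrate`.

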