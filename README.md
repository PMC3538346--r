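# tetramap

Genetic analysis of budding-yeast meiosis from dissected tetrads, for
geneticists mapping crossover defects in recombination mutants. The package
covers the full analysis chain of a multi-chromosome tetrad study:

* **Tetrad classification** — parental ditype / tetratype / nonparental
  ditype (PD/TT/NPD) calls per marker interval, with gene-conversion and
  missing-call handling;
* **Map distances** — the Perkins estimator
  cM = 100·(TT/2 + 3·NPD)/(PD+TT+NPD) with multinomial delta-method
  standard errors, and single-spore recombination frequencies
  100·R/(P+R); cumulative distances and fold changes between genotypes;
* **Aberrant segregation** — 3:1/1:3 tallies per marker from
  four-spore-viable tetrads;
* **Spore viability** — viable-spores-per-tetrad profiles, percent
  viability, a meiosis-I nondisjunction (4-2-0) bias score, χ² genotype
  comparisons, and the viability-versus-distance regression;
* **Fluctuation assays** — Luria–Delbrück mutation rates by the Drake
  median method (r/m − ln m = 1.24) with nonparametric order-statistic
  confidence intervals and relative rates;
* **Obligate-crossover modelling** — expected crossovers per chromosome
  after a fold reduction, Poisson achiasmate (E0) probabilities, and an
  exact tetrad-viability distribution under meiosis-I nondisjunction;
* **Synthetic meiosis** — a chromatid-level simulator (Poisson crossovers,
  mean d/50 per interval, no chromatid interference, two pathway classes,
  marker-local gene conversion, nondisjunction-driven spore death,
  Luria–Delbrück cultures) with reproducible manifests, plus genotype
  presets calibrated to the bundled study tables.

The per-interval and per-strain summary tables of a published *mlh3*/*mms4*
tetrad study ship as plain-text fixtures (`loadFixture("table3")` …
`"table8"`), so every estimator can be checked against printed values.
Deletion genotypes are spelled with a trailing `d` (`mlh3d`, `mms4d`,
`msh5d`).

## Worked example

```r
library(tetramap)

## Perkins map distance of the wild-type URA3-LEU2 interval (chromosome XV)
t5 <- loadFixture("table5")
wt <- subset(t5, genotype == "wild type" & interval == "URA3-LEU2")
perkinsEstimate(wt$PD, wt$TT, wt$NPD)
#>         cM        se   ci_low  ci_high    n         method
#> 1 22.75281 0.9535434 20.88386 24.62175 1068 perkins_tetrad

singleSporeCM(wt$parental, wt$recombinant)
#> [1] 21.72696

## Fold decrease in crossing over, double mutant vs wild type, per chromosome
t6   <- loadFixture("table6")
this <- subset(t6, source == "this_study")
w <- subset(this, genotype == "wild type")
d <- subset(this, genotype == "mlh3d mms4d")
data.frame(chromosome = w$chromosome,
           fold = foldDecrease(w$cumulative_cM, d$cumulative_cM))
#>   chromosome fold
#> 1        III  6.1
#> 2        VII  7.2
#> 3       VIII 16.5
#> 4         XV 11.4

## Spore viability falls linearly with map distance across the mlh3 panel
t4 <- loadFixture("table4")
m  <- subset(t4, group == "mlh3")
fitViabilityVsDistance(m$cumulative_cM, m$spore_viability_pct)$r_squared
#> [1] 0.8713765

## After those fold reductions, which chromosomes still expect a crossover?
crossoverScreen(c(III = 3, VII = 8, VIII = 4, XV = 7),
                c(III = 6.1, VII = 7.2, VIII = 16.5, XV = 11.4))
#>   chromosome wt_mean fold  expected        e0 at_least_one
#> 1        III       3  6.1 0.4918033 0.6115227        FALSE
#> 2        VII       8  7.2 1.1111111 0.3291930         TRUE
#> 3       VIII       4 16.5 0.2424242 0.7847232        FALSE
#> 4         XV       7 11.4 0.6140351 0.5411628        FALSE
```

The Perkins point estimate (22.75 cM) sits inside the printed 95% interval
(21.8–23.8); only chromosome VII keeps an expected crossover in the double
mutant, so the high observed spore viability implies achiasmate chromosomes
usually still disjoin — the question the obligate-crossover model
(`viabilityDistribution()`) quantifies.

A full synthetic study (tetrad tables, marker map, fluctuation inputs,
JSON manifests) is one call:

```r
runSimulation("study/", seed = 7)                       # four genotype presets
runAnalysis("report/", tetradFiles = ..., map = "study/marker_map.tsv")
```

or from the shell via `inst/scripts/tetramap.R`
(`analyze`, `simulate`, `fluctuation`, `fixtures` subcommands).

## Methods

The model assumptions, parameter choices, calibration of the genotype
presets and validated ranges are documented in
`vignettes/tetramap-methods.Rmd`.
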