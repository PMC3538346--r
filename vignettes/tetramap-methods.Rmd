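---
title: "Methods: tetrad linkage analysis, fluctuation assays, and the obligate-crossover viability model"
author: "tetramap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tetrad linkage analysis, fluctuation assays, and the obligate-crossover viability model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramap)
```

# Scope

`tetramap` implements the genetic-analysis toolkit used in budding-yeast
meiosis studies that dissect tetrads across multiply-marked chromosomes:
tetrad classification and Perkins map distances, single-spore recombination
frequencies, cumulative distances and fold changes between genotypes,
aberrant (3:1/1:3) marker segregation, spore-viability profiles with a
meiosis-I nondisjunction score, Luria–Delbrück fluctuation-assay mutation
rates, an exact obligate-crossover viability model, and a chromatid-level
meiosis simulator that generates realistic synthetic dissection data. The
per-interval and per-strain summary tables of a published *mlh3*/*mms4*
tetrad study are bundled as plain-text fixtures so every estimator can be
exercised against real printed numbers.

# Tetrad classification and map distances

For two linked markers, a four-spore-viable tetrad falls into one of three
classes: parental ditype (**PD**, only the two parental allele
combinations), nonparental ditype (**NPD**, only the two recombinant
combinations), and tetratype (**TT**, all four combinations once). A tetrad
is **unscorable** for an interval when either marker deviates from 2:2
segregation (gene conversion) or any spore lacks a call;
`classifyInterval()` implements exactly this case analysis, and the test
suite checks it against an independent exhaustive-case oracle over every
possible two-marker genotype assignment.

The Perkins estimator corrects the naive recombination fraction for
four-strand double crossovers:

$$\mathrm{cM} = 100\,\frac{TT/2 + 3\,NPD}{PD + TT + NPD}.$$

Two denominator conventions are possible when some complete tetrads are
unscorable for an interval. `tetramap` divides by the *scored* tetrads
(PD+TT+NPD), not all complete tetrads: in the bundled double-mutant rows
where ten of 170 tetrads are unscorable, only the scored-tetrad denominator
reproduces point estimates inside the printed confidence intervals.

The standard error treats (PD, TT, NPD) as a multinomial sample and
propagates through the (linear) Perkins statistic: with $f_T = TT/n$,
$f_N = NPD/n$,

$$\mathrm{se} = 100\sqrt{\tfrac{1}{n}\left(\tfrac14 f_T(1-f_T) +
9 f_N(1-f_N) - 3 f_T f_N\right)},$$

with a normal 95% interval floored at zero. The original analyses used an
external web tool whose interval construction is not documented; our
delta-method intervals may therefore differ slightly from printed CI
bounds, and validation asserts containment of point estimates in printed
intervals rather than CI equality. The delta-method se itself is verified
against a parametric multinomial bootstrap (agreement within 10% at
n = 500).

Single-spore distances are plain recombination frequencies,
$100\,R/(P+R)$, computed over *every* viable spore scored at both flanking
markers — including spores from incomplete tetrads and from tetrads that
are unscorable at the tetrad level. This is why the packaged tables have
more single spores than $4\times$ the tetrad count.

Cumulative distances add point estimates along a chromosome; standard
errors combine in quadrature. Report output rounds cM and fold changes to
one decimal, matching the tables; machine-readable output keeps full
precision. One packaged single-spore cell is internally inconsistent with
its own printed counts (the double-mutant *CEN3–MAT* entry equals the
chromosome III single-spore *sum*, 2.4+2.5+3.6 = 8.5, rather than the
interval value 3.6 that its counts imply); the fixture preserves the
printed value verbatim and the validation suite documents the
inconsistency instead of silently skipping the row.

$\chi^2$ comparisons (spore viability, sporulation) use the Pearson
statistic without continuity correction on 2×k tables, df = k−1. The
viability-versus-distance relationship is ordinary least squares of percent
spore viability on cumulative cM; on the ten bundled *mlh3*-panel strains
(wild type, the deletion, eight ATPase-domain point mutants) it reproduces
the published $R^2 = 0.87$.

# Fluctuation assays

Mutation rates from parallel-culture reversion assays use the median
method: the median mutant count $\tilde r$ maps to expected mutations per
culture $m$ through

$$\tilde r/m - \ln m = 1.24,$$

solved by bracketed root finding (`uniroot`, relative tolerance $10^{-9}$;
the left side is strictly decreasing so the root is unique). The rate is
$m/N_t$ with $N_t$ the cells at risk per culture. The original reports cite
a textbook order-statistic construction for 95% confidence limits without
reproducing it; `tetramap` uses the normal approximation to the
binomial$(n, \tfrac12)$ order statistics,
$l = \lfloor (n - 1.96\sqrt n)/2 \rfloor$,
$u = \lceil (n + 1.96\sqrt n)/2 \rceil$ (ranks (3, 12) at n = 15), each
bound transformed through the same Drake equation. Because the raw culture
counts behind the printed rates are not published, this choice is validated
by coverage simulation (≥85% over seeded synthetic assays) rather than
against printed intervals. Relative rates divide by the reference-strain
rate and are reported to one decimal below 10, three significant digits
above, matching the printed convention. Ma–Sandri–Sarkar maximum
likelihood, plating-efficiency and differential-fitness corrections are out
of scope — the analyses reproduced here did not use them.

Absolute rates require $N_t$, which the printed tables do not give
per culture; synthetic assays therefore carry their own $N_t$ (default
$2\times10^7$), and only *relative* rates are validated against printed
numbers — specifically the rows whose printed ratios are arithmetically
consistent with the printed rounded medians (16.0/4.71 → 3.4 and
30.5/4.71 → 6.5).

# The obligate-crossover viability model

Every yeast homolog pair needs at least one crossover to direct its
meiosis-I disjunction. When crossovers drop genome-wide by a fold $F$, a
chromosome with wild-type mean $\lambda$ crossovers expects $\lambda/F$;
modelling per-meiosis counts as Poisson (the minimal completion of a
means-only argument), the chance of an achiasmate (E0) meiosis is
$e^{-\lambda/F}$. Under the double-mutant fold reductions (6.1, 7.2, 16.5,
11.4 on III, VII, VIII, XV against wild-type means 3, 8, 4, 7), only
chromosome VII retains an expected crossover — `crossoverScreen()`
reproduces that arithmetic.

`viabilityDistribution()` turns per-chromosome E0 probabilities into an
exact distribution of viable spores per tetrad. Each chromosome
independently is chiasmate, achiasmate-but-disjoined (probability
`pDisjoin`), or nondisjoined; an MI nondisjunction makes a uniformly chosen
disjoint spore pair nullisomic (dead) and the complementary pair disomic
(viable by default — yeast disomes germinate — and togglable). Sister
segregation at MII is assumed faithful. The computation enumerates the 16
alive-subsets of spores exactly (no Monte-Carlo error); a seeded
Monte-Carlo oracle in the test suite confirms it to within three standard
errors on every class probability. Because nondisjunction kills spores two
at a time, it enriches even viable-spore counts; `ndjBiasScore()`
quantifies that 4-2-0 signature as $(f_4+f_2+f_0)-(f_3+f_1)$.

# The synthetic-meiosis generator

`simulateTetrads()` works at chromatid level. Per meiosis and interval the
crossover count is Poisson with mean $d/50$: one obligatory crossover per
four-chromatid bundle gives 100% tetratypes, i.e. 50 cM, which fixes the
cM-to-mean mapping. Each crossover picks one of the four non-sister
chromatid pairs uniformly (no chromatid interference) and exchanges the
distal segments. By default there is also no crossover interference
(placements are independent); the analyses this package reproduces never
estimate interference, so the Poisson default keeps the generator honest
about what is and is not being modelled. Meiosis I segregates the two
centromere pairs with random orientation, and spore labels are shuffled
per tetrad since dissection order carries no meaning.

Two crossover pathway classes (interference-dependent Msh4-Msh5/Mlh1-Mlh3
and interference-independent Mus81-Mms4) share placement rules and differ
only in rate multipliers; the interference class carries 70% of reference
crossovers by default. Because no quantitative pathway partition is
established for these data, genotype presets do not rely on the split:
their per-interval true distances are taken directly from the Perkins
estimates recomputed from the packaged count tables.

Each chromosome also has a total genetic length (`chromosomeCM`): the
marked intervals cover only part of a chromosome, and crossovers outside
the marked span still count towards the obligate-crossover requirement
while remaining invisible to the markers. Presets set these lengths from
the genome-wide wild-type means (3, 8, 4 crossovers on III, VII, VIII)
scaled down by the genotype's cumulative-distance fold change.

Gene conversion is overlaid marker-locally: each marker × tetrad converts
with the preset's mean per-marker aberrant fraction, flipping one uniformly
chosen spore's allele (3:1 and 1:3 equally likely). Conversion tracts are
not modelled — marker-local events suffice to exercise the
aberrant-segregation tallies, but they cannot produce the correlated
multi-marker conversions real tracts would.

Spore death has two sources. Nondisjunction of achiasmate chromosomes is
resolved per the viability model above, with `pDisjoin` genotype-dependent:
0.5 for wild type and the *mlh3* deletion (whose observed viable-spore
profile shows the 4-2-0 nondisjunction signature) and 0.9 for the *mms4*
deletion and the double mutant (whose profiles lack that signature despite
far lower crossover levels, pointing to an efficient pairing-based backup
disjunction of achiasmate pairs). A per-spore background death probability
is then calibrated so the preset's expected viability matches the printed
percentage. Disomic spores of a nondisjoined chromosome survive but are
unscorable along that chromosome (they are heterozygous there), and dead
spores are masked entirely.

Fluctuation cultures grow by synchronous doubling from $N_0$ to $N_t$;
each generation every non-mutant cell divides and each division mutates
with probability $\mu$, so the zero-mutant fraction follows the classic
$P_0 = e^{-\mu(N_t - N_0)}$ law, which the test suite checks directly,
along with the heavy upper tail (jackpot cultures).

What the generator deliberately does **not** emulate: DSB-level mechanism,
synaptonemal-complex dynamics, hotspots, conversion tracts, chromatid or
crossover interference, mutant-fitness effects in cultures, and ambiguous
replica-plating phenotypes (allele calls are clean binary or missing).
Passing recovery tests therefore demonstrates estimator correctness under
these idealized conditions, not robustness to every artifact of real
dissection data.

# Numerical choices and validated ranges

* Root finding for the Drake equation brackets the root by doubling/halving
  and solves to relative tolerance $10^{-9}$; the test suite freezes roots
  computed by an independent bisection oracle (e.g. $\tilde r = 5 \to
  m = 2.3752$, $\tilde r = 0.5 \to m = 0.6355$).
* All 95% intervals use the 1.96 normal quantile; Perkins intervals floor
  at 0 cM, single-spore intervals clamp to [0, 100].
* Perkins recovery is validated at d ∈ {2, 10, 20, 35} cM with 2000 tetrads
  per point. The estimator is linear in class frequencies, so its bias
  under Poisson placement is exactly the bias of the class expectations:
  negligible below ~20 cM and about 2.8 cM downward at 35 cM — the edge of
  the validated range. Larger distances are outside it.
* Tetrad-level and spore-level tallies of the same data are checked to
  agree within joint sampling error.
* Degenerate inputs error loudly rather than return silent zeros: no scored
  tetrads, zero-median fluctuation counts (rate only bounded from above),
  constant regressors, zero reference rates, too few cultures for CI ranks
  (fewer than 8).
* Validation problem sizes (2000-tetrad recoveries, $10^5$-meiosis
  Monte-Carlo cross-checks, 500-assay estimator-bias sweeps, 1000-culture
  $P_0$ checks) keep the full suite under half a minute while leaving
  3-standard-error margins well above Monte-Carlo noise.

# Known limitations

Perkins estimates above ~35 cM attenuate without an interference model;
the fluctuation CI uses a normal rank approximation rather than exact
binomial tables (coverage-validated only); cumulative-distance standard
errors treat adjacent intervals as independent although they share
tetrads; and the preset calibration inherits any biases of the printed
estimates it consumes (notably viability-driven selection of scorable
tetrads, which is also present in the real data).
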