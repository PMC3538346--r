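Package: tetramap
Title: Tetrad Analysis, Linkage Mapping, and Crossover-Viability Modelling for Yeast Meiosis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the genetic analysis of budding-yeast meiosis from dissected
    tetrads: classification of tetrads into parental ditype, tetratype and
    nonparental ditype; genetic map distances by the Perkins formula (with
    multinomial delta-method standard errors) and by single-spore recombination
    frequency; cumulative distances and fold changes between genotypes; aberrant
    (3:1/1:3) marker segregation; spore-viability profiles and a meiosis-I
    nondisjunction bias score; Luria-Delbruck fluctuation-assay mutation rates by
    the Drake median method with nonparametric confidence intervals; an exact
    obligate-crossover spore-viability model for achiasmate chromosomes; and a
    chromatid-level meiosis simulator with two crossover pathway classes, gene
    conversion and nondisjunction-driven spore death.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
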