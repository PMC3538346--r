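test_that("zero distance gives parental ditypes only; configs validate", {
  cfg <- SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 0),
                          nTetrads = 200, seed = 3)
  tl <- tallyIntervals(simulateTetrads(cfg)$tetrads)
  expect_equal(tl$PD, 200L)
  expect_equal(tl$recombinant, 0L)
  expect_error(SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = -1),
                                nTetrads = 10, seed = 1), ">= 0")
  expect_error(SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 10),
                                nTetrads = 10), "seed")
})

test_that("identical config and seed reproduce the simulation exactly", {
  cfg <- SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 15),
                          nTetrads = 150, seed = 99)
  s1 <- simulateTetrads(cfg)
  s2 <- simulateTetrads(cfg)
  expect_identical(spores(s1$tetrads), spores(s2$tetrads))
  expect_identical(s1$manifest$realized_crossovers, s2$manifest$realized_crossovers)
})

test_that("saturating distances approach the 1:4:1 tetrad-type limit", {
  # m = 10 crossovers per bundle: classes equilibrate at PD:TT:NPD = 1:4:1
  cfg <- SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 500),
                          nTetrads = 1e4, seed = 12)
  tl <- tallyIntervals(simulateTetrads(cfg)$tetrads)
  n <- tl$tetrads_scored
  for (pair in list(c(tl$PD, 1 / 6), c(tl$TT, 2 / 3), c(tl$NPD, 1 / 6))) {
    se <- sqrt(pair[2] * (1 - pair[2]) / n)
    expect_lt(abs(pair[1] / n - pair[2]), 3 * se)
  }
})

test_that("Perkins estimates recover the configured distance", {
  cfg <- SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 20),
                          nTetrads = 2000, seed = 42)
  tl <- tallyIntervals(simulateTetrads(cfg)$tetrads)
  pe <- perkinsEstimate(tl$PD, tl$TT, tl$NPD)
  expect_lt(abs(pe$cM - 20), 2 * pe$se)
  # single-spore and tetrad estimates agree on the same data
  ss <- singleSporeEstimate(tl$parental, tl$recombinant)
  expect_lt(abs(ss$cM - pe$cM), 3 * sqrt(ss$se^2 + pe$se^2))
})

test_that("NPD frequency matches an independent chain oracle at m = 0.4", {
  cfg <- SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 20),
                          nTetrads = 4000, seed = 8)
  tl <- tallyIntervals(simulateTetrads(cfg)$tetrads)
  # oracle: the crossover count -> tetrad class Markov chain, 10x sample size
  P <- matrix(c(0, 1, 0, 1/4, 1/2, 1/4, 0, 1, 0), 3, 3, byrow = TRUE)
  set.seed(88)
  k <- stats::rpois(4e4, 0.4)
  state <- vapply(k, function(ki) {
    s <- 1L
    for (i in seq_len(ki)) s <- sample.int(3, 1, prob = P[s, ])
    s
  }, integer(1))
  fOracle <- mean(state == 3L)
  fSim <- tl$NPD / tl$tetrads_scored
  se <- sqrt(fOracle * (1 - fOracle) * (1 / 4000 + 1 / 4e4))
  expect_lt(abs(fSim - fOracle), 3 * se)
})

test_that("pathway scaling rescales effective distances", {
  cfg <- SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 30),
                          pathwayScaling = c(interference = 0, noninterference = 1),
                          interferenceShare = 0.7, nTetrads = 2000, seed = 21)
  tl <- tallyIntervals(simulateTetrads(cfg)$tetrads)
  pe <- perkinsEstimate(tl$PD, tl$TT, tl$NPD)
  expect_lt(abs(pe$cM - 9), 3 * pe$se)  # 30 cM x 0.3 residual share
})

test_that("gene conversion overlays at the configured rate", {
  cfg <- SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 10),
                          nTetrads = 2000, seed = 5)
  ts <- simulateTetrads(cfg)$tetrads
  set.seed(50)
  expect_identical(spores(applyGeneConversion(ts, 0)$tetrads), spores(ts))
  set.seed(51)
  all1 <- applyGeneConversion(ts, 1)$tetrads
  expect_equal(segregationTally(all1, "A")$percent_aberrant, 100)
  set.seed(52)
  conv <- applyGeneConversion(ts, 0.03)
  pct <- segregationTally(conv$tetrads, "A")$percent_aberrant
  se <- 100 * sqrt(0.03 * 0.97 / 2000)
  expect_lt(abs(pct - 3), 3 * se)
})

test_that("viability resolution kills spore pairs on nondisjunction", {
  cfg <- SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 40),
                          nTetrads = 300, seed = 61)
  sim <- simulateTetrads(cfg)
  set.seed(62)
  keep <- applyViability(sim$tetrads, DisjunctionModel(pDisjoin = 1), sim$manifest)
  expect_true(all(nViable(keep$tetrads) == 4L))
  expect_equal(keep$n_ndj, 0L)
  # forced nondisjunction: zero-distance chromosome is always achiasmate
  cfg0 <- SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 0),
                           nTetrads = 300, seed = 63)
  sim0 <- simulateTetrads(cfg0)
  set.seed(64)
  ndj <- applyViability(sim0$tetrads, DisjunctionModel(pDisjoin = 0), sim0$manifest)
  expect_true(all(nViable(ndj$tetrads) == 2L))
  expect_equal(ndj$n_ndj, 300L)
  # dead spores are fully masked
  sp <- spores(ndj$tetrads)
  expect_true(all(sp$A[!sp$viable] == "-"))
})

test_that("Luria-Delbruck cultures obey the P0 law and are heavy-tailed", {
  expect_equal(cultureCounts(simulateFluctuation(0, 100, 1e4, 5)), rep(0, 5))
  set.seed(29)
  mu <- 5e-8  # one expected mutation per culture at N_t = 2e7
  fe <- simulateFluctuation(mu, 1250, 2e7, 1000)
  p0 <- exp(-mu * (2e7 - 1250))
  se <- sqrt(p0 * (1 - p0) / 1000)
  expect_lt(abs(mean(cultureCounts(fe) == 0) - p0), 3 * se)
  # jackpots drag the mean above the median
  set.seed(30)
  big <- simulateFluctuation(1e-7, 1250, 2e7, 500)
  expect_gt(mean(cultureCounts(big)), stats::median(cultureCounts(big)))
  expect_error(simulateFluctuation(0.5, 100, 10, 5), "nFinal")
})

test_that("genotype presets order viability and fold changes as observed", {
  set.seed(0)
  study <- withr::local_tempdir()
  res <- generateStudy(study, presets = c("wild type", "mlh3d mms4d"),
                       nTetrads = 2000, seed = 17)
  map <- readMarkerMap(file.path(study, "marker_map.tsv"))
  wt <- readTetradTable(res[["wild type"]]$tetrads, map)
  db <- readTetradTable(res[["mlh3d mms4d"]]$tetrads, map)
  expect_gt(percentViable(viabilityProfile(wt)),
            percentViable(viabilityProfile(db)))
  twt <- tallyIntervals(wt); tdb <- tallyIntervals(db)
  for (chr in c("III", "VII", "VIII")) {
    cwt <- sum(perkinsCM(twt$PD, twt$TT, twt$NPD)[twt$chromosome == chr])
    cdb <- sum(perkinsCM(tdb$PD, tdb$TT, tdb$NPD)[tdb$chromosome == chr])
    expect_gt(foldDecrease(cwt, cdb), 5)
    expect_lt(foldDecrease(cwt, cdb), 20)
  }
  # manifests reflect what was written
  expect_equal(res[["wild type"]]$manifest$observed_tallies, twt)
  # determinism: byte-identical on re-run
  study2 <- withr::local_tempdir()
  generateStudy(study2, presets = c("wild type", "mlh3d mms4d"),
                nTetrads = 2000, seed = 17)
  for (f in list.files(study, pattern = "tsv$"))
    expect_identical(readLines(file.path(study, f)),
                     readLines(file.path(study2, f)))
  expect_error(presetConfig("nonesuch", seed = 1), "unknown preset")
})
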