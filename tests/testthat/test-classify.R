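test_that("ditype and tetratype definitions classify correctly", {
  ts <- makeTetradSet(list(pdTetrad(), npdTetrad(), ttTetrad()))
  cls <- classifyInterval(ts, c("A", "B"))
  expect_equal(as.character(cls), c("PD", "NPD", "TT"))
  # 3:1 at marker A -> unscorable; missing call -> unscorable
  conv <- cbind(c("P", "P", "P", "M"), c("P", "P", "M", "M"))
  miss <- cbind(c("P", "P", "M", "M"), c("P", "-", "M", "M"))
  cls2 <- classifyInterval(makeTetradSet(list(conv, miss)), c("A", "B"))
  expect_equal(as.character(cls2), c("UNSCORABLE", "UNSCORABLE"))
  expect_error(classifyInterval(ts, c("A", "Q")), "absent")
})

test_that("classifier agrees with the exhaustive-case oracle on every two-marker genotype", {
  codes <- c("P", "M", "-")
  grid <- expand.grid(a1 = codes, a2 = codes, a3 = codes, a4 = codes,
                      b1 = codes, b2 = codes, b3 = codes, b4 = codes,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  a <- as.matrix(grid[, 1:4]); b <- as.matrix(grid[, 5:8])
  df <- data.frame(tetrad_id = rep(sprintf("g%04d", seq_len(n)), each = 4),
                   spore = rep(1:4, n), viable = TRUE,
                   A = as.vector(t(a)), B = as.vector(t(b)),
                   stringsAsFactors = FALSE)
  got <- as.character(classifyInterval(TetradSet(df, twoMarkerMap()), c("A", "B")))
  want <- vapply(seq_len(n), function(i) oracleClassify(a[i, ], b[i, ]), character(1))
  expect_equal(got, want)
})

test_that("interval tallies split tetrad and single-spore counts correctly", {
  ts <- makeTetradSet(list(pdTetrad(), ttTetrad()))
  tl <- tallyIntervals(ts)
  expect_equal(tl$PD, 1L)
  expect_equal(tl$TT, 1L)
  expect_equal(tl$NPD, 0L)
  expect_equal(tl$parental, 6L)     # 4 from the PD + 2 from the TT
  expect_equal(tl$recombinant, 2L)
  expect_equal(tl$spores_total, 8L)
  # empty input -> zero counts
  empty <- TetradSet(spores(ts)[0, ], twoMarkerMap())
  tl0 <- tallyIntervals(empty)
  expect_equal(tl0$PD + tl0$TT + tl0$NPD + tl0$spores_total, 0L)
})

test_that("spores of tetrad-unscorable or incomplete tetrads still feed single-spore tallies", {
  # 3:1 conversion at A: unscorable as a tetrad, but every spore has clean
  # calls at both markers and counts in the spore tally
  conv <- cbind(c("P", "P", "P", "M"), c("P", "P", "M", "M"))
  # a 3-viable tetrad: dead spore contributes nothing
  df <- data.frame(tetrad_id = "x", spore = 1:4,
                   viable = c(TRUE, TRUE, TRUE, FALSE),
                   A = c("P", "P", "M", "-"), B = c("P", "M", "M", "-"),
                   stringsAsFactors = FALSE)
  ts <- TetradSet(rbind(spores(makeTetradSet(list(conv))), df), twoMarkerMap())
  tl <- tallyIntervals(ts)
  expect_equal(tl$tetrads_scored, 0L)
  expect_equal(tl$spores_total, 7L)
  expect_equal(tl$recombinant, 2L)  # spore 3 of conv (PM) + spore 2 of x (PM)
})

test_that("segregation tally counts 3:1 and 1:3 tetrads among four-spore-viable ones", {
  t31 <- cbind(c("P", "P", "P", "M"), c("P", "P", "M", "M"))
  t13 <- cbind(c("P", "M", "M", "M"), c("P", "P", "M", "M"))
  ts <- makeTetradSet(list(pdTetrad(), t31, t13, ttTetrad()))
  st <- segregationTally(ts, "A")
  expect_equal(st$aberrant_3_1, 1L)
  expect_equal(st$aberrant_1_3, 1L)
  expect_equal(st$normal_2_2, 2L)
  expect_equal(st$percent_aberrant, 100 * 2 / 4)
  stB <- segregationTally(ts, "B")
  expect_equal(stB$percent_aberrant, 0)
  expect_error(segregationTally(ts, "Q"), "absent")
})

test_that("viability profile and nondisjunction bias score", {
  p <- viabilityProfile(c(4, 4, 2, 0))
  expect_equal(unname(profileCounts(p)), c(1, 0, 1, 0, 2))
  expect_equal(percentViable(p), 62.5)
  expect_equal(ndjBiasScore(p), 1)
  expect_equal(percentViable(viabilityProfile(c(4, 4, 4))), 100)
  expect_equal(ndjBiasScore(viabilityProfile(0:4)), 3 / 5 - 2 / 5)
})
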