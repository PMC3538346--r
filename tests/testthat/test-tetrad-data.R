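test_that("MarkerMap enforces ordering and exposes intervals", {
  map <- MarkerMap("III", c("HIS4", "LEU2", "CEN3", "MAT"), c(0, 23, 45, 135))
  expect_equal(markerNames(map), c("HIS4", "LEU2", "CEN3", "MAT"))
  iv <- mapIntervals(map)
  expect_equal(iv$interval, c("HIS4-LEU2", "LEU2-CEN3", "CEN3-MAT"))
  expect_equal(iv$length_kb, c(23, 22, 90))
  expect_error(MarkerMap("III", c("A", "B"), c(5, 5)), "increasing")
  expect_error(MarkerMap("III", "A", 0), "fewer than 2")
  expect_error(validObject(MarkerMap(c("I", "II"), c("A", "A", "B", "B"),
                                     c(0, 10, 0, 10))), "unique")
})

test_that("marker map files round-trip", {
  map <- loadFixture("map_nhy")
  p <- withr::local_tempfile(fileext = ".tsv")
  writeMarkerMap(map, p)
  expect_equal(readMarkerMap(p)@table, map@table)
})

test_that("tetrad tables round-trip through write and read", {
  ts <- makeTetradSet(list(pdTetrad(), ttTetrad()))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeTetradTable(ts, p)
  back <- readTetradTable(p, twoMarkerMap())
  expect_equal(spores(back), spores(ts))
  expect_equal(unname(nViable(back)), c(4L, 4L))
  # one tetrad -> header + 4 data rows; empty set -> header only
  writeTetradTable(makeTetradSet(list(pdTetrad())), p)
  expect_length(readLines(p), 5L)
  writeTetradTable(TetradSet(spores(ts)[0, ], twoMarkerMap()), p)
  expect_length(readLines(p), 1L)
})

test_that("large simulated sets round-trip to identical tallies", {
  cfg <- SimulationConfig(twoMarkerMap(), intervalCM = c("A-B" = 25),
                          nTetrads = 1068, seed = 9)
  ts <- simulateTetrads(cfg)$tetrads
  p <- withr::local_tempfile(fileext = ".tsv")
  writeTetradTable(ts, p)
  expect_equal(tallyIntervals(readTetradTable(p, twoMarkerMap())),
               tallyIntervals(ts))
})

test_that("reader rejects malformed input", {
  map <- twoMarkerMap()
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tetrad_id\tspore\tviable\tA\tB",
               "t1\t1\t1\tP\tP", "t1\t2\t1\tP\tX",
               "t1\t3\t1\tM\tM", "t1\t4\t1\tM\tM"), p)
  expect_error(readTetradTable(p, map), "invalid allele code 'X'")
  writeLines(c("tetrad_id\tspore\tviable\tA\tC", "t1\t1\t1\tP\tP"), p)
  expect_error(readTetradTable(p, map), "not in map: C")
  writeLines(c("tetrad_id\tspore\tviable\tA\tB",
               "t1\t1\t1\tP\tP", "t1\t2\t1\tM\tM"), p)
  expect_error(readTetradTable(p, map), "exactly 4 spores")
  writeLines(c("tetrad_id\tspore\tviable\tA\tB", "t1\t5\t1\tP\tP"), p)
  expect_error(readTetradTable(p, map), "malformed spore/viable")
})

test_that("dead spores must be fully unscored", {
  bad <- data.frame(tetrad_id = "t1", spore = 1:4,
                    viable = c(TRUE, TRUE, TRUE, FALSE),
                    A = c("P", "P", "M", "M"), B = c("P", "P", "M", "M"),
                    stringsAsFactors = FALSE)
  expect_error(TetradSet(bad, twoMarkerMap()), "unscored")
  bad$A[4] <- "-"; bad$B[4] <- "-"
  ts <- TetradSet(bad, twoMarkerMap())
  expect_equal(unname(nViable(ts)), 3L)
})

test_that("packaged fixtures hold the printed values and are consistent", {
  t5 <- loadFixture("table5")
  expect_equal(nrow(t5), 48L)
  wt <- subset(t5, genotype == "wild type" & interval == "URA3-LEU2")
  expect_equal(wt$PD, 607)
  expect_equal(wt$TT, 456)
  expect_equal(wt$NPD, 5)
  t3 <- loadFixture("table3")
  expect_equal(t3$median_rate_e7[t3$genotype == "mlh3d"], 26.5)
  t6 <- loadFixture("table6")
  expect_equal(t6$cumulative_cM[t6$genotype == "mlh3d mms4d" &
                                  t6$chromosome == "VIII"], 2.8)
  t7 <- loadFixture("table7")
  expect_equal(nrow(t7), 32L)
  # load-time integrity: parental + recombinant = n for every row
  both <- intervalCountTables()
  expect_true(all(both$parental + both$recombinant == both$spores_total))
  expect_true(all(both$PD + both$TT + both$NPD <= both$tetrads))
  expect_error(loadFixture("table99"), "unknown fixture")
})
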