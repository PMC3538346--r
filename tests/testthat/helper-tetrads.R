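# Builders for small in-code fixtures.

twoMarkerMap <- function() MarkerMap("Z", c("A", "B"), c(0, 50))

# tetrads: list of 4x2 character matrices (rows = spores, cols = markers A, B)
makeTetradSet <- function(tetrads, map = twoMarkerMap(),
                          viable = rep(TRUE, 4)) {
  df <- do.call(rbind, lapply(seq_along(tetrads), function(i) {
    m <- tetrads[[i]]
    data.frame(tetrad_id = sprintf("t%03d", i), spore = 1:4,
               viable = viable, A = m[, 1], B = m[, 2],
               stringsAsFactors = FALSE)
  }))
  TetradSet(df, map)
}

pdTetrad <- function() cbind(c("P", "P", "M", "M"), c("P", "P", "M", "M"))
npdTetrad <- function() cbind(c("P", "P", "M", "M"), c("M", "M", "P", "P"))
ttTetrad <- function() cbind(c("P", "P", "M", "M"), c("P", "M", "P", "M"))

# Independent exhaustive-case classification oracle, written directly from
# the definition (multiset comparison), not sharing code with the package.
oracleClassify <- function(a, b) {
  a <- unname(a); b <- unname(b)
  if (any(c(a, b) == "-")) return("UNSCORABLE")
  if (!identical(sort(a), c("M", "M", "P", "P"))) return("UNSCORABLE")
  if (!identical(sort(b), c("M", "M", "P", "P"))) return("UNSCORABLE")
  ps <- sort(paste0(a, b))
  if (identical(ps, c("MM", "MM", "PP", "PP"))) return("PD")
  if (identical(ps, c("MP", "MP", "PM", "PM"))) return("NPD")
  if (identical(ps, c("MM", "MP", "PM", "PP"))) return("TT")
  "UNSCORABLE"
}

# Monte-Carlo oracle for the nondisjunction viability model: simulates
# meioses directly instead of enumerating states.
mcViability <- function(e0, pDisjoin, disomicViable = TRUE,
                        backgroundDeath = 0, nSim = 1e5) {
  alive <- matrix(TRUE, nSim, 4)
  pairs <- utils::combn(4, 2, simplify = FALSE)
  for (p0 in e0) {
    ndj <- stats::runif(nSim) < p0 * (1 - pDisjoin)
    pick <- sample.int(6, nSim, replace = TRUE)
    for (i in which(ndj)) {
      nulli <- pairs[[pick[i]]]
      alive[i, nulli] <- FALSE
      if (!disomicViable) alive[i, setdiff(1:4, nulli)] <- FALSE
    }
  }
  if (backgroundDeath > 0)
    alive <- alive & matrix(stats::runif(nSim * 4) >= backgroundDeath, nSim, 4)
  tabulate(rowSums(alive) + 1L, 5L) / nSim  # classes 0..4
}
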