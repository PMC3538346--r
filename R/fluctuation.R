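#' Construct a FluctuationExperiment
#'
#' @param cultureCounts integer mutant-colony counts per parallel culture.
#' @param cellsAtRisk cells per culture at plating (N_t); default 2e7.
#' @return a [FluctuationExperiment-class]
#' @export
FluctuationExperiment <- function(cultureCounts, cellsAtRisk = 2e7) {
  new("FluctuationExperiment", cultureCounts = as.numeric(cultureCounts),
      cellsAtRisk = as.numeric(cellsAtRisk))
}

#' @rdname FluctuationExperiment
#' @export
setMethod("cultureCounts", "FluctuationExperiment", function(x) x@cultureCounts)

#' @rdname FluctuationExperiment
#' @export
setMethod("cellsAtRisk", "FluctuationExperiment", function(x) x@cellsAtRisk)

setMethod("show", "FluctuationExperiment", function(object) {
  cat(sprintf("FluctuationExperiment: %d cultures, median count %g, N_t = %g\n",
              length(object@cultureCounts), stats::median(object@cultureCounts),
              object@cellsAtRisk))
})

#' Median mutant count
#'
#' Middle order statistic; mean of the two central values for even n.
#' @param r numeric vector of counts.
#' @export
medianCount <- function(r) {
  if (!length(r)) stop("empty count vector")
  stats::median(r)
}

#' Solve the Drake median equation for expected mutations per culture
#'
#' Finds the unique m > 0 with r/m - ln(m) = 1.24, the median-based
#' estimator of the expected number of mutations per culture under the
#' Luria-Delbruck distribution. The left side is strictly decreasing in m,
#' so bisection-style root finding converges to a unique root; tolerance is
#' relative 1e-9.
#'
#' @param r_median median mutant count; must be > 0.
#' @return m, expected mutations per culture.
#' @examples
#' drakeM(1.24)  # exactly 1
#' @export
drakeM <- function(r_median) {
  if (r_median <= 0)
    stop("median count must be > 0: rate only bounded from above")
  g <- function(m) r_median / m - log(m) - 1.24
  lo <- r_median / 1e6; hi <- max(2, r_median)
  while (g(hi) > 0) hi <- hi * 2
  while (g(lo) < 0) lo <- lo / 2
  stats::uniroot(g, c(lo, hi), tol = 1e-9 * max(1, r_median))$root
}

#' Nonparametric 95% CI ranks for the median
#'
#' Normal approximation to the binomial(n, 1/2) order statistics:
#' l = floor((n - 1.96 sqrt(n))/2), u = ceil((n + 1.96 sqrt(n))/2).
#'
#' @param n number of cultures.
#' @return integer vector c(lower, upper) of 1-based ranks.
#' @export
medianCIRanks <- function(n) {
  l <- floor((n - 1.96 * sqrt(n)) / 2)
  u <- ceiling((n + 1.96 * sqrt(n)) / 2)
  if (l < 1 || u > n)
    stop("too few cultures for a nonparametric median CI (n = ", n, ")")
  c(lower = as.integer(l), upper = as.integer(u))
}

#' Nonparametric 95% CI for the mutation rate
#'
#' Order-statistic CI for the median mutant count, each bound transformed
#' through the Drake equation and divided by the cells at risk. A zero
#' lower-bound count yields a 0 lower rate bound.
#'
#' @param experiment a [FluctuationExperiment-class]
#' @return numeric c(low, high) mutations/cell/generation.
#' @export
rateCI <- function(experiment) {
  r <- sort(cultureCounts(experiment))
  rk <- medianCIRanks(length(r))
  nt <- cellsAtRisk(experiment)
  lo <- if (r[rk[["lower"]]] > 0) drakeM(r[rk[["lower"]]]) / nt else 0
  hi <- drakeM(r[rk[["upper"]]]) / nt
  c(low = lo, high = hi)
}

#' Median-method mutation rate with 95% CI
#'
#' rate = drakeM(median count) / N_t, with the nonparametric order-statistic
#' interval of [rateCI()].
#'
#' @param experiment a [FluctuationExperiment-class]
#' @param reference optional reference rate; if given, `relative` =
#'   rate/reference is included.
#' @return data.frame: `n`, `median_count`, `m`, `rate`, `ci_low`,
#'   `ci_high`, and optionally `relative`.
#' @export
mutationRate <- function(experiment, reference = NULL) {
  r <- cultureCounts(experiment)
  med <- medianCount(r)
  if (med <= 0)
    stop("median mutant count is 0: rate not estimable by the median method")
  m <- drakeM(med)
  rate <- m / cellsAtRisk(experiment)
  ci <- tryCatch(rateCI(experiment), error = function(e) c(low = NA_real_, high = NA_real_))
  out <- data.frame(n = length(r), median_count = med, m = m, rate = rate,
                    ci_low = ci[["low"]], ci_high = ci[["high"]])
  if (!is.null(reference)) out$relative <- relativeRate(rate, reference, digits = Inf)
  out
}

#' Mutation rate relative to a reference strain
#'
#' Reported to 1 decimal below 10 and as a whole-number style above
#' (3 significant digits), matching the published table conventions.
#'
#' @param test,reference mutation rates; reference must be > 0.
#' @param digits rounding of ratios < 10; `Inf` for full precision.
#' @export
relativeRate <- function(test, reference, digits = 1) {
  if (any(reference <= 0)) stop("reference rate must be positive")
  r <- test / reference
  if (!is.finite(digits)) return(r)
  ifelse(r < 10, round(r, digits), signif(r, 3))
}

#' Read a fluctuation-assay TSV
#'
#' Dialect: `strain  culture  mutant_colonies  cells_plated`; `#` comments.
#' @param path file path
#' @return named list of [FluctuationExperiment-class], one per strain.
#' @export
readFluctuationTable <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("strain", "culture", "mutant_colonies", "cells_plated")
  if (!all(need %in% names(tb)))
    stop("fluctuation table must have columns: ", paste(need, collapse = ", "))
  lapply(split(tb, factor(tb$strain, unique(tb$strain))), function(d) {
    nt <- unique(d$cells_plated)
    if (length(nt) != 1)
      stop("cells_plated must be constant within strain ", d$strain[1])
    FluctuationExperiment(d$mutant_colonies, nt)
  })
}
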