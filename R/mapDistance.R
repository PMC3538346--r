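#' Perkins map distance from tetrad counts
#'
#' cM = 100 (TT/2 + 3 NPD) / (PD + TT + NPD). The denominator is the number
#' of tetrads scorable for the interval (unscorable tetrads -- gene
#' conversion at a flanking marker, missing calls -- are excluded). The NPD
#' term corrects for four-strand double crossovers.
#'
#' @param PD,TT,NPD tetrad counts (vectorized).
#' @return map distance in cM.
#' @examples
#' perkinsCM(607, 456, 5)  # 22.75
#' @export
perkinsCM <- function(PD, TT, NPD) {
  n <- PD + TT + NPD
  if (any(n <= 0)) stop("no scored tetrads: Perkins estimate undefined")
  100 * (TT / 2 + 3 * NPD) / n
}

#' Perkins estimate with delta-method standard error and 95% CI
#'
#' Treats (PD, TT, NPD) as multinomial and propagates to the Perkins
#' statistic: with f_T = TT/n, f_N = NPD/n,
#' se = 100 sqrt((f_T(1-f_T)/4 + 9 f_N(1-f_N) - 3 f_T f_N)/n).
#' The 95% interval is cM +/- 1.96 se, floored at 0.
#'
#' @inheritParams perkinsCM
#' @return data.frame: `cM`, `se`, `ci_low`, `ci_high`, `n`, `method`.
#' @export
perkinsEstimate <- function(PD, TT, NPD) {
  n <- PD + TT + NPD
  cm <- perkinsCM(PD, TT, NPD)
  fT <- TT / n; fN <- NPD / n
  v <- (fT * (1 - fT) / 4 + 9 * fN * (1 - fN) - 3 * fT * fN) / n
  se <- 100 * sqrt(pmax(0, v))
  data.frame(cM = cm, se = se,
             ci_low = pmax(0, cm - 1.96 * se), ci_high = cm + 1.96 * se,
             n = n, method = "perkins_tetrad", stringsAsFactors = FALSE)
}

#' Single-spore map distance (recombination frequency)
#'
#' 100 x recombinant / (parental + recombinant).
#'
#' @param parental,recombinant spore counts (vectorized).
#' @return map distance in cM.
#' @examples
#' singleSporeCM(3635, 1009)  # 21.7
#' @export
singleSporeCM <- function(parental, recombinant) {
  n <- parental + recombinant
  if (any(n <= 0)) stop("no scored spores: estimate undefined")
  100 * recombinant / n
}

#' @rdname singleSporeCM
#' @return `singleSporeEstimate` adds a binomial delta-method se and 95% CI.
#' @export
singleSporeEstimate <- function(parental, recombinant) {
  n <- parental + recombinant
  cm <- singleSporeCM(parental, recombinant)
  p <- recombinant / n
  se <- 100 * sqrt(p * (1 - p) / n)
  data.frame(cM = cm, se = se,
             ci_low = pmax(0, cm - 1.96 * se),
             ci_high = pmin(100, cm + 1.96 * se),
             n = n, method = "single_spore", stringsAsFactors = FALSE)
}

#' Cumulative map distance over consecutive intervals
#'
#' Point estimates add; standard errors combine in quadrature (interval
#' tallies from the same tetrads are treated as independent, adequate for
#' the well-spaced intervals used here).
#'
#' @param cM numeric interval estimates (all from one method).
#' @param se optional numeric standard errors.
#' @return list with `cM` and (if `se` given) `se`, `ci_low`, `ci_high`.
#' @export
cumulativeDistance <- function(cM, se = NULL) {
  if (!length(cM)) stop("no interval estimates to accumulate")
  out <- list(cM = sum(cM))
  if (!is.null(se)) {
    out$se <- sqrt(sum(se^2))
    out$ci_low <- max(0, out$cM - 1.96 * out$se)
    out$ci_high <- out$cM + 1.96 * out$se
  }
  out
}

#' Fold decrease in crossing over
#'
#' @param reference reference (e.g. wild-type) map distance.
#' @param test reduced map distance; must be positive.
#' @param digits rounding for report output (1, as in the tables); use
#'   `Inf` for full precision.
#' @return reference / test.
#' @export
foldDecrease <- function(reference, test, digits = 1) {
  if (any(test <= 0)) stop("fold decrease undefined for non-positive test distance")
  r <- reference / test
  if (is.finite(digits)) round(r, digits) else r
}

#' Pearson chi-square test on a 2 x k count table
#'
#' No continuity correction; df = k - 1.
#'
#' @param table numeric matrix with 2 rows and k >= 2 columns.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chiSquare2xk <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2 || ncol(table) < 2)
    stop("need a 2 x k table with k >= 2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero marginal")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Viability-versus-map-distance regression
#'
#' Ordinary least squares of spore viability (%) on cumulative map distance
#' (cM) across strains; the R^2 is the squared sample correlation.
#'
#' @param cM,viability paired numeric vectors (>= 3 points, non-constant cM).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
fitViabilityVsDistance <- function(cM, viability) {
  stopifnot(length(cM) == length(viability))
  if (length(cM) < 2) stop("need at least 2 points")
  if (stats::var(cM) == 0) stop("degenerate fit: map distance is constant")
  if (stats::var(viability) == 0) stop("degenerate fit: viability is constant")
  fit <- stats::lm(viability ~ cM)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}
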