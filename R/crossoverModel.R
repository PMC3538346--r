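#' Construct a DisjunctionModel
#'
#' @param pDisjoin probability an achiasmate homolog pair disjoins correctly
#'   at meiosis I (default 0.5: a coin flip between the two MI outcomes).
#' @param disomicViable do disomic spores germinate? Yeast disomes usually
#'   do; default TRUE.
#' @param backgroundDeath per-spore death probability independent of
#'   nondisjunction; default 0.
#' @return a [DisjunctionModel-class]
#' @export
DisjunctionModel <- function(pDisjoin = 0.5, disomicViable = TRUE,
                             backgroundDeath = 0) {
  new("DisjunctionModel", pDisjoin = pDisjoin,
      disomicViable = isTRUE(disomicViable), backgroundDeath = backgroundDeath)
}

setMethod("show", "DisjunctionModel", function(object) {
  cat(sprintf(
    "DisjunctionModel: pDisjoin = %g, disomicViable = %s, backgroundDeath = %g\n",
    object@pDisjoin, object@disomicViable, object@backgroundDeath))
})

#' Expected crossovers per chromosome after a fold reduction
#'
#' wild-type mean / fold reduction, assuming crossover loss is uniform along
#' the chromosome.
#'
#' @param wtMean wild-type mean crossovers per meiosis for the chromosome.
#' @param fold fold reduction in crossing over (>= 1 in practice; must be > 0).
#' @return expected crossovers per meiosis (vectorized).
#' @examples
#' expectedCrossovers(8, 7.2)  # ~1.11, chromosome VII under the double mutant
#' @export
expectedCrossovers <- function(wtMean, fold) {
  stopifnot(all(wtMean > 0))
  if (any(fold <= 0)) stop("fold reduction must be positive")
  wtMean / fold
}

#' Probability a chromosome receives no crossover (E0)
#'
#' Under a Poisson model for per-meiosis crossover counts,
#' P(zero crossovers) = exp(-mean). Poisson is the minimal completion of a
#' means-only argument; interference would lower this probability slightly
#' at a given mean.
#'
#' @param mean expected crossovers per meiosis (>= 0, vectorized).
#' @return probability of an achiasmate (E0) meiosis for that chromosome.
#' @export
probAchiasmate <- function(mean) {
  if (any(mean < 0)) stop("mean crossover count must be >= 0")
  exp(-mean)
}

#' Exact tetrad viability distribution under MI nondisjunction
#'
#' Each chromosome independently is chiasmate (probability 1 - e0),
#' achiasmate but correctly disjoined (e0 * pDisjoin), or achiasmate and
#' nondisjoined (e0 * (1 - pDisjoin)). An MI nondisjunction sends both
#' homologs to one pole: a uniformly chosen disjoint spore pair becomes
#' nullisomic (dead) and the complementary pair disomic (dead unless
#' `disomicViable`). Background death then applies independently per
#' surviving spore. The distribution over 0-4 viable spores is computed by
#' exact enumeration over the 16 alive-subsets of spores.
#'
#' @param e0 numeric vector of per-chromosome achiasmate probabilities.
#' @param model a [DisjunctionModel-class]
#' @return a [ViabilityProfile-class] whose counts are class probabilities
#'   (nTetrads = 1).
#' @examples
#' viabilityDistribution(1, DisjunctionModel(pDisjoin = 0))  # all tetrads 2-viable
#' @export
viabilityDistribution <- function(e0, model = DisjunctionModel()) {
  if (any(e0 < 0 | e0 > 1)) stop("e0 probabilities must lie in [0,1]")
  # nullisomic pair: uniform over the 3 disjoint-pair partitions and, within
  # a partition, over which pole received zero copies => 6 equally likely pairs
  pairs <- utils::combn(4, 2, simplify = FALSE)
  subsets <- lapply(0:15, function(m) which(bitwAnd(m, 2^(0:3)) > 0))
  # state: probability over alive-subsets, indexed 1..16 by bitmask + 1
  p <- numeric(16); p[16] <- 1
  pNDJ <- (1 - model@pDisjoin)
  for (ch in seq_along(e0)) {
    pOK <- 1 - e0[ch] * pNDJ
    q <- p * pOK
    for (j in seq_along(pairs)) {
      nulli <- pairs[[j]]
      disomic <- setdiff(1:4, nulli)
      for (m in 0:15) {
        if (p[m + 1] == 0) next
        alive <- subsets[[m + 1]]
        kill <- if (model@disomicViable) nulli else c(nulli, disomic)
        new <- setdiff(alive, kill)
        nm <- sum(2^(new - 1))
        q[nm + 1] <- q[nm + 1] + p[m + 1] * e0[ch] * pNDJ / 6
      }
    }
    p <- q
  }
  # collapse to #alive, then apply background death
  nAlive <- vapply(subsets, length, integer(1))
  pk <- vapply(0:4, function(k) sum(p[nAlive == k]), numeric(1))
  bd <- model@backgroundDeath
  if (bd > 0) {
    out <- numeric(5)
    for (k in 0:4) {
      if (pk[k + 1] == 0) next
      for (j in 0:k)
        out[j + 1] <- out[j + 1] +
          pk[k + 1] * stats::dbinom(j, k, 1 - bd)
    }
    pk <- out
  }
  names(pk) <- as.character(0:4)
  new("ViabilityProfile", counts = pk, nTetrads = 1)
}

#' Screen chromosomes for expected residual crossovers
#'
#' Applies [expectedCrossovers()] and [probAchiasmate()] across chromosomes,
#' flagging those still expected to receive at least one crossover after the
#' fold reduction.
#'
#' @param wtMeans named numeric: wild-type mean crossovers per chromosome.
#' @param folds named numeric: fold reduction per chromosome (same names).
#' @return data.frame: `chromosome`, `wt_mean`, `fold`, `expected`, `e0`,
#'   `at_least_one` (expected >= 1).
#' @export
crossoverScreen <- function(wtMeans, folds) {
  stopifnot(setequal(names(wtMeans), names(folds)))
  chr <- names(wtMeans)
  ex <- expectedCrossovers(wtMeans[chr], folds[chr])
  data.frame(chromosome = chr, wt_mean = unname(wtMeans[chr]),
             fold = unname(folds[chr]), expected = unname(ex),
             e0 = unname(probAchiasmate(ex)),
             at_least_one = unname(ex >= 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
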