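#' @import methods
NULL

# Allele codes used throughout: "P" (EAY1108-type parent), "M" (EAY1112-type
# parent), "-" (unscored, including every cell of a dead spore).
.ALLELES <- c("P", "M", "-")

#' MarkerMap: ordered genetic markers with physical positions
#'
#' Holds one or more chromosomes' worth of scored markers, each with a
#' physical position in kb. Adjacent markers on the same chromosome define
#' the genetic intervals over which map distances are estimated.
#'
#' @slot table data.frame with columns `chromosome`, `marker`, `position_kb`,
#'   ordered by chromosome then position.
#' @export
setClass("MarkerMap", representation(table = "data.frame"))

setValidity("MarkerMap", function(object) {
  tb <- object@table
  need <- c("chromosome", "marker", "position_kb")
  if (!all(need %in% names(tb)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$marker))
    return("marker names must be unique across the map")
  msgs <- character(0)
  for (chr in unique(tb$chromosome)) {
    pos <- tb$position_kb[tb$chromosome == chr]
    if (length(pos) < 2)
      msgs <- c(msgs, sprintf("chromosome %s has fewer than 2 markers", chr))
    else if (any(diff(pos) <= 0))
      msgs <- c(msgs, sprintf("positions not strictly increasing on %s", chr))
  }
  if (length(msgs)) msgs else TRUE
})

#' TetradSet: spore genotypes of dissected tetrads
#'
#' One row per spore (four per tetrad) with a viability flag and one allele
#' column per scored marker. Allele codes are `P`/`M` relative to the two
#' parental haploids, `-` for unscored; dead spores carry `-` everywhere.
#'
#' @slot spores data.frame with columns `tetrad_id`, `spore` (1-4),
#'   `viable` (logical) followed by one character column per marker.
#' @slot map the [MarkerMap-class] the genotypes were scored against.
#' @export
setClass("TetradSet", representation(spores = "data.frame", map = "MarkerMap"))

setValidity("TetradSet", function(object) {
  sp <- object@spores
  need <- c("tetrad_id", "spore", "viable")
  if (!all(need %in% names(sp)))
    return("spores must have columns tetrad_id, spore, viable")
  mk <- setdiff(names(sp), need)
  unknown <- setdiff(mk, markerNames(object@map))
  if (length(unknown))
    return(sprintf("markers not in map: %s", paste(unknown, collapse = ", ")))
  if (nrow(sp) == 0) return(TRUE)
  bad <- vapply(split(sp$spore, sp$tetrad_id),
                function(ix) length(ix) != 4L || !setequal(ix, 1:4),
                logical(1))
  if (any(bad))
    return(sprintf("tetrads without spores 1-4 exactly once: %s",
                   paste(names(bad)[bad], collapse = ", ")))
  al <- as.matrix(sp[mk])
  if (!all(al %in% .ALLELES))
    return("allele codes must be P, M or -")
  dead <- !sp$viable
  if (any(dead) && !all(al[dead, , drop = FALSE] == "-"))
    return("dead spores must be unscored ('-') at every marker")
  TRUE
})

#' ViabilityProfile: distribution of viable spores per tetrad
#'
#' The per-tetrad viable-spore distribution of Fig-4 style plots. `counts`
#' may hold tetrad counts (from data) or class probabilities (from the
#' obligate-crossover model); both support [percentViable()] and
#' [ndjBiasScore()].
#'
#' @slot counts numeric length 5, named "0".."4": weight of tetrads with
#'   that many viable spores.
#' @slot nTetrads numeric; total tetrads (1 for a probability profile).
#' @export
setClass("ViabilityProfile",
         representation(counts = "numeric", nTetrads = "numeric"))

setValidity("ViabilityProfile", function(object) {
  if (length(object@counts) != 5L ||
      !identical(names(object@counts), as.character(0:4)))
    return("counts must be length 5 named '0'..'4'")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (abs(sum(object@counts) - object@nTetrads) > 1e-8 * max(1, object@nTetrads))
    return("counts must sum to nTetrads")
  TRUE
})

#' FluctuationExperiment: one Luria-Delbruck fluctuation assay
#'
#' @slot cultureCounts integer mutant-colony counts, one per parallel culture
#'   (dilution-corrected).
#' @slot cellsAtRisk numeric; cells per culture at plating (N_t).
#' @export
setClass("FluctuationExperiment",
         representation(cultureCounts = "numeric", cellsAtRisk = "numeric"))

setValidity("FluctuationExperiment", function(object) {
  r <- object@cultureCounts
  if (length(r) < 2) return("need at least 2 cultures")
  if (any(r < 0) || any(r != round(r))) return("counts must be non-negative integers")
  if (length(object@cellsAtRisk) != 1 || object@cellsAtRisk <= 0)
    return("cellsAtRisk must be a single positive number")
  TRUE
})

#' DisjunctionModel: fate of achiasmate chromosomes at meiosis I
#'
#' @slot pDisjoin probability an achiasmate homolog pair nevertheless
#'   disjoins correctly (distributive disjunction / centromere pairing).
#' @slot disomicViable logical; whether disomic spores germinate.
#' @slot backgroundDeath per-spore death probability independent of
#'   nondisjunction.
#' @export
setClass("DisjunctionModel",
         representation(pDisjoin = "numeric", disomicViable = "logical",
                        backgroundDeath = "numeric"))

setValidity("DisjunctionModel", function(object) {
  p <- c(object@pDisjoin, object@backgroundDeath)
  if (length(object@pDisjoin) != 1 || length(object@backgroundDeath) != 1 ||
      any(p < 0) || any(p > 1))
    return("pDisjoin and backgroundDeath must be single probabilities in [0,1]")
  TRUE
})

#' SimulationConfig: parameters of the synthetic meiosis generator
#'
#' @slot map the [MarkerMap-class] to genotype against.
#' @slot intervalCM numeric named by "A-B" interval: true map distance (cM)
#'   of each interval for the genotype being simulated.
#' @slot chromosomeCM numeric named by chromosome: the chromosome's total
#'   genetic length (cM), at least the sum of its marked intervals. The
#'   excess places crossovers outside the marked span, which count towards
#'   the obligate-crossover (achiasmate) bookkeeping but do not alter
#'   marker genotypes.
#' @slot pathwayScaling numeric length 2, named `interference`,
#'   `noninterference`: multipliers on the two crossover pathway classes.
#' @slot interferenceShare fraction of wild-type crossovers carried by the
#'   interference-dependent class.
#' @slot conversionRate per-marker per-meiosis gene-conversion probability.
#' @slot disjunction a [DisjunctionModel-class].
#' @slot nTetrads number of meioses to simulate.
#' @slot seed integer RNG seed (mandatory: manifests must be reproducible).
#' @export
setClass("SimulationConfig",
         representation(map = "MarkerMap", intervalCM = "numeric",
                        chromosomeCM = "numeric",
                        pathwayScaling = "numeric", interferenceShare = "numeric",
                        conversionRate = "numeric", disjunction = "DisjunctionModel",
                        nTetrads = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  iv <- mapIntervals(object@map)
  key <- paste(iv$marker_a, iv$marker_b, sep = "-")
  if (!all(key %in% names(object@intervalCM)))
    return(sprintf("intervalCM missing intervals: %s",
                   paste(setdiff(key, names(object@intervalCM)), collapse = ", ")))
  if (any(object@intervalCM < 0)) return("interval distances must be >= 0")
  chrs <- unique(iv$chromosome)
  if (!all(chrs %in% names(object@chromosomeCM)))
    return("chromosomeCM must name every chromosome of the map")
  marked <- vapply(chrs, function(ch)
    sum(object@intervalCM[key[iv$chromosome == ch]]), numeric(1))
  if (any(object@chromosomeCM[chrs] + 1e-9 < marked))
    return("chromosomeCM cannot be smaller than the summed interval distances")
  if (!identical(sort(names(object@pathwayScaling)),
                 c("interference", "noninterference")))
    return("pathwayScaling must be named interference, noninterference")
  if (any(object@pathwayScaling < 0)) return("pathway multipliers must be >= 0")
  if (object@interferenceShare < 0 || object@interferenceShare > 1)
    return("interferenceShare must be in [0,1]")
  if (object@conversionRate < 0 || object@conversionRate > 1)
    return("conversionRate must be in [0,1]")
  if (object@nTetrads < 0 || object@nTetrads != round(object@nTetrads))
    return("nTetrads must be a non-negative integer")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("seed is mandatory")
  TRUE
})
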