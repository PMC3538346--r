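#' Construct a SimulationConfig
#'
#' @param map a [MarkerMap-class]
#' @param intervalCM named numeric, one true map distance (cM) per "A-B"
#'   interval of the map. These are the distances of the genotype being
#'   simulated.
#' @param chromosomeCM named numeric, total genetic length (cM) per
#'   chromosome; defaults to the summed marked intervals. Length beyond the
#'   marked span contributes crossovers that count for achiasmate
#'   bookkeeping but are invisible to the markers.
#' @param pathwayScaling numeric c(interference=, noninterference=):
#'   multipliers on the two crossover pathway classes; both 1 leaves
#'   `intervalCM` unscaled.
#' @param interferenceShare fraction of crossovers carried by the
#'   interference-dependent (Msh4-Msh5/Mlh1-Mlh3) class in the reference
#'   genotype; default 0.7.
#' @param conversionRate per-marker per-meiosis gene-conversion probability.
#' @param disjunction a [DisjunctionModel-class]
#' @param nTetrads meioses to simulate.
#' @param seed mandatory integer seed: manifests must be reproducible.
#' @return a [SimulationConfig-class]
#' @export
SimulationConfig <- function(map, intervalCM, chromosomeCM = NULL,
                             pathwayScaling = c(interference = 1, noninterference = 1),
                             interferenceShare = 0.7,
                             conversionRate = 0,
                             disjunction = DisjunctionModel(),
                             nTetrads = 100, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(chromosomeCM)) {
    iv <- mapIntervals(map)
    chromosomeCM <- vapply(unique(iv$chromosome), function(ch)
      sum(intervalCM[iv$interval[iv$chromosome == ch]]), numeric(1))
  }
  new("SimulationConfig", map = map, intervalCM = intervalCM,
      chromosomeCM = chromosomeCM,
      pathwayScaling = pathwayScaling, interferenceShare = interferenceShare,
      conversionRate = conversionRate, disjunction = disjunction,
      nTetrads = nTetrads, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d tetrads, %d intervals, scaling (i=%g, ni=%g), seed %d\n",
    object@nTetrads, length(object@intervalCM),
    object@pathwayScaling[["interference"]],
    object@pathwayScaling[["noninterference"]], as.integer(object@seed)))
})

# Effective distances after pathway scaling: the two classes share placement
# rules and differ only in rates, so scaling acts on the cM scale.
.pathwayMultiplier <- function(config) {
  s <- config@interferenceShare
  s * config@pathwayScaling[["interference"]] +
    (1 - s) * config@pathwayScaling[["noninterference"]]
}

.effectiveCM <- function(config) config@intervalCM * .pathwayMultiplier(config)

#' Simulate tetrads by chromatid-level meiosis
#'
#' Per meiosis and interval the crossover count is Poisson with mean
#' d/50 (d = effective cM after pathway scaling): one crossover per
#' four-chromatid bundle yields 100% tetratypes = 50 cM. Each crossover
#' picks one of the four non-sister chromatid pairs uniformly (no chromatid
#' interference) and exchanges the segments distal to its interval. MI
#' segregates the two centromere pairs to opposite poles with random
#' orientation; spore labels are shuffled per tetrad (dissection order is
#' arbitrary). All spores start viable; [applyViability()] resolves
#' nondisjunction afterwards using the manifest's achiasmate flags.
#'
#' @param config a [SimulationConfig-class]
#' @return list with `tetrads` (a [TetradSet-class]) and `manifest` (config
#'   echo, realized per-interval crossover counts, per-tetrad achiasmate
#'   flags and MI pole partition, expected tallies).
#' @export
simulateTetrads <- function(config) {
  stopifnot(validObject(config))
  set.seed(as.integer(config@seed))
  map <- config@map
  iv <- mapIntervals(map)
  dEff <- .effectiveCM(config)[iv$interval]
  n <- config@nTetrads
  chrs <- chromosomes(map)
  allMk <- markerNames(map)
  mult <- .pathwayMultiplier(config)
  unmarkedCM <- vapply(chrs, function(ch) {
    marked <- sum(config@intervalCM[iv$interval[iv$chromosome == ch]])
    max(0, config@chromosomeCM[[ch]] - marked) * mult
  }, numeric(1))
  names(unmarkedCM) <- chrs

  alleles <- vector("list", n)
  achiasmate <- matrix(FALSE, n, length(chrs), dimnames = list(NULL, chrs))
  poleA <- matrix("", n, length(chrs), dimnames = list(NULL, chrs))
  xoCounts <- stats::setNames(numeric(nrow(iv)), iv$interval)

  for (t in seq_len(n)) {
    gt <- matrix("-", 4, length(allMk), dimnames = list(NULL, allMk))
    shuffle <- sample.int(4)  # chromatid-slot -> spore label, shared across chromosomes
    for (ci in seq_along(chrs)) {
      chr <- chrs[ci]
      mk <- markerNames(map, chr)
      K <- length(mk)
      # chromatids 1,2 carry P centromeres; 3,4 carry M
      ch <- rbind(rep("P", K), rep("P", K), rep("M", K), rep("M", K))
      ividx <- which(iv$chromosome == chr)
      nxo <- stats::rpois(length(ividx), dEff[ividx] / 50)
      xoCounts[ividx] <- xoCounts[ividx] + nxo
      # crossovers outside the marked span: invisible to markers but they
      # still satisfy the obligate-crossover requirement
      unmarked <- stats::rpois(1, unmarkedCM[chr] / 50)
      achiasmate[t, ci] <- sum(nxo) + unmarked == 0L
      for (j in seq_along(ividx)) {
        for (e in seq_len(nxo[j])) {
          pr <- c(sample(1:2, 1), sample(3:4, 1))  # non-sister pair, uniform
          distal <- (j + 1):K
          tmp <- ch[pr[1], distal]
          ch[pr[1], distal] <- ch[pr[2], distal]
          ch[pr[2], distal] <- tmp
        }
      }
      # MI: centromere pairs {1,2} and {3,4} to opposite poles, random
      # orientation; spore slots 1,2 = pole A, 3,4 = pole B
      slots <- if (stats::runif(1) < 0.5) c(1, 2, 3, 4) else c(3, 4, 1, 2)
      gt[shuffle[slots], mk] <- ch
      poleA[t, ci] <- paste(sort(shuffle[slots[1:2]]), collapse = ",")
    }
    alleles[[t]] <- gt
  }

  ids <- sprintf("t%04d", seq_len(n))
  df <- data.frame(tetrad_id = rep(ids, each = 4), spore = rep(1:4, n),
                   viable = TRUE, stringsAsFactors = FALSE)
  big <- do.call(rbind, alleles)
  for (m in allMk) df[[m]] <- big[, m]
  tetrads <- TetradSet(df, map)

  expCM <- stats::setNames(dEff, iv$interval)
  manifest <- list(
    config = list(nTetrads = n, seed = as.integer(config@seed),
                  intervalCM = as.list(config@intervalCM),
                  pathwayScaling = as.list(config@pathwayScaling),
                  interferenceShare = config@interferenceShare,
                  conversionRate = config@conversionRate,
                  pDisjoin = config@disjunction@pDisjoin,
                  disomicViable = config@disjunction@disomicViable,
                  backgroundDeath = config@disjunction@backgroundDeath),
    realized_crossovers = as.list(xoCounts),
    expected_cM = as.list(expCM),
    achiasmate = achiasmate,
    pole_pairs = poleA,
    conversion_events = 0L,
    ndj_events = 0L)
  list(tetrads = tetrads, manifest = manifest)
}

#' Overlay marker-local gene conversion
#'
#' Each marker x tetrad is independently converted with probability `rate`:
#' one uniformly chosen spore's allele is overwritten by the opposite
#' allele, producing 3:1 and 1:3 segregation with equal probability from a
#' 2:2 input. Tracts are not modelled; conversions are marker-local.
#'
#' @param tetrads a [TetradSet-class] (all spores still scored).
#' @param rate per-marker per-tetrad conversion probability.
#' @return list with modified `tetrads` and `n_events`.
#' @export
applyGeneConversion <- function(tetrads, rate) {
  stopifnot(rate >= 0, rate <= 1)
  sp <- spores(tetrads)
  mk <- markerNames(tetrads)
  n <- nTetrads(tetrads)
  events <- 0L
  if (rate > 0 && n > 0) {
    for (m in mk) {
      hit <- which(stats::runif(n) < rate)
      for (t in hit) {
        row <- (t - 1) * 4 + sample.int(4, 1)
        cur <- sp[[m]][row]
        if (cur == "-") next
        sp[[m]][row] <- if (cur == "P") "M" else "P"
        events <- events + 1L
      }
    }
  }
  list(tetrads = TetradSet(sp, markerMap(tetrads)), n_events = events)
}

#' Resolve nondisjunction-driven spore death
#'
#' For each meiosis, each achiasmate chromosome (from the simulation
#' manifest) disjoins correctly with probability `pDisjoin`; otherwise both
#' homologs travel to one MI pole (chosen at random between the two), the
#' nullisomic spore pair dies and the disomic pair survives iff
#' `disomicViable` (its markers on that chromosome become unscorable).
#' Background death is then applied per surviving spore. Dead spores have
#' all alleles masked to `-`.
#'
#' @param tetrads a [TetradSet-class] from [simulateTetrads()]
#' @param model a [DisjunctionModel-class]
#' @param manifest the manifest of [simulateTetrads()] (achiasmate flags and
#'   MI pole partitions).
#' @return list with modified `tetrads` and `n_ndj` events.
#' @export
applyViability <- function(tetrads, model, manifest) {
  sp <- spores(tetrads)
  map <- markerMap(tetrads)
  ids <- tetradIds(tetrads)
  ach <- manifest$achiasmate
  poles <- manifest$pole_pairs
  ndj <- 0L
  viable <- matrix(TRUE, length(ids), 4)
  for (t in seq_along(ids)) {
    for (ci in seq_len(ncol(ach))) {
      if (!ach[t, ci]) next
      if (stats::runif(1) < model@pDisjoin) next
      ndj <- ndj + 1L
      pairA <- as.integer(strsplit(poles[t, ci], ",")[[1]])
      pairB <- setdiff(1:4, pairA)
      both <- stats::runif(1) < 0.5  # which pole receives both homologs
      disomic <- if (both) pairA else pairB
      nulli <- if (both) pairB else pairA
      viable[t, nulli] <- FALSE
      if (!model@disomicViable) viable[t, disomic] <- FALSE
      # disomic spores are heterozygous along this chromosome: unscorable
      mk <- markerNames(map, chromosomes(map)[ci])
      rows <- (t - 1) * 4 + disomic
      for (m in mk) sp[[m]][rows] <- "-"
    }
  }
  if (model@backgroundDeath > 0) {
    bg <- matrix(stats::runif(length(ids) * 4) < model@backgroundDeath,
                 length(ids), 4)
    viable <- viable & !bg
  }
  sp$viable <- as.vector(t(viable))  # spores ordered tetrad-major, spore 1..4
  mk <- markerNames(tetrads)
  dead <- !sp$viable
  for (m in mk) sp[[m]][dead] <- "-"
  list(tetrads = TetradSet(sp, map), n_ndj = ndj)
}

#' Simulate one fluctuation assay (Luria-Delbruck cultures)
#'
#' Synchronous doubling from `nInitial` to `nFinal` cells. Each generation
#' every non-mutant cell divides; each division yields a new mutant with
#' probability `mu` (new mutants ~ Binomial(#divisions, mu)); existing
#' mutant lineages double. The zero-mutant fraction therefore follows the
#' P0 law exp(-mu (nFinal - nInitial)).
#'
#' @param mu per-division mutation probability, in (0, 1).
#' @param nInitial,nFinal initial and final cells per culture
#'   (nFinal > nInitial >= 1); growth stops once nFinal is reached.
#' @param nCultures number of parallel cultures.
#' @return a [FluctuationExperiment-class] with cellsAtRisk = nFinal.
#' @export
simulateFluctuation <- function(mu, nInitial, nFinal, nCultures) {
  if (mu < 0 || mu >= 1) stop("mu must lie in [0, 1)")
  if (!(nFinal > nInitial) || nInitial < 1) stop("need nFinal > nInitial >= 1")
  gens <- ceiling(log2(nFinal / nInitial))
  counts <- vapply(seq_len(nCultures), function(i) {
    nonmut <- nInitial; mut <- 0
    for (g in seq_len(gens)) {
      divisions <- min(nonmut, nFinal - (nonmut + mut))  # cap growth at nFinal
      if (divisions <= 0) break
      newMut <- stats::rbinom(1, divisions, mu)
      mut <- 2 * mut + newMut
      nonmut <- nonmut + divisions - newMut
    }
    mut
  }, numeric(1))
  FluctuationExperiment(counts, cellsAtRisk = nFinal)
}

# ---- genotype presets ----------------------------------------------------

#' Genotype presets for the study generator
#'
#' Per-interval true distances are the Perkins estimates recomputed from the
#' packaged chromosome III/VII/VIII count table; viability and conversion
#' parameters come from the packaged viability and aberrant-segregation
#' tables. `backgroundDeath` is calibrated so the preset's expected percent
#' viability (nondisjunction from achiasmate chromosomes, at the preset's
#' own distances, plus background death) matches the printed viability.
#'
#' `pDisjoin` is genotype-dependent, following the observed viable-spore
#' profiles: the mlh3 deletion shows the 4-2-0 signature of meiosis-I
#' nondisjunction (achiasmate pairs segregate like a coin flip, 0.5),
#' whereas the mms4 deletion and the double mutant lack that signature
#' despite far lower crossover levels, implying an efficient backup
#' disjunction route for their achiasmate pairs (0.9).
#'
#' @param name one of `"wild type"`, `"mlh3d"`, `"mms4d"`, `"mlh3d mms4d"`.
#' @param nTetrads meioses to simulate; defaults to the printed dissection
#'   count for the genotype.
#' @param seed mandatory seed.
#' @return a [SimulationConfig-class]
#' @export
presetConfig <- function(name, nTetrads = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  t7 <- loadFixture("table7")
  t6 <- loadFixture("table6")
  if (!name %in% unique(t7$genotype))
    stop("unknown preset '", name, "'; available: ",
         paste(unique(t7$genotype), collapse = ", "))
  map <- loadFixture("map_nhy")
  d <- t7[t7$genotype == name, ]
  cm <- stats::setNames(perkinsCM(d$PD, d$TT, d$NPD), d$interval)
  iv <- mapIntervals(map)
  cm <- cm[iv$interval]
  # conversion rate: mean per-marker aberrant fraction of the genotype
  t8 <- loadFixture("table8")
  ab <- t8[t8$genotype == name & t8$marker != "(total)", "percent_aberrant"]
  conv <- mean(ab) / 100
  # chromosome genetic lengths: genome-wide wild-type means (3, 8 and 4
  # crossovers per meiosis on III, VII, VIII) scaled down by the genotype's
  # cumulative-distance fold change over the marked intervals
  wtMeans <- c(III = 3, VII = 8, VIII = 4)
  t6g <- t6[t6$genotype == name & t6$source == "this_study", ]
  t6wt <- t6[t6$genotype == "wild type" & t6$source == "this_study", ]
  fold <- stats::setNames(
    t6wt$cumulative_cM[match(names(wtMeans), t6wt$chromosome)] /
      t6g$cumulative_cM[match(names(wtMeans), t6g$chromosome)],
    names(wtMeans))
  chrMeans <- expectedCrossovers(wtMeans, fold)
  chrCM <- pmax(50 * chrMeans, vapply(names(wtMeans), function(ch)
    sum(cm[iv$interval[iv$chromosome == ch]]), numeric(1)))
  # background death calibrated so expected viability (nondisjunction from
  # achiasmate chromosomes plus background) matches the printed percent
  pDis <- c("wild type" = 0.5, "mlh3d" = 0.5,
            "mms4d" = 0.9, "mlh3d mms4d" = 0.9)[[name]]
  target <- t6g$spore_viability_pct[1]
  e0 <- probAchiasmate(chrCM / 50)
  base <- percentViable(viabilityDistribution(e0, DisjunctionModel(pDisjoin = pDis)))
  bd <- max(0, min(1, 1 - target / base))
  n <- if (is.null(nTetrads)) t6g$n_tetrads[1] else nTetrads
  SimulationConfig(map = map, intervalCM = cm, chromosomeCM = chrCM,
                   conversionRate = conv,
                   disjunction = DisjunctionModel(pDisjoin = pDis,
                                                  backgroundDeath = bd),
                   nTetrads = n, seed = seed)
}

#' Generate a full synthetic study for the genotype presets
#'
#' Runs [simulateTetrads()], [applyGeneConversion()] and [applyViability()]
#' for each preset, writes the tetrad tables, the marker map, a fluctuation
#' input table and a JSON manifest into `dir`. Outputs are byte-identical
#' for identical (presets, nTetrads, seed).
#'
#' @param dir output directory (created if absent).
#' @param presets character vector of preset names.
#' @param nTetrads optional override of per-preset tetrad numbers.
#' @param seed mandatory master seed; per-preset seeds are derived from it.
#' @return invisible named list of per-preset file paths and manifests.
#' @export
generateStudy <- function(dir, presets = c("wild type", "mlh3d", "mms4d", "mlh3d mms4d"),
                          nTetrads = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMarkerMap(loadFixture("map_nhy"), file.path(dir, "marker_map.tsv"))
  out <- list()
  for (i in seq_along(presets)) {
    pr <- presets[i]
    cfg <- presetConfig(pr, nTetrads = nTetrads, seed = (seed * 131 + i) %% .Machine$integer.max)
    sim <- simulateTetrads(cfg)
    set.seed(as.integer(cfg@seed) + 1L)
    gc_ <- applyGeneConversion(sim$tetrads, cfg@conversionRate)
    vi <- applyViability(gc_$tetrads, cfg@disjunction, sim$manifest)
    slug <- gsub("[^A-Za-z0-9]+", "_", pr)
    tpath <- file.path(dir, paste0("tetrads_", slug, ".tsv"))
    writeTetradTable(vi$tetrads, tpath)
    man <- sim$manifest
    man$conversion_events <- gc_$n_events
    man$ndj_events <- vi$n_ndj
    man$achiasmate <- colSums(man$achiasmate)
    man$pole_pairs <- NULL
    man$observed_tallies <- tallyIntervals(vi$tetrads)
    mpath <- file.path(dir, paste0("manifest_", slug, ".json"))
    jsonlite::write_json(man, mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out[[pr]] <- list(tetrads = tpath, manifest_path = mpath, manifest = man)
  }
  # fluctuation inputs: wild-type-like and mutator-like rates (per 2e7 cells)
  set.seed(as.integer(seed) + 999L)
  fl <- rbind(
    data.frame(strain = "MLH3", culture = 1:15,
               mutant_colonies = cultureCounts(
                 simulateFluctuation(4.71e-7, 1250, 2e7, 15)),
               cells_plated = 2e7),
    data.frame(strain = "mlh3d", culture = 1:15,
               mutant_colonies = cultureCounts(
                 simulateFluctuation(26.5e-7, 1250, 2e7, 15)),
               cells_plated = 2e7))
  fpath <- file.path(dir, "fluctuation.tsv")
  utils::write.table(fl, fpath, sep = "\t", quote = FALSE, row.names = FALSE)
  out$fluctuation <- fpath
  invisible(out)
}
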