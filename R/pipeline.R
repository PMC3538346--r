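#' Run the full tetrad analysis and write report files
#'
#' Two input modes, mirroring how such data exist in practice:
#' genotype-level (one tetrad genotype TSV per genotype, plus a marker map)
#' and summary-level (a single per-interval count table, the only level at
#' which published data are available).
#'
#' Writes into `outDir`:
#' \describe{
#'   \item{estimates.tsv}{per genotype x interval x method: cM, se, 95% CI
#'     and the underlying counts.}
#'   \item{cumulative.tsv}{per genotype x chromosome cumulative distances
#'     (both methods) and fold decrease versus the reference genotype.}
#'   \item{segregation.tsv}{per genotype x marker aberrant-segregation
#'     tallies (genotype-level mode only).}
#'   \item{summary.json}{viability profiles with nondisjunction bias
#'     scores, chi-square viable/dead comparisons against the reference,
#'     and the viability-versus-distance regression (genotype-level mode,
#'     3+ genotypes).}
#' }
#'
#' @param outDir output directory, created if needed.
#' @param tetradFiles named character vector (genotype -> tetrad TSV path)
#'   for genotype-level mode.
#' @param map a [MarkerMap-class] or path to a marker map TSV
#'   (genotype-level mode).
#' @param summaryFile per-interval count TSV with columns `genotype`,
#'   `chromosome`, `interval`, `spores_total`, `parental`, `recombinant`,
#'   `tetrads`, `PD`, `TT`, `NPD` (summary-level mode).
#' @param reference reference genotype for fold changes and chi-square
#'   comparisons; defaults to the first genotype.
#' @return invisible list with the computed tables and the paths written.
#' @export
runAnalysis <- function(outDir, tetradFiles = NULL, map = NULL,
                        summaryFile = NULL, reference = NULL) {
  if (is.null(tetradFiles) && is.null(summaryFile))
    stop("no input: give tetradFiles+map or summaryFile")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(summaryFile)) {
    tb <- utils::read.delim(summaryFile, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("genotype", "chromosome", "interval", "spores_total",
              "parental", "recombinant", "tetrads", "PD", "TT", "NPD")
    if (!all(need %in% names(tb)))
      stop("summary counts file must have columns: ",
           paste(need, collapse = ", "))
    if (!nrow(tb)) stop("summary counts file is empty")
    counts <- tb
    extras <- NULL
  } else {
    if (is.null(names(tetradFiles)) || any(names(tetradFiles) == ""))
      stop("tetradFiles must be a named vector: genotype -> path")
    if (!length(tetradFiles)) stop("no tetrad files given")
    if (is.character(map)) map <- readMarkerMap(map)
    if (is.null(map)) stop("genotype-level mode needs a marker map")
    sets <- lapply(tetradFiles, readTetradTable, map = map)
    counts <- do.call(rbind, lapply(names(sets), function(g) {
      tl <- tallyIntervals(sets[[g]])
      message(sprintf("[%s] %d tetrads read, %d four-spore viable", g,
                      nTetrads(sets[[g]]), sum(nViable(sets[[g]]) == 4L)))
      data.frame(genotype = g, tl[c("chromosome", "interval")],
                 spores_total = tl$spores_total, parental = tl$parental,
                 recombinant = tl$recombinant, tetrads = tl$tetrads_scored,
                 PD = tl$PD, TT = tl$TT, NPD = tl$NPD,
                 stringsAsFactors = FALSE)
    }))
    extras <- sets
  }

  genos <- unique(counts$genotype)
  if (is.null(reference)) reference <- genos[1]
  if (!reference %in% genos)
    stop("reference genotype '", reference, "' not among inputs")

  est <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    pe <- if (r$PD + r$TT + r$NPD > 0)
      perkinsEstimate(r$PD, r$TT, r$NPD) else
      data.frame(cM = NA, se = NA, ci_low = NA, ci_high = NA, n = 0,
                 method = "perkins_tetrad")
    se_ <- if (r$spores_total > 0)
      singleSporeEstimate(r$parental, r$recombinant) else
      data.frame(cM = NA, se = NA, ci_low = NA, ci_high = NA, n = 0,
                 method = "single_spore")
    cbind(r[c("genotype", "chromosome", "interval", "PD", "TT", "NPD",
              "parental", "recombinant")],
          rbind(pe, se_), row.names = NULL)
  }))
  utils::write.table(est, file.path(outDir, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cum <- do.call(rbind, lapply(genos, function(g) {
    do.call(rbind, lapply(unique(counts$chromosome), function(chr) {
      d <- est[est$genotype == g & est$chromosome == chr, ]
      do.call(rbind, lapply(split(d, d$method), function(dd) {
        if (any(is.na(dd$cM))) return(NULL)
        cd <- cumulativeDistance(dd$cM, dd$se)
        data.frame(genotype = g, chromosome = chr, method = dd$method[1],
                   cumulative_cM = cd$cM, se = cd$se,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(cum) <- NULL
  cum$fold_vs_reference <- NA_real_
  for (i in seq_len(nrow(cum))) {
    ref <- cum[cum$genotype == reference & cum$chromosome == cum$chromosome[i] &
                 cum$method == cum$method[i], "cumulative_cM"]
    if (length(ref) == 1 && cum$cumulative_cM[i] > 0)
      cum$fold_vs_reference[i] <- foldDecrease(ref, cum$cumulative_cM[i])
  }
  utils::write.table(cum, file.path(outDir, "cumulative.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(reference = reference, genotypes = genos)
  paths <- list(estimates = file.path(outDir, "estimates.tsv"),
                cumulative = file.path(outDir, "cumulative.tsv"))

  if (!is.null(extras)) {
    seg <- do.call(rbind, lapply(names(extras), function(g) {
      mk <- markerNames(extras[[g]])
      cbind(genotype = g,
            do.call(rbind, lapply(mk, function(m) segregationTally(extras[[g]], m))))
    }))
    utils::write.table(seg, file.path(outDir, "segregation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths$segregation <- file.path(outDir, "segregation.tsv")

    profiles <- lapply(extras, viabilityProfile)
    summary$viability <- lapply(names(profiles), function(g) {
      p <- profiles[[g]]
      list(genotype = g, counts = as.list(profileCounts(p)),
           percent_viable = percentViable(p), ndj_bias = ndjBiasScore(p))
    })
    summary$chi_square_vs_reference <- lapply(setdiff(names(profiles), reference),
      function(g) {
        vd <- function(p) c(sum((0:4) * profileCounts(p)),
                            4 * p@nTetrads - sum((0:4) * profileCounts(p)))
        ht <- chiSquare2xk(rbind(vd(profiles[[reference]]), vd(profiles[[g]])))
        list(genotype = g, statistic = ht$statistic, df = ht$df,
             p_value = ht$p_value)
      })
    if (length(genos) >= 3) {
      pv <- vapply(profiles, percentViable, numeric(1))
      cc <- vapply(genos, function(g) {
        d <- cum[cum$genotype == g & cum$method == "perkins_tetrad", ]
        sum(d$cumulative_cM)
      }, numeric(1))
      if (stats::var(cc) > 0 && stats::var(pv) > 0)
        summary$regression <- fitViabilityVsDistance(cc, pv[genos])
    }
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$summary <- file.path(outDir, "summary.json")
  invisible(list(counts = counts, estimates = est, cumulative = cum,
                 summary = summary, paths = paths))
}

#' Generate a synthetic study from presets
#'
#' Thin wrapper over [generateStudy()] that reports the files written.
#' @inheritParams generateStudy
#' @export
runSimulation <- function(outDir, presets = c("wild type", "mlh3d", "mms4d", "mlh3d mms4d"),
                          nTetrads = NULL, seed) {
  res <- generateStudy(outDir, presets = presets, nTetrads = nTetrads, seed = seed)
  for (pr in presets)
    message("wrote ", res[[pr]]$tetrads, " + ", res[[pr]]$manifest_path)
  invisible(res)
}

#' Fluctuation-assay analysis over a strain table
#'
#' @param input fluctuation TSV (see [readFluctuationTable()]).
#' @param referenceStrain strain whose rate normalizes the others; default
#'   the first strain in the file.
#' @param out optional output TSV path.
#' @return data.frame: `strain`, `n`, `rate`, `ci_low`, `ci_high`, `relative`.
#' @export
runFluctuation <- function(input, referenceStrain = NULL, out = NULL) {
  exps <- readFluctuationTable(input)
  if (is.null(referenceStrain)) referenceStrain <- names(exps)[1]
  if (!referenceStrain %in% names(exps))
    stop("reference strain '", referenceStrain, "' not in input")
  refRate <- mutationRate(exps[[referenceStrain]])$rate
  tab <- do.call(rbind, lapply(names(exps), function(s) {
    mr <- mutationRate(exps[[s]], reference = refRate)
    data.frame(strain = s, n = mr$n, rate = mr$rate, ci_low = mr$ci_low,
               ci_high = mr$ci_high,
               relative = relativeRate(mr$rate, refRate),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

#' Copy the packaged summary tables into a directory
#'
#' @param outDir destination directory.
#' @return invisible character vector of the files written.
#' @export
dumpFixtures <- function(outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  src <- vapply(.FIXTURE_FILES, function(f)
    system.file("extdata", f, package = "tetramap", mustWork = TRUE), character(1))
  ok <- file.copy(src, file.path(outDir, basename(src)), overwrite = TRUE)
  if (!all(ok)) stop("failed to copy fixture files")
  invisible(file.path(outDir, basename(src)))
}
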