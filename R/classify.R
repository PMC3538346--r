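#' Classify tetrads for a two-marker interval
#'
#' For each tetrad the four (markerA, markerB) allele pairs are classified:
#' parental ditype (`PD`, the two parental combinations 2:2), nonparental
#' ditype (`NPD`, the two recombinant combinations 2:2), tetratype (`TT`,
#' all four combinations once). A tetrad is `UNSCORABLE` when either marker
#' deviates from 2:2 segregation (gene conversion) or any spore carries a
#' missing call at either marker; only four-spore-viable tetrads are
#' classifiable, others are `UNSCORABLE` by the missing-call rule.
#'
#' @param tetrads a [TetradSet-class]
#' @param interval length-2 character: the two flanking marker names.
#' @return factor of levels PD, TT, NPD, UNSCORABLE, named by tetrad id.
#' @export
classifyInterval <- function(tetrads, interval) {
  stopifnot(length(interval) == 2)
  sp <- spores(tetrads)
  if (!all(interval %in% names(sp)))
    stop("interval markers absent from genotypes: ",
         paste(setdiff(interval, names(sp)), collapse = ", "))
  ids <- tetradIds(tetrads)
  a <- matrix(sp[[interval[1]]], nrow = 4)  # spores ordered 1:4 within tetrad
  b <- matrix(sp[[interval[2]]], nrow = 4)
  out <- vapply(seq_along(ids), function(i) {
    .classifyPairs(a[, i], b[, i])
  }, character(1))
  factor(stats::setNames(out, ids), levels = c("PD", "TT", "NPD", "UNSCORABLE"))
}

# Case analysis for one tetrad's allele vectors at two markers.
.classifyPairs <- function(a, b) {
  if (any(a == "-") || any(b == "-")) return("UNSCORABLE")
  if (sum(a == "P") != 2L || sum(b == "P") != 2L) return("UNSCORABLE")
  pair <- paste0(a, b)
  tab <- table(factor(pair, c("PP", "PM", "MP", "MM")))
  if (tab[["PP"]] == 2L && tab[["MM"]] == 2L) return("PD")
  if (tab[["PM"]] == 2L && tab[["MP"]] == 2L) return("NPD")
  "TT"  # both markers 2:2 and not a ditype => all four combinations once
}

#' Per-interval tetrad and single-spore tallies
#'
#' Tetrad tallies (PD/TT/NPD) use only four-spore-viable tetrads whose class
#' is scorable for the interval. Single-spore tallies use every viable spore
#' scored at both flanking markers, including spores of incomplete tetrads
#' and of tetrads unscorable at the tetrad level; a spore is recombinant
#' when its two-marker allele pair is non-parental (PM or MP).
#'
#' @param tetrads a [TetradSet-class]
#' @param map optional [MarkerMap-class]; defaults to the set's own map.
#' @return data.frame with one row per interval: `chromosome`, `interval`,
#'   `PD`, `TT`, `NPD`, `tetrads_scored`, `parental`, `recombinant`,
#'   `spores_total`.
#' @export
tallyIntervals <- function(tetrads, map = markerMap(tetrads)) {
  iv <- mapIntervals(map)
  sp <- spores(tetrads)
  nv <- nViable(tetrads)
  full <- names(nv)[nv == 4L]
  out <- lapply(seq_len(nrow(iv)), function(k) {
    ma <- iv$marker_a[k]; mb <- iv$marker_b[k]
    cls <- if (length(full) && nrow(sp)) {
      classifyInterval(tetrads[full], c(ma, mb))
    } else factor(character(0), c("PD", "TT", "NPD", "UNSCORABLE"))
    tc <- table(cls)
    ok <- nrow(sp) > 0 & sp$viable & sp[[ma]] != "-" & sp[[mb]] != "-"
    rec <- sum(ok & sp[[ma]] != sp[[mb]])
    par <- sum(ok) - rec
    data.frame(chromosome = iv$chromosome[k], interval = iv$interval[k],
               PD = as.integer(tc[["PD"]]), TT = as.integer(tc[["TT"]]),
               NPD = as.integer(tc[["NPD"]]),
               tetrads_scored = as.integer(sum(tc[c("PD", "TT", "NPD")])),
               parental = par, recombinant = rec, spores_total = par + rec,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aberrant (3:1 / 1:3) segregation at a marker
#'
#' Considers only four-spore-viable tetrads with complete calls at the
#' marker and classifies each by its P:M allele ratio. The percent aberrant
#' is 100 x (3:1 + 1:3) / tetrads examined.
#'
#' @param tetrads a [TetradSet-class]
#' @param marker marker name
#' @return data.frame row: `marker`, `n_tetrads`, `normal_2_2`,
#'   `aberrant_3_1`, `aberrant_1_3`, `other`, `percent_aberrant`.
#' @export
segregationTally <- function(tetrads, marker) {
  sp <- spores(tetrads)
  if (!marker %in% names(sp)) stop("marker absent from genotypes: ", marker)
  nv <- nViable(tetrads)
  full <- names(nv)[nv == 4L]
  al <- matrix(sp[[marker]][sp$tetrad_id %in% full], nrow = 4)
  scored <- colSums(al == "-") == 0L
  nP <- colSums(al[, scored, drop = FALSE] == "P")
  n <- sum(scored)
  n31 <- sum(nP == 3L); n13 <- sum(nP == 1L); n22 <- sum(nP == 2L)
  data.frame(marker = marker, n_tetrads = n, normal_2_2 = n22,
             aberrant_3_1 = n31, aberrant_1_3 = n13,
             other = n - n22 - n31 - n13,
             percent_aberrant = if (n > 0) 100 * (n31 + n13) / n else NA_real_,
             stringsAsFactors = FALSE)
}

#' Viable-spores-per-tetrad profile
#'
#' @param tetrads a [TetradSet-class], or an integer vector of viable-spore
#'   counts per tetrad (0-4).
#' @return a [ViabilityProfile-class]
#' @export
viabilityProfile <- function(tetrads) {
  k <- if (is(tetrads, "TetradSet")) nViable(tetrads) else as.integer(tetrads)
  stopifnot(all(k %in% 0:4))
  counts <- as.numeric(table(factor(k, 0:4)))
  names(counts) <- as.character(0:4)
  new("ViabilityProfile", counts = counts, nTetrads = sum(counts))
}

#' @rdname ViabilityProfile
#' @export
setMethod("profileCounts", "ViabilityProfile", function(x) x@counts)

#' Percent of all spores viable
#' @rdname ViabilityProfile
#' @export
setMethod("percentViable", "ViabilityProfile", function(x) {
  if (x@nTetrads == 0) return(NA_real_)
  100 * sum((0:4) * x@counts) / (4 * x@nTetrads)
})

setMethod("show", "ViabilityProfile", function(object) {
  cat(sprintf("ViabilityProfile: n = %g tetrads, %.1f%% spores viable\n",
              object@nTetrads, percentViable(object)))
  f <- object@counts / max(1e-12, sum(object@counts))
  cat("  viable spores 0..4: ",
      paste(sprintf("%.3f", f), collapse = " "), "\n", sep = "")
})

#' Meiosis-I nondisjunction bias score
#'
#' MI nondisjunction of a single homolog pair kills spores two at a time,
#' enriching tetrads with an even number of viable spores. The score is
#' (f4 + f2 + f0) - (f3 + f1) over the class fractions; 1 for a purely even
#' profile, 0.2 for a uniform one.
#'
#' @param profile a [ViabilityProfile-class]
#' @return numeric score in [-1, 1]
#' @export
ndjBiasScore <- function(profile) {
  stopifnot(is(profile, "ViabilityProfile"), profile@nTetrads > 0)
  f <- profile@counts / sum(profile@counts)
  unname(f[["4"]] + f[["2"]] + f[["0"]] - f[["3"]] - f[["1"]])
}
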