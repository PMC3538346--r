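.FIXTURE_FILES <- c(
  table3 = "table3_mutation_rates.tsv",
  table4 = "table4_viability_cm.tsv",
  table5 = "table5_chrXV.tsv",
  table6 = "table6_cumulative.tsv",
  table7 = "table7_chrIII_VII_VIII.tsv",
  table8 = "table8_aberrant.tsv",
  map_nhy = "marker_map_NHY.tsv",
  map_xv = "marker_map_XV.tsv"
)

#' Load a packaged summary table
#'
#' The package ships, as plain TSV, the study's printed summary data:
#' `table3` (fluctuation-assay mutation rates), `table4` (spore viability and
#' cumulative chromosome XV distances per strain), `table5` (chromosome XV
#' per-interval single-spore and tetrad counts), `table6` (cumulative
#' distances for four chromosomes), `table7` (chromosomes III/VII/VIII
#' per-interval counts), `table8` (aberrant 3:1/1:3 marker segregation), and
#' the two marker maps `map_nhy` and `map_xv`.
#'
#' Deletion genotypes are spelled with a trailing ASCII `d` (`mlh3d`,
#' `mms4d`, `msh5d`). Internal consistency of the per-interval tables
#' (parental + recombinant = total spores; PD+TT+NPD no larger than the
#' number of complete tetrads) is re-checked at every load.
#'
#' @param name one of `table3` ... `table8`, `map_nhy`, `map_xv`.
#' @return a data.frame, or a [MarkerMap-class] for the two maps.
#' @examples
#' t5 <- loadFixture("table5")
#' subset(t5, genotype == "wild type" & interval == "URA3-LEU2")$PD  # 607
#' @export
loadFixture <- function(name) {
  if (!name %in% names(.FIXTURE_FILES))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.FIXTURE_FILES), collapse = ", "))
  path <- system.file("extdata", .FIXTURE_FILES[[name]], package = "tetramap",
                      mustWork = TRUE)
  if (name %in% c("map_nhy", "map_xv")) return(readMarkerMap(path))
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (name %in% c("table5", "table7")) {
    stopifnot(all(tb$parental + tb$recombinant == tb$spores_total),
              all(tb$PD + tb$TT + tb$NPD <= tb$tetrads),
              all(tb[c("PD", "TT", "NPD", "parental", "recombinant")] >= 0))
  }
  tb
}

#' Both per-interval count tables as one data.frame
#'
#' Convenience wrapper binding the chromosome XV (`table5`) and the
#' III/VII/VIII (`table7`) per-interval tables.
#' @return data.frame in the `table5` layout.
#' @export
intervalCountTables <- function() {
  rbind(loadFixture("table5"), loadFixture("table7"))
}
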