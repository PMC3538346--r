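#' Construct a MarkerMap
#'
#' @param chromosome character vector of chromosome identifiers, recycled to
#'   the number of markers.
#' @param marker character vector of unique marker names.
#' @param position_kb numeric physical positions (kb), strictly increasing
#'   within each chromosome.
#' @return a [MarkerMap-class]
#' @examples
#' MarkerMap("III", c("HIS4", "LEU2", "CEN3", "MAT"), c(0, 23, 45, 135))
#' @export
MarkerMap <- function(chromosome, marker, position_kb) {
  tb <- data.frame(chromosome = as.character(rep_len(chromosome, length(marker))),
                   marker = as.character(marker),
                   position_kb = as.numeric(position_kb),
                   stringsAsFactors = FALSE)
  new("MarkerMap", table = tb)
}

#' @rdname MarkerMap
#' @export
setMethod("markerNames", "MarkerMap", function(x, chromosome = NULL) {
  tb <- x@table
  if (!is.null(chromosome)) tb <- tb[tb$chromosome %in% chromosome, , drop = FALSE]
  tb$marker
})

#' @rdname MarkerMap
#' @export
setMethod("chromosomes", "MarkerMap", function(x) unique(x@table$chromosome))

#' Adjacent-marker intervals of a map
#'
#' @rdname MarkerMap
#' @return `mapIntervals` returns a data.frame with columns `chromosome`,
#'   `interval` ("A-B"), `marker_a`, `marker_b`, `length_kb`.
#' @export
setMethod("mapIntervals", "MarkerMap", function(x, chromosome = NULL) {
  tb <- x@table
  if (!is.null(chromosome)) tb <- tb[tb$chromosome %in% chromosome, , drop = FALSE]
  out <- lapply(split(tb, factor(tb$chromosome, unique(tb$chromosome))), function(d) {
    k <- nrow(d)
    data.frame(chromosome = d$chromosome[-k],
               interval = paste(d$marker[-k], d$marker[-1], sep = "-"),
               marker_a = d$marker[-k], marker_b = d$marker[-1],
               length_kb = diff(d$position_kb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
})

setMethod("show", "MarkerMap", function(object) {
  tb <- object@table
  cat(sprintf("MarkerMap: %d markers on %d chromosome(s) [%s]\n",
              nrow(tb), length(unique(tb$chromosome)),
              paste(unique(tb$chromosome), collapse = ", ")))
  for (chr in unique(tb$chromosome)) {
    d <- tb[tb$chromosome == chr, ]
    cat(sprintf("  %s: %s\n", chr,
                paste(sprintf("%s@%gkb", d$marker, d$position_kb), collapse = " ")))
  }
})

#' Read / write a marker map TSV
#'
#' File dialect: tab-separated, header `chromosome  marker  position_kb`,
#' rows ordered by position within chromosome; `#` lines are comments.
#'
#' @param path file path
#' @return [MarkerMap-class]
#' @export
readMarkerMap <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chromosome", "marker", "position_kb")
  if (!all(need %in% names(tb)))
    stop("marker map file must have columns: ", paste(need, collapse = ", "))
  MarkerMap(tb$chromosome, tb$marker, tb$position_kb)
}

#' @rdname readMarkerMap
#' @param map a [MarkerMap-class]
#' @export
writeMarkerMap <- function(map, path) {
  utils::write.table(map@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
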