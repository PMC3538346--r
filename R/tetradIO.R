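#' Construct a TetradSet
#'
#' @param spores data.frame with columns `tetrad_id`, `spore` (1-4),
#'   `viable` (logical or 0/1), then one character column per marker with
#'   allele codes `P`, `M`, `-`.
#' @param map the [MarkerMap-class] the genotypes refer to.
#' @return a [TetradSet-class]
#' @export
TetradSet <- function(spores, map) {
  spores$tetrad_id <- as.character(spores$tetrad_id)
  spores$spore <- as.integer(spores$spore)
  spores$viable <- as.logical(spores$viable)
  mk <- setdiff(names(spores), c("tetrad_id", "spore", "viable"))
  for (m in mk) spores[[m]] <- as.character(spores[[m]])
  spores <- spores[order(match(spores$tetrad_id, unique(spores$tetrad_id)),
                         spores$spore), , drop = FALSE]
  rownames(spores) <- NULL
  new("TetradSet", spores = spores, map = map)
}

#' @rdname TetradSet
#' @export
setMethod("spores", "TetradSet", function(x) x@spores)

#' @rdname TetradSet
#' @export
setMethod("markerMap", "TetradSet", function(x) x@map)

#' @rdname TetradSet
#' @export
setMethod("tetradIds", "TetradSet", function(x) unique(x@spores$tetrad_id))

#' @rdname TetradSet
#' @export
setMethod("nTetrads", "TetradSet", function(x) length(tetradIds(x)))

#' Viable spores per tetrad
#' @rdname TetradSet
#' @return `nViable` returns an integer vector named by tetrad id.
#' @export
setMethod("nViable", "TetradSet", function(x) {
  sp <- x@spores
  ids <- tetradIds(x)
  out <- vapply(split(sp$viable, factor(sp$tetrad_id, ids)), sum, integer(1))
  out[ids]
})

#' @rdname TetradSet
#' @export
setMethod("markerNames", "TetradSet", function(x, chromosome = NULL) {
  mk <- setdiff(names(x@spores), c("tetrad_id", "spore", "viable"))
  if (is.null(chromosome)) return(mk)
  intersect(mk, markerNames(x@map, chromosome))
})

setMethod("show", "TetradSet", function(object) {
  nv <- nViable(object)
  cat(sprintf("TetradSet: %d tetrads (%d four-spore viable), %d markers\n",
              nTetrads(object), sum(nv == 4L), length(markerNames(object))))
})

#' Subset a TetradSet by tetrad ids
#' @param x a TetradSet
#' @param i character tetrad ids or logical/integer index into [tetradIds()]
#' @param j,drop,... ignored
#' @export
setMethod("[", "TetradSet", function(x, i, j, ..., drop = FALSE) {
  ids <- tetradIds(x)
  keep <- if (is.character(i)) i else ids[i]
  TetradSet(x@spores[x@spores$tetrad_id %in% keep, , drop = FALSE], x@map)
})

#' Read a tetrad genotype table
#'
#' Dialect: TSV with header `tetrad_id  spore  viable  <marker...>`;
#' `spore` in 1-4, `viable` in 0/1, alleles in `P`/`M`/`-`; `#` lines are
#' comments. Rows are grouped into tetrads by `tetrad_id`; each tetrad must
#' have exactly the four spores 1-4.
#'
#' @param path file path
#' @param map [MarkerMap-class]; every marker column must be present in it.
#' @return a [TetradSet-class]
#' @export
readTetradTable <- function(path, map) {
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("tetrad_id", "spore", "viable")
  if (!all(need %in% names(tb)))
    stop("tetrad table must start with columns: ", paste(need, collapse = ", "))
  mk <- setdiff(names(tb), need)
  unknown <- setdiff(mk, markerNames(map))
  if (length(unknown))
    stop("marker column(s) not in map: ", paste(unknown, collapse = ", "))
  sp <- suppressWarnings(as.integer(tb$spore))
  vi <- suppressWarnings(as.integer(tb$viable))
  bad <- which(is.na(sp) | !(sp %in% 1:4) | is.na(vi) | !(vi %in% 0:1))
  if (length(bad))
    stop(sprintf("malformed spore/viable value at data row %d of %s",
                 bad[1], path))
  al <- as.matrix(tb[mk])
  badc <- which(!(al %in% .ALLELES))
  if (length(badc)) {
    r <- ((badc[1] - 1) %% nrow(tb)) + 1
    stop(sprintf("invalid allele code '%s' at data row %d of %s",
                 al[badc[1]], r, path))
  }
  sizes <- table(tb$tetrad_id)
  if (any(sizes != 4))
    stop("tetrad(s) without exactly 4 spores: ",
         paste(names(sizes)[sizes != 4], collapse = ", "))
  df <- data.frame(tetrad_id = tb$tetrad_id, spore = sp,
                   viable = vi == 1L, stringsAsFactors = FALSE)
  df[mk] <- tb[mk]
  TetradSet(df, map)
}

#' Write a tetrad genotype table
#'
#' Inverse of [readTetradTable()]: `readTetradTable(writeTetradTable(x))`
#' returns an identical TetradSet.
#'
#' @param tetrads a [TetradSet-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeTetradTable <- function(tetrads, path) {
  sp <- spores(tetrads)
  out <- sp
  out$viable <- as.integer(sp$viable)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
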