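#' Accessors for simulator objects
#'
#' Small generic accessors used throughout: \code{nCells} gives the number of
#' grid cells; \code{cohorts} and \code{stocks} return decoded tidy tables;
#' \code{landscape} extracts the grid; \code{trophicTotals} sums biomass by
#' trophic compartment.
#'
#' @param x a \linkS4class{Landscape} or \linkS4class{SimState}.
#' @return \code{nCells}: integer. \code{cohorts}, \code{stocks}: data.frame
#'   with categorical codes decoded to labels. \code{trophicTotals}: named
#'   numeric (herbivore, omnivore, carnivore, autotroph, total), kg.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setMethod("nCells", "Landscape", function(x) x@nRows * x@nCols)

#' @rdname accessors
#' @export
setMethod("nCells", "SimState", function(x) nCells(x@landscape))

#' @rdname accessors
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))

#' @rdname accessors
#' @export
setMethod("cohorts", "SimState", function(x) {
  co <- x@cohorts
  co$trophic <- TROPHIC_LEVELS[co$trophic]
  co$thermo <- THERMO_LEVELS[co$thermo]
  co$repro <- REPRO_LEVELS[co$repro]
  cbind(co, cellRowCol(x@landscape, co$cell))
})

#' @rdname accessors
#' @export
setGeneric("stocks", function(x) standardGeneric("stocks"))

#' @rdname accessors
#' @export
setMethod("stocks", "SimState", function(x) {
  st <- x@stocks
  st$strategy <- LEAF_LEVELS[st$strategy]
  cbind(st, cellRowCol(x@landscape, st$cell))
})

#' @rdname accessors
#' @export
setGeneric("landscape", function(x) standardGeneric("landscape"))

#' @rdname accessors
#' @export
setMethod("landscape", "SimState", function(x) x@landscape)

#' @rdname accessors
#' @export
setGeneric("simMonth", function(x) standardGeneric("simMonth"))

#' @rdname accessors
#' @export
setMethod("simMonth", "SimState", function(x) x@month)

#' @rdname accessors
#' @export
setGeneric("trophicTotals", function(x) standardGeneric("trophicTotals"))

#' @rdname accessors
#' @export
setMethod("trophicTotals", "SimState", function(x) {
  co <- x@cohorts
  bio <- (co$mass + co$reproPool) * co$abundance
  out <- c(
    herbivore = sum(bio[co$trophic == 1L]),
    omnivore  = sum(bio[co$trophic == 2L]),
    carnivore = sum(bio[co$trophic == 3L]),
    autotroph = sum(x@stocks$leaf) + sum(x@stocks$structural)
  )
  c(out, total = sum(out))
})

## (row, col) of 1-based linear indices; exported tables use 0-based rows/cols
## with (0, 0) the north-west corner.
cellRowCol <- function(land, cell) {
  data.frame(row = (cell - 1L) %/% land@nCols,
             col = (cell - 1L) %% land@nCols)
}

## linear index from 0-based (row, col)
cellIndex <- function(land, row, col) row * land@nCols + col + 1L
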