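#' Validate a model object against its invariants
#'
#' Pure reporting: returns a character vector of violations (empty when the
#' object satisfies every invariant) and never mutates its argument. For a
#' \linkS4class{SimState} this checks cohort invariants (positive masses,
#' birth mass not above maturity mass, non-negative abundance, valid trait
#' codes and cell indices) and stock invariants (non-negative pools); for an
#' \linkS4class{EcosystemSummary} it checks component non-negativity and
#' that the stored total equals the independently recomputed component sum.
#'
#' @param state the object to validate.
#' @return character vector of human-readable violations; empty if valid.
#' @export
setGeneric("validateState", function(state) standardGeneric("validateState"))

#' @rdname validateState
#' @export
setMethod("validateState", "SimState", function(state) {
  v <- character()
  co <- state@cohorts
  nc <- state@landscape@nRows * state@landscape@nCols
  bad <- function(cond, what) {
    w <- which(cond)
    if (length(w))
      sprintf("cohort %d: %s", w, what)
    else character()
  }
  if (nrow(co)) {
    v <- c(v,
           bad(co$abundance < 0, "negative abundance"),
           bad(co$mass <= 0, "non-positive current mass"),
           bad(co$birthMass > co$maturityMass, "birth mass above maturity mass"),
           bad(!co$trophic %in% 1:3 | !co$thermo %in% 1:2 |
                 !co$repro %in% 1:2, "invalid categorical trait code"),
           bad(co$cell < 1L | co$cell > nc, "cell index outside grid"))
  }
  st <- state@stocks
  wbad <- which(st$leaf < 0 | st$structural < 0)
  if (length(wbad))
    v <- c(v, sprintf("stock in cell %d: negative biomass pool", wbad))
  if (nrow(st) != nc)
    v <- c(v, "stock table does not cover every cell")
  v
})

#' @rdname validateState
#' @export
setMethod("validateState", "EcosystemSummary", function(state) {
  v <- character()
  comp <- c(carnivore = state@carnivore, omnivore = state@omnivore,
            herbivore = state@herbivore, autotroph = state@autotroph)
  neg <- names(comp)[comp < 0]
  if (length(neg)) v <- c(v, paste("negative biomass:", neg))
  if (abs(state@total - sum(comp)) > 1e-9 * max(1, abs(state@total)))
    v <- c(v, "total biomass does not equal the component sum")
  v
})
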