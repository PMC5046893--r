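#' Trophic skew between an impacted and a pristine ecosystem
#'
#' Compares the relative biomass composition of the four trophic
#' compartments (carnivore, omnivore, herbivore, autotroph) between an
#' impacted ecosystem and its pristine reference, as half the L1 distance
#' (total-variation distance) between the two share vectors:
#' \deqn{skew = \frac{1}{2} \sum_{g \in \{C,O,H,A\}}
#'   \left| \frac{g_I}{T_I} - \frac{g_P}{T_P} \right|}
#' It is zero exactly when the compositions are equal — in particular under
#' the loss of an equal proportion of biomass from every trophic group — is
#' bounded by 1, is symmetric in its arguments, and reads as the fraction of
#' total ecosystem biomass redistributed between compartments. Complete
#' ecosystem collapse (zero impacted total) is excluded.
#'
#' @param impacted,pristine \linkS4class{EcosystemSummary} objects (or named
#'   vectors/lists with components C, O, H, A).
#' @return list with elements \code{skew}, \code{impactedShares},
#'   \code{pristineShares}.
#' @export
trophicSkew <- function(impacted, pristine) {
  gI <- summaryComponents(impacted)
  gP <- summaryComponents(pristine)
  tI <- sum(gI); tP <- sum(gP)
  if (tI <= 0 || tP <= 0)
    stop("excluded scenario: total biomass is zero (complete collapse)",
         call. = FALSE)
  sI <- gI / tI; sP <- gP / tP
  list(skew = sum(abs(sI - sP)) / 2, impactedShares = sI,
       pristineShares = sP)
}

summaryComponents <- function(x) {
  if (is(x, "EcosystemSummary"))
    return(c(C = x@carnivore, O = x@omnivore, H = x@herbivore,
             A = x@autotroph))
  x <- unlist(x)
  stopifnot2(all(c("C", "O", "H", "A") %in% names(x)),
             "summary must provide components C, O, H, A")
  stopifnot2(all(x[c("C", "O", "H", "A")] >= 0),
             "biomass components must be non-negative")
  x[c("C", "O", "H", "A")]
}

#' Top-down mitigation of autotroph biomass loss
#'
#' Under a scenario of extent E and intensity i, the naive expectation — no
#' trophic effects, no regrowth dynamics — is that a fraction E x i of the
#' pristine autotroph biomass is lost, leaving
#' \eqn{(1 - E i) A_P}. Mitigation is the proportional difference between
#' the observed impacted biomass and this expectation:
#' \deqn{M = \frac{A_I}{(1 - E i) A_P} - 1} Positive values indicate more
#' autotroph biomass than naively predicted (release from herbivory);
#' negative values indicate increased herbivore pressure or failure to
#' regenerate between removals. At E = i = 1 the naive expectation is zero
#' and the scenario is excluded.
#'
#' @param aImpacted,aPristine autotroph biomass in the impacted and pristine
#'   systems, kg; aPristine must be positive.
#' @param extent,intensity scenario fractions in [0, 1] with extent x
#'   intensity < 1.
#' @return list with elements \code{mitigation}, \code{naiveExpected} (kg),
#'   \code{extent}, \code{intensity}.
#' @export
biomassMitigation <- function(aImpacted, aPristine, extent, intensity) {
  stopifnot2(aPristine > 0, "pristine autotroph biomass must be positive")
  stopifnot2(aImpacted >= 0, "impacted autotroph biomass must be >= 0")
  stopifnot2(extent >= 0 && extent <= 1 && intensity >= 0 && intensity <= 1,
             "extent and intensity must lie in [0, 1]")
  if (extent * intensity >= 1)
    stop("excluded scenario: extent x intensity = 1 (naive expectation 0)",
         call. = FALSE)
  naive <- (1 - extent * intensity) * aPristine
  list(mitigation = aImpacted / naive - 1, naiveExpected = naive,
       extent = extent, intensity = intensity)
}

#' Patch occupancy by trait class
#'
#' For scenarios that remove all plant biomass from impacted cells (100\%
#' intensity), remaining pristine cells are unambiguously the suitable
#' patches. For every trait class — trophic group crossed with a log10
#' body-mass bin — this reports the proportion of pristine cells containing
#' at least one cohort of the class whose abundance reaches the presence
#' threshold.
#'
#' @param state final \linkS4class{SimState} of a run.
#' @param pristineMask logical per cell, TRUE for unimpacted cells; must
#'   contain at least one TRUE.
#' @param presenceThreshold minimum abundance (individuals) for a cohort to
#'   count as a population (default 1).
#' @param massBinWidth width of the log10 body-mass bins, decades; use
#'   \code{NULL} for a single class per trophic group (massBin reported as
#'   NA). The default origin and width quarter the default seeded mass
#'   range (0.4 mg to 5000 kg).
#' @param massBinOrigin lower log10 edge (kg) of the first bin.
#' @return data.frame with columns trophic, massBin (lower log10 edge of
#'   the bin, as an offset from the origin), occupancy in [0, 1],
#'   nOccupied, nPristine.
#' @export
patchOccupancy <- function(state, pristineMask, presenceThreshold = 1,
                           massBinWidth = 2.6, massBinOrigin = -6.4) {
  nPristine <- sum(pristineMask)
  if (nPristine == 0)
    stop("excluded scenario: no pristine cells remain (100% extent)",
         call. = FALSE)
  co <- state@cohorts
  co <- co[co$abundance >= presenceThreshold &
             pristineMask[co$cell], , drop = FALSE]
  if (nrow(co) == 0L)
    return(data.frame(trophic = character(), massBin = numeric(),
                      occupancy = numeric(), nOccupied = integer(),
                      nPristine = integer()))
  bin <- if (is.null(massBinWidth)) rep(NA_real_, nrow(co)) else
    massBinOrigin +
    pmax(0, floor((log10(co$mass) - massBinOrigin) / massBinWidth)) *
    massBinWidth
  key <- paste(co$trophic, bin, sep = "/")
  occ <- tapply(co$cell, key, function(cells) length(unique(cells)))
  parts <- strsplit(names(occ), "/", fixed = TRUE)
  out <- data.frame(
    trophic = TROPHIC_LEVELS[as.integer(vapply(parts, `[`, "", 1))],
    massBin = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2))),
    occupancy = as.integer(occ) / nPristine,
    nOccupied = as.integer(occ), nPristine = nPristine)
  out[order(out$trophic, out$massBin), ]
}

#' Metric table for an experiment
#'
#' Computes trophic skew and mitigation for every impacted run of an
#' experiment against its paired pristine reference (same scale and
#' replicate). Total-collapse runs (zero impacted total biomass) and, for
#' mitigation, full-removal scenarios (extent = intensity = 1) are skipped
#' for the affected metric.
#'
#' @param summaries the \code{summaries} data.frame from
#'   \code{\link{runExperiment}}.
#' @return data.frame keyed by (scale, configuration, extent, intensity,
#'   replicate) with columns skew and mitigation (NA where excluded).
#' @export
metricTable <- function(summaries) {
  pris <- summaries[summaries$configuration == "pristine", ]
  imp <- summaries[summaries$configuration != "pristine", ]
  out <- imp[, c("scale", "label", "configuration", "extent", "intensity",
                 "replicate")]
  out$skew <- NA_real_
  out$mitigation <- NA_real_
  for (k in seq_len(nrow(imp))) {
    ref <- pris[pris$scale == imp$scale[k] &
                  pris$replicate == imp$replicate[k], ]
    if (nrow(ref) != 1L)
      stop("no unique pristine reference for scale ", imp$scale[k],
           " replicate ", imp$replicate[k], call. = FALSE)
    if (imp$T[k] > 0)
      out$skew[k] <- trophicSkew(
        c(C = imp$C[k], O = imp$O[k], H = imp$H[k], A = imp$A[k]),
        c(C = ref$C, O = ref$O, H = ref$H, A = ref$A))$skew
    if (imp$extent[k] * imp$intensity[k] < 1 && ref$A > 0)
      out$mitigation[k] <- biomassMitigation(
        imp$A[k], ref$A, imp$extent[k], imp$intensity[k])$mitigation
  }
  rownames(out) <- NULL
  out
}
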