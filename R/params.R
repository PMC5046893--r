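#' Ecological process parameters
#'
#' Returns the full set of constants governing the monthly ecological
#' processes, with documented defaults. Every functional form in the engine
#' reads its constants from this list, so alternative parameterizations are
#' a matter of configuration. Units are kg, km^2, and months throughout.
#'
#' Defaults are chosen so that a seeded savanna-like landscape assembles
#' into a persistent, size-structured trophic pyramid (autotrophs >>
#' herbivores >= omnivores + carnivores) within a 100-year spin-up; see the
#' package vignette for the calibration rationale.
#'
#' @param metaCoefEndo,metaCoefEcto metabolic loss coefficients, kg^(1-b) per
#'   month, for endotherms and ectotherms; endotherm cost exceeds the
#'   ectotherm baseline and is not temperature-scaled.
#' @param metaExp allometric metabolic exponent b (loss ~ m^b).
#' @param q10,refTemp Q10 temperature scaling for ectotherm metabolism and
#'   its reference temperature, degrees C.
#' @param assimEffHerbivory,assimEffPredation assimilation efficiencies in
#'   (0, 1]: fraction of removed leaf / prey biomass credited to the
#'   consumer.
#' @param herbAttack,herbExp,herbHalfSat herbivore intake: per-individual
#'   demand = herbAttack * m^herbExp * L/(L + herbHalfSat * area), with L the
#'   cell leaf pool (kg) and herbHalfSat a leaf density (kg/km^2).
#' @param predAttack,predExp,predHalfSat predator intake: same saturating
#'   form on kernel-weighted prey density (kg/km^2).
#' @param preyRefugeDensity prey biomass density (kg/km^2 per cohort) below
#'   which prey are unavailable to predators (a low-density refuge), so
#'   predation cannot extirpate rare classes locally.
#' @param optimalPreyRatio,kernelWidth log-normal prey-size preference:
#'   weight = exp(-(ln(m_prey / (phi * m_pred)))^2 / (2 sigma^2)); phi is the
#'   optimal prey:predator mass ratio, sigma the kernel width in log-e mass.
#' @param omnivoreHerbivoryWeight omnivore diet share from herbivory; the
#'   complement is taken by predation.
#' @param omnivoreEfficiency jack-of-all-trades penalty multiplying both
#'   omnivore intake channels; keeps diet generalism from strictly
#'   dominating the specialist strategies.
#' @param mortBackground background mortality rate, per month.
#' @param mortSenescenceRate senescence mortality scale; the realized rate is
#'   mortSenescenceRate * age / lifespan with lifespan = lifespanCoef *
#'   maturityMass^0.25 months.
#' @param lifespanCoef allometric lifespan coefficient, months per kg^0.25.
#' @param mortStarvation additional mortality rate while starving, per month.
#' @param mortCrowding crowding (self-limitation) mortality rate per month
#'   at the reference density; scales linearly with the cohort's trophic
#'   group's biomass density in its cell.
#' @param crowdingReference named per-trophic-group biomass densities
#'   (kg/km^2) at which crowding mortality equals mortCrowding; lower for
#'   higher trophic levels (territoriality).
#' @param hungerThreshold realized intake / metabolic requirement ratio below
#'   which a cohort counts as starving (drives starvation mortality and
#'   responsive dispersal).
#' @param massFloorFraction individual mass is never metabolised below this
#'   fraction of birth mass.
#' @param reproFraction fraction of post-maturity surplus routed to the
#'   reproductive pool.
#' @param dispersalCoef,dispersalExp dispersal radius d = dispersalCoef *
#'   m^dispersalExp, km.
#' @param natalDispersalProb probability a newly spawned cohort disperses.
#' @param responsiveDispersalProb probability a starving cohort disperses.
#' @param autotrophGrowthRate intrinsic relative growth rate of the leaf
#'   pool, per month, at reference NPP; realized rate scales linearly with
#'   the cell's NPP.
#' @param nppReference NPP at which the intrinsic growth rate applies,
#'   kg/km^2/month.
#' @param nppSensitivity exponent of the growth-rate response to relative
#'   NPP; values below 1 buffer seasonality (reserve storage).
#' @param leafAllocation fraction of autotroph growth allocated to the leaf
#'   (edible) pool; the complement goes to structural biomass.
#' @param climateMortality monthly proportional climate-driven loss from
#'   the leaf pool.
#' @param structuralTurnover monthly proportional loss from the structural
#'   pool (stem and standing-dead turnover).
#' @param carryingCapacityDensity leaf-pool carrying capacity, kg/km^2;
#'   growth is damped by (1 - L/K) with K = density * area.
#' @param grazeableFraction at most this fraction of a cell's leaf pool can
#'   be consumed by herbivory in one month (the remainder is a grazing
#'   refuge), so grazing alone never empties a cell.
#' @param deciduousShedFraction leaf fraction shed by deciduous stocks in
#'   dry-season months (months with below-annual-mean NPP).
#' @param deciduousFraction fraction of cells seeded with deciduous stocks.
#' @param initialStockFraction initial autotroph biomass as a fraction of
#'   carrying capacity.
#' @param initialDensity named vector: initial heterotroph biomass density
#'   seeded per trophic group, kg/km^2.
#' @param cohortCap maximum cohorts per cell before merging.
#' @param minAbundance cohorts below this abundance are culled.
#' @return named list of class \code{"ProcessParams"}.
#' @export
processParams <- function(
    metaCoefEndo = 0.15, metaCoefEcto = 0.05, metaExp = 0.75,
    q10 = 2, refTemp = 20,
    assimEffHerbivory = 0.4, assimEffPredation = 0.6,
    herbAttack = 0.5, herbExp = 0.7, herbHalfSat = 1e5,
    predAttack = 0.65, predExp = 0.7, predHalfSat = 5e3,
    preyRefugeDensity = 1,
    optimalPreyRatio = 0.01, kernelWidth = 1.5,
    omnivoreHerbivoryWeight = 0.5, omnivoreEfficiency = 0.7,
    mortBackground = 0.01, mortSenescenceRate = 0.05, lifespanCoef = 60,
    mortStarvation = 0.3, mortCrowding = 0.1,
    crowdingReference = c(herbivore = 5e4, omnivore = 2e4,
                          carnivore = 1e4),
    hungerThreshold = 0.6, massFloorFraction = 0.5,
    reproFraction = 0.8,
    dispersalCoef = 4, dispersalExp = 0.25,
    natalDispersalProb = 0.8, responsiveDispersalProb = 0.9,
    autotrophGrowthRate = 5, nppReference = 5e4, nppSensitivity = 0.5,
    leafAllocation = 0.95, climateMortality = 0.05,
    structuralTurnover = 0.3,
    carryingCapacityDensity = 5e5, grazeableFraction = 0.9,
    deciduousShedFraction = 0.15,
    deciduousFraction = 0.5, initialStockFraction = 0.5,
    initialDensity = c(herbivore = 4000, omnivore = 800, carnivore = 400),
    cohortCap = 64L, minAbundance = 1e-3) {
  p <- as.list(environment())
  probs <- c("assimEffHerbivory", "assimEffPredation", "mortBackground",
             "mortStarvation", "climateMortality", "reproFraction",
             "natalDispersalProb", "responsiveDispersalProb",
             "omnivoreHerbivoryWeight", "omnivoreEfficiency",
             "leafAllocation",
             "grazeableFraction", "structuralTurnover",
             "deciduousShedFraction", "deciduousFraction",
             "initialStockFraction", "massFloorFraction")
  for (nm in probs)
    stopifnot2(p[[nm]] >= 0 && p[[nm]] <= 1,
               paste0(nm, " must lie in [0, 1]"))
  stopifnot2(p$assimEffHerbivory > 0 && p$assimEffPredation > 0,
             "assimilation efficiencies must be positive")
  for (nm in c("metaExp", "herbExp", "predExp", "dispersalExp"))
    stopifnot2(is.finite(p[[nm]]), paste0(nm, " must be finite"))
  stopifnot2(p$cohortCap >= 1, "cohortCap must be >= 1")
  stopifnot2(all(p$crowdingReference > 0) &&
               all(c("herbivore", "omnivore", "carnivore") %in%
                     names(p$crowdingReference)),
             "crowdingReference must name herbivore, omnivore, carnivore")
  stopifnot2(all(p$initialDensity >= 0) &&
               all(c("herbivore", "omnivore", "carnivore") %in%
                     names(p$initialDensity)),
             "initialDensity must name herbivore, omnivore, carnivore")
  p$cohortCap <- as.integer(p$cohortCap)
  class(p) <- "ProcessParams"
  p
}
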