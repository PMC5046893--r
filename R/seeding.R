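#' Default functional-group table
#'
#' The full factorial of categorical heterotroph traits: trophic group
#' (herbivore, omnivore, carnivore) x thermoregulation (endotherm,
#' ectotherm) x reproductive strategy (iteroparous, semelparous), twelve
#' groups in all. Each group carries the admissible juvenile and adult body
#' mass ranges (kg) from which cohorts are seeded. Exclusions (e.g. no
#' semelparous endotherms) can be expressed by dropping rows.
#'
#' @param juvenileRange,adultRange numeric length-2 mass intervals, kg. The
#'   default seeding range spans 0.4 mg to 5000 kg.
#' @return data.frame with columns group, trophic, thermo, repro,
#'   juvenileMin, juvenileMax, adultMin, adultMax.
#' @export
functionalGroupTable <- function(juvenileRange = c(4e-7, 5000),
                                 adultRange = c(4e-7, 5000)) {
  stopifnot2(juvenileRange[1] > 0, "juvenile mass lower bound must be > 0")
  stopifnot2(adultRange[1] >= juvenileRange[1],
             "adult lower bound must be >= juvenile lower bound")
  g <- expand.grid(trophic = TROPHIC_LEVELS, thermo = THERMO_LEVELS,
                   repro = REPRO_LEVELS, stringsAsFactors = FALSE)
  data.frame(group = seq_len(nrow(g)), g,
             juvenileMin = juvenileRange[1], juvenileMax = juvenileRange[2],
             adultMin = adultRange[1], adultMax = adultRange[2])
}

#' Seed an initial model state
#'
#' Builds the initial \linkS4class{SimState}: per-cell autotroph stocks at a
#' configured fraction of carrying capacity, and, for every functional
#' group, \code{nCohortsPerCell} cohorts per cell with maturity masses drawn
#' log-uniformly from the group's adult range and birth masses drawn
#' log-uniformly between the juvenile lower bound and the maturity mass.
#' Cohorts start as adults (current mass = maturity mass). Initial
#' abundances follow a Damuth-like allometry, N proportional to m^-0.75,
#' rescaled within each cell and trophic group so that seeded biomass
#' density matches \code{params$initialDensity}.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param groupTable functional-group table from
#'   \code{\link{functionalGroupTable}}.
#' @param nCohortsPerCell cohorts seeded per functional group per cell.
#' @param params a \code{\link{processParams}} list (stock initialization
#'   and density constants).
#' @param seed integer seed; seeding is deterministic given the seed.
#' @return a \linkS4class{SimState} at month 0.
#' @export
seedCohorts <- function(landscape, groupTable = functionalGroupTable(),
                        nCohortsPerCell = 3L, params = processParams(),
                        seed = 1L) {
  stopifnot2(nrow(groupTable) > 0 || nCohortsPerCell == 0L,
             "groupTable must be non-empty")
  stopifnot2(nCohortsPerCell >= 0, "nCohortsPerCell must be >= 0")
  nc <- nCells(landscape)

  withSeed(seed, {
    ## autotroph stocks: strategy per cell, biomass at a fraction of K
    strat <- ifelse(runif(nc) < params$deciduousFraction, 1L, 2L)
    B0 <- params$initialStockFraction * params$carryingCapacityDensity *
      landscape@cellArea
    stocksDf <- data.frame(
      cell = seq_len(nc),
      leaf = params$leafAllocation * B0,
      structural = (1 - params$leafAllocation) * B0,
      strategy = strat)

    if (nCohortsPerCell == 0L || nrow(groupTable) == 0L) {
      co <- emptyCohorts()
    } else {
      n <- nc * nrow(groupTable) * nCohortsPerCell
      cell <- rep(seq_len(nc), each = nrow(groupTable) * nCohortsPerCell)
      gi <- rep(rep(seq_len(nrow(groupTable)), each = nCohortsPerCell),
                times = nc)
      maturity <- exp(runif(n, log(groupTable$adultMin[gi]),
                            log(groupTable$adultMax[gi])))
      birth <- exp(runif(n, log(groupTable$juvenileMin[gi]),
                         log(pmin(maturity, groupTable$juvenileMax[gi]))))
      trophic <- match(groupTable$trophic[gi], TROPHIC_LEVELS)
      ## Damuth-like N ~ m^-0.75, rescaled per (cell, trophic) to the target
      ## biomass density
      raw <- maturity^(-0.75)
      target <- params$initialDensity[TROPHIC_LEVELS[trophic]] *
        landscape@cellArea[cell]
      key <- paste(cell, trophic)
      groupBio <- tapply(raw * maturity, key, sum)
      abundance <- raw * target / as.numeric(groupBio[key])
      co <- data.frame(
        group = groupTable$group[gi],
        trophic = trophic,
        thermo = match(groupTable$thermo[gi], THERMO_LEVELS),
        repro = match(groupTable$repro[gi], REPRO_LEVELS),
        mass = maturity, birthMass = birth, maturityMass = maturity,
        abundance = abundance, reproPool = 0,
        cell = cell, age = 0, hunger = 1, natal = FALSE)
    }

    new("SimState", cohorts = co, stocks = stocksDf,
        landscape = landscape, month = 0L)
  })
}

emptyCohorts <- function() {
  data.frame(group = integer(), trophic = integer(), thermo = integer(),
             repro = integer(), mass = numeric(), birthMass = numeric(),
             maturityMass = numeric(), abundance = numeric(),
             reproPool = numeric(), cell = integer(), age = numeric(),
             hunger = numeric(), natal = logical())
}
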