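## Shared tiny fixtures, built in code.

tinyLandscape <- function(nRows = 3L, nCols = 3L, cellSize = 0.1) {
  makeLandscape(nRows, nCols, cellSize, centre = c(0.05, 38))
}

tinyEnvironment <- function(land = tinyLandscape(), seed = 7L, ...) {
  generateEnvironment(land, savannaParams(...), seed = seed)
}

## flat environment: no seasonality, no spatial noise
flatEnvironment <- function(land, meanNpp = 5e4, meanTemperature = 20) {
  generateEnvironment(
    land, savannaParams(meanTemperature = meanTemperature,
                        temperatureAmplitude = 0, meanNpp = meanNpp,
                        nppSeasonalAmplitude = 0, spatialNoise = 0),
    seed = 1L)
}

## a one-row cohort table with sensible defaults, overridable per field
makeCohort <- function(trophic = 1L, thermo = 1L, repro = 1L,
                       mass = 10, birthMass = 1, maturityMass = 10,
                       abundance = 100, reproPool = 0, cell = 1L,
                       age = 0, hunger = 1, natal = FALSE, group = 1L) {
  data.frame(group = group, trophic = trophic, thermo = thermo,
             repro = repro, mass = mass, birthMass = birthMass,
             maturityMass = maturityMass, abundance = abundance,
             reproPool = reproPool, cell = cell, age = age,
             hunger = hunger, natal = natal)
}

tinyStocks <- function(land = tinyLandscape(), leaf = 1e6,
                       structural = 1e6, strategy = 2L) {
  n <- nCells(land)
  data.frame(cell = seq_len(n), leaf = rep_len(leaf, n),
             structural = rep_len(structural, n),
             strategy = rep_len(strategy, n))
}

tinyState <- function(co, st = NULL, land = tinyLandscape(), month = 0L) {
  if (is.null(st)) st <- tinyStocks(land)
  new("SimState", cohorts = co, stocks = st, landscape = land,
      month = as.integer(month))
}

totalBiomass <- function(state) {
  unname(trophicTotals(state)[["total"]])
}
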