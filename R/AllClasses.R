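#' @import methods
NULL

## Categorical trait levels used throughout. Cohort tables store integer codes
## into these vectors; I/O converts to labels.
TROPHIC_LEVELS <- c("herbivore", "omnivore", "carnivore")
THERMO_LEVELS  <- c("endotherm", "ectotherm")
REPRO_LEVELS   <- c("iteroparous", "semelparous")
LEAF_LEVELS    <- c("deciduous", "evergreen")

#' Bounded rectangular landscape grid
#'
#' A closed (no-flux) rectangular grid of habitat cells centred on a
#' geographic coordinate. Cell areas come from spherical-Earth geometry, so
#' rows at different latitudes have slightly different areas. Linear cell
#' indices are 1-based and row-major, with cell 1 in the north-west corner.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot cellSize cell edge length, degrees.
#' @slot centre numeric length-2, (latitude, longitude) of the grid centre,
#'   degrees.
#' @slot cellArea numeric vector, one area per cell, km^2, row-major.
#' @slot cellX,cellY numeric vectors of cell-centre planar coordinates, km,
#'   used for dispersal distances (local tangent-plane approximation).
#' @exportClass Landscape
setClass("Landscape", representation(
  nRows = "integer", nCols = "integer",
  cellSize = "numeric", centre = "numeric",
  cellArea = "numeric", cellX = "numeric", cellY = "numeric"
))

setValidity("Landscape", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "grid dimensions must be >= 1")
  if (length(object@cellArea) != object@nRows * object@nCols)
    msg <- c(msg, "cellArea length must equal nRows * nCols")
  if (any(object@cellArea <= 0))
    msg <- c(msg, "all cell areas must be positive")
  if (length(object@centre) != 2L || abs(object@centre[1]) >= 90)
    msg <- c(msg, "centre must be (lat, lon) with |lat| < 90")
  if (length(msg)) msg else TRUE
})

#' Monthly abiotic environment on a landscape
#'
#' Twelve calendar months of temperature and net primary productivity per
#' cell, recycled annually. Generated synthetically (seasonal sinusoid plus
#' smooth spatial noise) as a stand-in for observed climate drivers.
#'
#' @slot temperature 12 x nCells matrix, degrees C.
#' @slot npp 12 x nCells matrix, kg biomass per km^2 per month; non-negative.
#' @slot params named list of the seasonality parameters used.
#' @slot seed integer seed the surfaces were generated from.
#' @exportClass EnvironmentGrid
setClass("EnvironmentGrid", representation(
  temperature = "matrix", npp = "matrix",
  params = "list", seed = "integer"
))

setValidity("EnvironmentGrid", function(object) {
  msg <- character()
  if (nrow(object@temperature) != 12L || nrow(object@npp) != 12L)
    msg <- c(msg, "temperature and npp must have 12 rows (calendar months)")
  if (!all(is.finite(object@temperature)))
    msg <- c(msg, "temperature must be finite")
  if (any(object@npp < 0) || !all(is.finite(object@npp)))
    msg <- c(msg, "npp must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' One land-use treatment
#'
#' A spatial configuration (random, continuous, or pristine), an extent (the
#' fraction of cells impacted), an intensity (the fraction of autotroph
#' biomass removed from each impacted cell at every monthly step), and the
#' realized impacted-cell mask.
#'
#' @slot configuration one of "random", "continuous", "pristine".
#' @slot extent fraction of cells impacted, in [0, 1].
#' @slot intensity fraction of autotroph biomass removed per step, in [0, 1].
#' @slot mask logical vector, one flag per cell (TRUE = impacted).
#' @slot label short unique treatment label.
#' @exportClass Treatment
setClass("Treatment", representation(
  configuration = "character", extent = "numeric",
  intensity = "numeric", mask = "logical", label = "character"
))

setValidity("Treatment", function(object) {
  msg <- character()
  if (!object@configuration %in% c("random", "continuous", "pristine"))
    msg <- c(msg, "configuration must be random, continuous or pristine")
  if (object@extent < 0 || object@extent > 1 ||
      object@intensity < 0 || object@intensity > 1)
    msg <- c(msg, "extent and intensity must lie in [0, 1]")
  if ((object@configuration == "pristine") != (object@extent == 0))
    msg <- c(msg, "pristine configuration iff extent 0")
  if (length(object@mask) &&
      sum(object@mask) != roundHalfUp(object@extent * length(object@mask)))
    msg <- c(msg, "mask cardinality must equal round(extent * n_cells)")
  if (length(msg)) msg else TRUE
})

#' Full simulator state
#'
#' Heterotroph cohorts (one row each), per-cell autotroph stocks, the
#' landscape, and the current month. Cohort categorical traits are stored as
#' integer codes into the package's trait level sets; see
#' \code{\link{cohorts}} for the decoded table.
#'
#' @slot cohorts data.frame with columns group (functional-group id), trophic,
#'   thermo, repro (integer trait codes), mass, birthMass, maturityMass (kg
#'   per individual), abundance (individuals, non-negative real), reproPool
#'   (kg per individual), cell (1-based linear index), age (months), hunger
#'   (last realized intake/requirement ratio), natal (logical, spawned this
#'   step).
#' @slot stocks data.frame with columns cell, leaf, structural (kg per cell),
#'   strategy (integer code: deciduous/evergreen).
#' @slot landscape the \linkS4class{Landscape}.
#' @slot month integer month counter (0 at seeding).
#' @exportClass SimState
setClass("SimState", representation(
  cohorts = "data.frame", stocks = "data.frame",
  landscape = "Landscape", month = "integer"
))

setValidity("SimState", function(object) {
  v <- validateState(object)
  if (length(v)) paste(v, collapse = "; ") else TRUE
})

#' Factorial experiment plan
#'
#' The full design for a habitat loss and fragmentation experiment: the
#' factor levels, replication, landscape specification, phase durations, and
#' base seed. The default construction is the full-scale factorial
#' design (4 extents x 4 intensities x 2 configurations, deduplicated at
#' full extent, plus a pristine control = 29 treatments; 10 replicates; two
#' landscape scales; 1200 + 1200 months); the desk preset scales the plan
#' down for interactive use.
#'
#' @slot extents,intensities numeric factor levels, fractions in (0, 1].
#' @slot configurations character subset of c("random", "continuous").
#' @slot replicates integer number of replicate runs per treatment.
#' @slot scales list of landscape specs (each a list with nRows, nCols,
#'   cellSize, centre, label).
#' @slot burnInMonths,impactMonths,recordWindowMonths integer phase lengths.
#' @slot baseSeed integer seed from which all run seeds are derived.
#' @slot engine list of engine settings (process parameters, environment
#'   parameters, seeding settings) shared by all runs.
#' @exportClass ExperimentPlan
setClass("ExperimentPlan", representation(
  extents = "numeric", intensities = "numeric", configurations = "character",
  replicates = "integer", scales = "list",
  burnInMonths = "integer", impactMonths = "integer",
  recordWindowMonths = "integer", baseSeed = "integer", engine = "list"
))

setValidity("ExperimentPlan", function(object) {
  msg <- character()
  fr <- c(object@extents, object@intensities)
  if (any(fr <= 0 | fr > 1))
    msg <- c(msg, "extents and intensities must lie in (0, 1]")
  if (object@recordWindowMonths > object@impactMonths)
    msg <- c(msg, "recordWindowMonths must not exceed impactMonths")
  if (object@replicates < 1L)
    msg <- c(msg, "replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Per-run ecosystem summary
#'
#' Landscape-total biomasses by trophic compartment, averaged over the
#' recorded window of a run: carnivore (C), omnivore (O), herbivore (H),
#' autotroph (A) and their total (T), in kg, plus scenario metadata.
#'
#' @slot carnivore,omnivore,herbivore,autotroph,total biomasses, kg.
#' @slot meta named list of scenario metadata (scale, configuration, extent,
#'   intensity, replicate, seed).
#' @exportClass EcosystemSummary
setClass("EcosystemSummary", representation(
  carnivore = "numeric", omnivore = "numeric", herbivore = "numeric",
  autotroph = "numeric", total = "numeric", meta = "list"
))

setValidity("EcosystemSummary", function(object) {
  comp <- c(object@carnivore, object@omnivore, object@herbivore,
            object@autotroph)
  msg <- character()
  if (any(comp < 0)) msg <- c(msg, "biomass components must be non-negative")
  if (abs(object@total - sum(comp)) >
      1e-9 * max(1, abs(object@total)))
    msg <- c(msg, "total must equal the component sum")
  if (length(msg)) msg else TRUE
})

#' @describeIn Landscape-class construct an EcosystemSummary (helper).
#' @param C,O,H,A carnivore, omnivore, herbivore, autotroph biomass, kg.
#' @param meta named list of scenario metadata.
#' @export
ecosystemSummary <- function(C, O, H, A, meta = list()) {
  new("EcosystemSummary", carnivore = C, omnivore = O, herbivore = H,
      autotroph = A, total = C + O + H + A, meta = meta)
}

setMethod("show", "Landscape", function(object) {
  cat(sprintf("Landscape: %d x %d cells of %g deg, centre (%g, %g)\n",
              object@nRows, object@nCols, object@cellSize,
              object@centre[1], object@centre[2]))
  cat(sprintf("  total area %.4g km^2 (cells %.4g-%.4g km^2), closed boundary\n",
              sum(object@cellArea), min(object@cellArea), max(object@cellArea)))
})

setMethod("show", "SimState", function(object) {
  cat(sprintf("SimState: month %d, %d cohorts on %d cells\n",
              object@month, nrow(object@cohorts), nCells(object@landscape)))
  tot <- trophicTotals(object)
  cat(sprintf("  biomass (kg): A %.4g | H %.4g | O %.4g | C %.4g\n",
              tot[["autotroph"]], tot[["herbivore"]],
              tot[["omnivore"]], tot[["carnivore"]]))
})

setMethod("show", "Treatment", function(object) {
  cat(sprintf("Treatment %s: %s, extent %d%%, intensity %d%% (%d cells masked)\n",
              object@label, object@configuration,
              round(100 * object@extent), round(100 * object@intensity),
              sum(object@mask)))
})

setMethod("show", "ExperimentPlan", function(object) {
  cat(sprintf(
    "ExperimentPlan: %d treatments x %d replicates x %d scale(s) = %d runs\n",
    nrow(enumerateTreatments(object@extents, object@intensities,
                             object@configurations)),
    object@replicates, length(object@scales), planSize(object)))
  cat(sprintf("  burn-in %d months, impact %d months, record window %d months\n",
              object@burnInMonths, object@impactMonths,
              object@recordWindowMonths))
})

setMethod("show", "EcosystemSummary", function(object) {
  cat("EcosystemSummary (kg, window means):\n")
  cat(sprintf("  C %.4g | O %.4g | H %.4g | A %.4g | T %.4g\n",
              object@carnivore, object@omnivore, object@herbivore,
              object@autotroph, object@total))
})
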