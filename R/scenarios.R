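#' Enumerate the factorial treatment set
#'
#' Crosses spatial configuration, extent, and intensity into the full
#' treatment table, deduplicating configurations at 100\% extent (where the
#' random and continuous masks are identical: every cell) and adding exactly
#' one pristine control. With the default four extents, four intensities,
#' and both configurations this yields 29 treatments: 4 intensities x (3
#' partial extents x 2 configurations + 1 full extent) + 1 pristine.
#' Ordering is canonical and stable: pristine first, then by configuration,
#' extent, intensity.
#'
#' @param extents,intensities numeric fractions in (0, 1].
#' @param configurations character subset of c("random", "continuous").
#' @return data.frame with columns label, configuration, extent, intensity.
#' @export
enumerateTreatments <- function(extents = c(0.25, 0.5, 0.75, 1),
                                intensities = c(0.25, 0.5, 0.75, 1),
                                configurations = c("random", "continuous")) {
  stopifnot2(length(extents) > 0 && length(intensities) > 0,
             "extents and intensities must be non-empty")
  stopifnot2(all(extents > 0 & extents <= 1) &&
               all(intensities > 0 & intensities <= 1),
             "extents and intensities must lie in (0, 1]")
  stopifnot2(all(configurations %in% c("random", "continuous")),
             "configurations must be 'random' and/or 'continuous'")
  g <- expand.grid(intensity = sort(unique(intensities)),
                   extent = sort(unique(extents)),
                   configuration = sort(unique(configurations)),
                   stringsAsFactors = FALSE)
  ## at full extent the mask is all cells for either configuration
  g <- g[!duplicated(paste(g$intensity, g$extent,
                           ifelse(g$extent == 1, "full", g$configuration))), ]
  g <- g[order(g$configuration, g$extent, g$intensity), ]
  out <- rbind(
    data.frame(configuration = "pristine", extent = 0, intensity = 0),
    g[, c("configuration", "extent", "intensity")])
  out$label <- ifelse(
    out$configuration == "pristine", "pristine",
    sprintf("%s%02d_i%02d", substr(out$configuration, 1, 1),
            round(100 * out$extent), round(100 * out$intensity)))
  rownames(out) <- NULL
  out[, c("label", "configuration", "extent", "intensity")]
}

#' Select impacted cells for a treatment
#'
#' Random configuration: a seeded uniform sample without replacement of
#' round(extent x nCells) cells (fragmenting). Continuous configuration:
#' cells fill in row-major order starting from the first (northern) row
#' until the quota is met, keeping impacted and pristine habitat each
#' unbroken. A non-integral quota is rounded half up with a warning.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param extent fraction of cells in [0, 1].
#' @param configuration "random", "continuous", or "pristine".
#' @param seed optional integer seed for the random draw.
#' @return logical mask, one flag per cell (TRUE = impacted).
#' @export
selectImpactedCells <- function(landscape, extent, configuration,
                                seed = NULL) {
  nc <- nCells(landscape)
  stopifnot2(extent >= 0 && extent <= 1, "extent must lie in [0, 1]")
  quota <- extent * nc
  if (abs(quota - round(quota)) > 1e-9) {
    warning("non-integral impacted-cell quota; rounding half up")
  }
  quota <- roundHalfUp(quota)
  mask <- logical(nc)
  if (quota == 0 || configuration == "pristine") return(mask)
  if (configuration == "continuous") {
    mask[seq_len(quota)] <- TRUE
  } else if (configuration == "random") {
    mask[withSeed(seed, sample.int(nc, quota))] <- TRUE
  } else stop("unknown configuration: ", configuration, call. = FALSE)
  mask
}

#' Build a Treatment object
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param configuration,extent,intensity treatment factors.
#' @param seed optional seed for random masks.
#' @param label optional label (defaults to a canonical one).
#' @return a \linkS4class{Treatment}.
#' @export
makeTreatment <- function(landscape, configuration, extent, intensity,
                          seed = NULL, label = NULL) {
  mask <- selectImpactedCells(landscape, extent, configuration, seed)
  if (is.null(label))
    label <- if (configuration == "pristine") "pristine" else
      sprintf("%s%02d_i%02d", substr(configuration, 1, 1),
              round(100 * extent), round(100 * intensity))
  new("Treatment", configuration = configuration, extent = extent,
      intensity = intensity, mask = mask, label = label)
}

#' Apply one month of land-use impact
#'
#' Removes the treatment's intensity fraction of autotroph biomass from
#' every impacted cell and reports the removed mass. By default the debit
#' falls proportionally on the leaf and structural pools ("total" mode);
#' "leaf" mode removes from the leaf pool only. Heterotrophs are never
#' debited directly.
#'
#' @param state a \linkS4class{SimState}.
#' @param mask logical impacted-cell mask.
#' @param intensity fraction of autotroph biomass removed, in [0, 1].
#' @param pools which autotroph pools the removal debits.
#' @return list(state, removed, removedPerCell) with removals in kg.
#' @export
applyImpact <- function(state, mask, intensity,
                        pools = c("total", "leaf")) {
  stopifnot2(intensity >= 0 && intensity <= 1,
             "intensity must lie in [0, 1]")
  pools <- match.arg(pools)
  st <- state@stocks
  perCell <- numeric(nrow(st))
  if (any(mask) && intensity > 0) {
    if (pools == "total") {
      perCell[mask] <- intensity * (st$leaf[mask] + st$structural[mask])
      st$leaf[mask] <- st$leaf[mask] * (1 - intensity)
      st$structural[mask] <- st$structural[mask] * (1 - intensity)
    } else {
      perCell[mask] <- intensity * st$leaf[mask]
      st$leaf[mask] <- st$leaf[mask] * (1 - intensity)
    }
    state@stocks <- st
  }
  list(state = state, removed = sum(perCell), removedPerCell = perCell)
}

#' Run a simulation phase
#'
#' Advances a state month by month, optionally applying a land-use
#' treatment's biomass removal at the start of each month (so a 100\%
#' intensity cell starts every month empty), and records landscape totals
#' by trophic compartment after every month. Uses the current RNG stream:
#' call \code{set.seed} first for a reproducible trajectory.
#'
#' @param state a \linkS4class{SimState}.
#' @param env an \linkS4class{EnvironmentGrid}.
#' @param params a \code{\link{processParams}} list.
#' @param months number of monthly steps.
#' @param treatment optional \linkS4class{Treatment}.
#' @return list(state, records, removal, ledgers): records is a months x 5
#'   matrix (herbivore, omnivore, carnivore, autotroph, total, kg, end of
#'   month); removal the per-month removed biomass (kg); ledgers the
#'   per-month mass ledgers (months x entries).
#' @export
runSimulation <- function(state, env, params = processParams(),
                          months = 12L, treatment = NULL) {
  months <- as.integer(months)
  records <- matrix(NA_real_, months, 5,
                    dimnames = list(NULL, c("herbivore", "omnivore",
                                            "carnivore", "autotroph",
                                            "total")))
  removal <- numeric(months)
  ledgers <- NULL
  for (m in seq_len(months)) {
    if (!is.null(treatment) && treatment@intensity > 0) {
      imp <- applyImpact(state, treatment@mask, treatment@intensity)
      state <- imp$state
      removal[m] <- imp$removed
    }
    stp <- stepMonth(state, env, params)
    state <- stp$state
    if (is.null(ledgers))
      ledgers <- matrix(NA_real_, months, length(stp$ledger),
                        dimnames = list(NULL, names(stp$ledger)))
    ledgers[m, ] <- stp$ledger
    records[m, ] <- trophicTotals(state)
  }
  list(state = state, records = records, removal = removal,
       ledgers = ledgers)
}

#' Construct an experiment plan
#'
#' Two presets ship. \code{"paper"} is the full-scale factorial:
#' 29 treatments x 10 replicates x 2 landscape scales (10 x 10 grids of 0.1
#' and 0.01 degree cells) with a 1200-month burn-in, 1200-month impact
#' phase, and a 120-month recording window — 580 runs, hours of compute.
#' \code{"desk"} is the interactive/test preset: one 5 x 5 grid of 0.1
#' degree cells, 240 + 240 months, a 36-month window, 3 replicates — 87
#' runs in minutes.
#'
#' @param preset "desk" or "paper".
#' @param baseSeed integer seed from which all run seeds are derived.
#' @param ... overrides for any slot (extents, intensities, configurations,
#'   replicates, scales, burnInMonths, impactMonths, recordWindowMonths,
#'   engine).
#' @return an \linkS4class{ExperimentPlan}.
#' @export
experimentPlan <- function(preset = c("desk", "paper"), baseSeed = 1L, ...) {
  preset <- match.arg(preset)
  def <- list(
    extents = c(0.25, 0.5, 0.75, 1),
    intensities = c(0.25, 0.5, 0.75, 1),
    configurations = c("random", "continuous"),
    engine = list(params = processParams(), envParams = savannaParams(),
                  nCohortsPerCell = 2L))
  if (preset == "paper") {
    def <- c(def, list(
      replicates = 10L,
      scales = list(
        list(label = "large", nRows = 10L, nCols = 10L, cellSize = 0.1,
             centre = c(0.05, 38.00)),
        list(label = "small", nRows = 10L, nCols = 10L, cellSize = 0.01,
             centre = c(0.05, 38.00))),
      burnInMonths = 1200L, impactMonths = 1200L,
      recordWindowMonths = 120L))
    def$engine$nCohortsPerCell <- 3L
  } else {
    def <- c(def, list(
      replicates = 3L,
      scales = list(
        list(label = "desk", nRows = 5L, nCols = 5L, cellSize = 0.1,
             centre = c(0.05, 38.00))),
      burnInMonths = 240L, impactMonths = 240L,
      recordWindowMonths = 36L))
  }
  ov <- list(...)
  def[names(ov)] <- ov
  new("ExperimentPlan",
      extents = def$extents, intensities = def$intensities,
      configurations = def$configurations,
      replicates = as.integer(def$replicates), scales = def$scales,
      burnInMonths = as.integer(def$burnInMonths),
      impactMonths = as.integer(def$impactMonths),
      recordWindowMonths = as.integer(def$recordWindowMonths),
      baseSeed = as.integer(baseSeed), engine = def$engine)
}

#' Number of runs in a plan
#' @param plan an \linkS4class{ExperimentPlan}.
#' @return integer: treatments x replicates x scales.
#' @export
planSize <- function(plan) {
  nrow(enumerateTreatments(plan@extents, plan@intensities,
                           plan@configurations)) *
    plan@replicates * length(plan@scales)
}

#' Run a full factorial experiment
#'
#' For each landscape scale and replicate, seeds an ecosystem and runs the
#' unimpacted burn-in once; every treatment of that replicate (including
#' the pristine control) then starts from the identical end-of-burn-in
#' state, making the pristine run a paired reference. Each impact phase
#' applies the treatment's removal at the start of every month. Summaries
#' average the landscape totals over the recording window (the final months
#' of the impact phase). For 100\%-intensity treatments with surviving
#' pristine cells, patch occupancy by trait class is computed from the
#' final state.
#'
#' All randomness derives from the plan's base seed via a documented hash
#' of (scale, replicate, treatment), so identical plans give identical
#' results.
#'
#' @param plan an \linkS4class{ExperimentPlan}.
#' @param verbose print per-run progress lines.
#' @return list with elements \code{summaries} (one row per run: scenario
#'   metadata, window-mean biomasses C, O, H, A, T in kg, and total removed
#'   biomass), \code{occupancy} (long table of per-class patch occupancy for
#'   100\%-intensity runs), and \code{plan}.
#' @export
runExperiment <- function(plan, verbose = FALSE) {
  treatments <- enumerateTreatments(plan@extents, plan@intensities,
                                    plan@configurations)
  eng <- plan@engine
  params <- eng$params
  groupTable <- if (is.null(eng$groupTable)) functionalGroupTable() else
    eng$groupTable
  sumRows <- list()
  occRows <- list()
  for (si in seq_along(plan@scales)) {
    sc <- plan@scales[[si]]
    land <- makeLandscape(sc$nRows, sc$nCols, sc$cellSize, sc$centre)
    env <- generateEnvironment(land, eng$envParams,
                               seed = deriveSeed(plan@baseSeed, si, 7L))
    for (r in seq_len(plan@replicates)) {
      state0 <- seedCohorts(land, groupTable, eng$nCohortsPerCell, params,
                            seed = deriveSeed(plan@baseSeed, si, 2L, r))
      burnSeed <- deriveSeed(plan@baseSeed, si, 1L, r)
      set.seed(burnSeed)
      burn <- runSimulation(state0, env, params, plan@burnInMonths)
      for (ti in seq_len(nrow(treatments))) {
        tr <- treatments[ti, ]
        runSeed <- deriveSeed(plan@baseSeed, si, 3L, r, ti)
        treatment <- makeTreatment(
          land, tr$configuration, tr$extent, tr$intensity,
          seed = deriveSeed(plan@baseSeed, si, 4L, r, ti),
          label = tr$label)
        set.seed(runSeed)
        res <- tryCatch(
          runSimulation(burn$state, env, params, plan@impactMonths,
                        treatment),
          error = function(e) {
            warning(sprintf("run failed (%s, rep %d, %s): %s",
                            sc$label, r, tr$label, conditionMessage(e)))
            NULL
          })
        if (is.null(res)) next
        win <- seq(plan@impactMonths - plan@recordWindowMonths + 1L,
                   plan@impactMonths)
        m <- colMeans(res$records[win, , drop = FALSE])
        sumRows[[length(sumRows) + 1L]] <- data.frame(
          scale = sc$label, label = tr$label,
          configuration = tr$configuration, extent = tr$extent,
          intensity = tr$intensity, replicate = r, seed = runSeed,
          C = m[["carnivore"]], O = m[["omnivore"]], H = m[["herbivore"]],
          A = m[["autotroph"]], T = m[["total"]],
          removed = sum(res$removal))
        if (tr$intensity == 1 && tr$extent < 1) {
          ## body-mass-binned classes plus whole-trophic-group classes
          ## (massBin NA)
          occ <- rbind(
            patchOccupancy(res$state, !treatment@mask),
            patchOccupancy(res$state, !treatment@mask,
                           massBinWidth = NULL))
          if (nrow(occ)) {
            occ <- cbind(data.frame(scale = sc$label, label = tr$label,
                                    configuration = tr$configuration,
                                    extent = tr$extent,
                                    intensity = tr$intensity,
                                    replicate = r), occ)
            occRows[[length(occRows) + 1L]] <- occ
          }
        }
        if (verbose)
          message(sprintf("%s rep %d %s: A=%.3g H=%.3g O=%.3g C=%.3g",
                          sc$label, r, tr$label, m[["autotroph"]],
                          m[["herbivore"]], m[["omnivore"]],
                          m[["carnivore"]]))
      }
    }
  }
  list(summaries = do.call(rbind, sumRows),
       occupancy = if (length(occRows)) do.call(rbind, occRows) else NULL,
       plan = plan)
}
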