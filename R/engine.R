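## The monthly ecology engine.
##
## All sub-processes operate on the cohort table (one row per cohort; a
## "single cohort" is a one-row table) and/or the per-cell stock table, and
## return an itemized mass ledger (kg) so every monthly step can be audited
## for conservation. Transient per-individual assimilate gained while eating
## is carried in an `assim` column until growth allocates it; individuals
## killed or dying mid-month carry their share, which the ledger values.

#' Autotroph growth, climate mortality, and leaf shedding
#'
#' One month of plant production. Growth is proportional to standing leaf
#' biomass — photosynthesis happens in leaves — at a rate scaled by the
#' cell's NPP relative to the reference NPP (sublinearly, reflecting
#' reserve buffering of seasonality), and damped logistically toward
#' the cell's leaf carrying capacity: growth = r x
#' (npp/nppRef)^sensitivity x L x max(0, 1 - L/K). A stock at or above capacity therefore gains nothing,
#' and a cell whose leaf pool has been driven to zero (total removal) stays
#' bare until the pressure ends. Growth is split between the leaf and
#' structural pools by the allocation fraction; both pools then suffer
#' proportional climate-driven mortality, and deciduous stocks shed a
#' configured fraction of leaf biomass in dry-season months.
#'
#' @param stocks stock table (cell, leaf, structural, strategy).
#' @param npp per-cell NPP this month, kg/km^2/month.
#' @param cellArea per-cell areas, km^2.
#' @param dry logical per cell: is this a dry-season month (below
#'   annual-mean NPP)?
#' @param params a \code{\link{processParams}} list.
#' @return list(stocks, ledger) with ledger entries nppInput, climateLoss,
#'   shedLoss (kg).
#' @export
autotrophGrowth <- function(stocks, npp, cellArea, dry = FALSE, params = processParams()) {
  K <- params$carryingCapacityDensity * cellArea
  growth <- params$autotrophGrowthRate *
    (npp / params$nppReference)^params$nppSensitivity *
    stocks$leaf * pmax(0, 1 - stocks$leaf / K)
  leaf <- stocks$leaf + params$leafAllocation * growth
  structural <- stocks$structural + (1 - params$leafAllocation) * growth

  climateLoss <- params$climateMortality * leaf +
    params$structuralTurnover * structural
  leaf <- leaf * (1 - params$climateMortality)
  structural <- structural * (1 - params$structuralTurnover)

  shed <- ifelse(rep_len(dry, length(leaf)) & stocks$strategy == 1L,
                 params$deciduousShedFraction * leaf, 0)
  leaf <- leaf - shed

  stocks$leaf <- leaf
  stocks$structural <- structural
  list(stocks = stocks,
       ledger = c(nppInput = sum(growth), climateLoss = sum(climateLoss),
                  shedLoss = sum(shed)))
}

## log-normal prey-size preference weight; maximal when
## m_prey = optimalPreyRatio * m_pred
preyKernel <- function(preyMass, predMass, params) {
  exp(-(log(preyMass / (params$optimalPreyRatio * predMass)))^2 /
        (2 * params$kernelWidth^2))
}

#' Eating: herbivory and predation within cells
#'
#' Herbivores (and omnivores, by their diet weight) remove leaf biomass with
#' a saturating per-individual intake; when cell-level demand exceeds the
#' leaf pool, intake is rationed proportionally so the pool never goes
#' negative. Carnivores (and omnivores) kill prey-cohort biomass weighted by
#' a log-normal size-preference kernel centred on the optimal prey mass,
#' again rationed so no prey cohort is over-killed; kills reduce prey
#' abundance, and intake times assimilation efficiency is credited to the
#' consumer's transient assimilate store.
#'
#' @param co cohort table (all cells; eating is resolved cell by cell).
#' @param stocks stock table.
#' @param cellArea per-cell areas, km^2.
#' @param params a \code{\link{processParams}} list.
#' @return list(cohorts, stocks, ledger) where cohorts gains an
#'   \code{assim} column (kg per individual) and ledger itemizes herbDebit,
#'   herbAssim, predDebit, predAssim (kg).
#' @export
eat <- function(co, stocks, cellArea, params = processParams()) {
  n <- nrow(co)
  assim <- numeric(n)
  ledger <- c(herbDebit = 0, herbAssim = 0, predDebit = 0, predAssim = 0)
  if (n == 0L) {
    co$assim <- numeric(0)
    return(list(cohorts = co, stocks = stocks, ledger = ledger))
  }

  N <- co$abundance
  area <- cellArea[co$cell]

  ## ---- herbivory (cell-aggregated, vectorized) ----
  hw <- numeric(n)
  hw[co$trophic == 1L] <- 1
  hw[co$trophic == 2L] <- params$omnivoreEfficiency *
    params$omnivoreHerbivoryWeight
  leafDens <- stocks$leaf / cellArea
  sat <- leafDens / (leafDens + params$herbHalfSat)
  demand <- hw * params$herbAttack * co$mass^params$herbExp *
    sat[co$cell] * N
  cellDemand <- rowsum(demand, co$cell, reorder = FALSE)
  dcells <- as.integer(rownames(cellDemand))
  ration <- rep(1, nrow(stocks))
  pos <- cellDemand[, 1] > 0
  ration[dcells[pos]] <- pmin(1, params$grazeableFraction *
                                stocks$leaf[dcells[pos]] /
                                cellDemand[pos, 1])
  intake <- demand * ration[co$cell]
  stocks$leaf <- stocks$leaf - tapplySum(intake, co$cell, nrow(stocks))
  posN <- N > 0
  assim[posN] <- assim[posN] +
    intake[posN] * params$assimEffHerbivory / N[posN]
  ledger["herbDebit"] <- sum(intake)
  ledger["herbAssim"] <- sum(intake) * params$assimEffHerbivory

  ## ---- predation (per cell) ----
  pw <- numeric(n)
  pw[co$trophic == 3L] <- 1
  pw[co$trophic == 2L] <- params$omnivoreEfficiency *
    (1 - params$omnivoreHerbivoryWeight)
  abund <- co$abundance
  mass <- co$mass
  pool <- co$reproPool
  alive <- which(abund > 0)
  idxByCell <- split(alive, co$cell[alive])
  predCells <- unique(co$cell[pw > 0 & abund > 0])
  for (cc in predCells) {
    idx <- idxByCell[[as.character(cc)]]
    if (length(idx) < 2L) next
    pj <- idx[pw[idx] > 0]
    if (!length(pj)) next
    perIndB <- mass[idx] + pool[idx] + assim[idx]
    preyB <- abund[idx] * perIndB
    ## low-density refuge: biomass below the refuge density is unavailable,
    ## so rare prey classes cannot be predated to local extinction
    preyAvail <- pmax(0, preyB - params$preyRefugeDensity * cellArea[cc])
    Kmat <- outer(mass[pj], mass[idx],
                  function(mp, my) preyKernel(my, mp, params))
    Kmat[cbind(seq_along(pj), match(pj, idx))] <- 0  # no self-predation
    V <- drop(Kmat %*% preyAvail)
    if (all(V <= 0)) next
    satP <- (V / cellArea[cc]) / (V / cellArea[cc] + params$predHalfSat)
    demandJ <- pw[pj] * params$predAttack * mass[pj]^params$predExp *
      satP * abund[pj]
    demandJ[V <= 0] <- 0
    ## allocation of each predator's demand across prey, then rationing
    alloc <- (Kmat * rep(preyAvail, each = length(pj))) /
      ifelse(V > 0, V, 1) * demandJ
    killDesired <- colSums(alloc)
    f <- ifelse(killDesired > 0, pmin(1, preyAvail / killDesired), 0)
    kill <- killDesired * f
    creditJ <- drop(alloc %*% f) * params$assimEffPredation
    ## apply kills, then credit survivors
    newAbund <- abund[idx] - ifelse(perIndB > 0, kill / perIndB, 0)
    newAbund[newAbund < 0] <- 0
    abund[idx] <- newAbund
    nPost <- abund[pj]
    ok <- nPost > 0
    assim[pj[ok]] <- assim[pj[ok]] + creditJ[ok] / nPost[ok]
    ledger["predDebit"] <- ledger["predDebit"] + sum(kill)
    ledger["predAssim"] <- ledger["predAssim"] + sum(creditJ[ok])
  }
  co$abundance <- abund
  co$assim <- assim
  list(cohorts = co, stocks = stocks, ledger = ledger)
}

## sum of x grouped by 1-based cell index, returned as a length-nCells vector
tapplySum <- function(x, cell, nCells) {
  out <- numeric(nCells)
  s <- rowsum(x, cell, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Metabolic mass loss
#'
#' Debits each individual's metabolic cost for the month:
#' coefficient x m^b, with the ectotherm coefficient Q10-scaled by cell
#' temperature and the (larger) endotherm coefficient constant. Mass is
#' floored at a fraction of birth mass (the loss is clipped, never making
#' mass negative); a clipped cohort, or one whose realized intake fell below
#' the hunger threshold of its requirement, is flagged starving. The
#' realized intake/requirement ratio is stored as \code{hunger}.
#'
#' @param co cohort table carrying an \code{assim} column (kg/individual);
#'   absent columns are treated as zero intake.
#' @param temperature per-cohort cell temperature, degrees C (recycled).
#' @param params a \code{\link{processParams}} list.
#' @return list(cohorts, ledger) where cohorts gains \code{surplus} (kg per
#'   individual, may be negative), \code{hunger}, and \code{starving}
#'   columns; ledger entry metabolismLoss (kg).
#' @export
metabolise <- function(co, temperature, params = processParams()) {
  if (is.null(co$assim)) co$assim <- numeric(nrow(co))
  temperature <- rep_len(temperature, nrow(co))
  coef <- ifelse(co$thermo == 1L, params$metaCoefEndo,
                 params$metaCoefEcto *
                   params$q10^((temperature - params$refTemp) / 10))
  loss <- coef * co$mass^params$metaExp
  floorMass <- params$massFloorFraction * co$birthMass
  maxLoss <- co$assim + pmax(0, co$mass - floorMass)
  actual <- pmin(loss, maxLoss)
  co$surplus <- co$assim - actual
  co$hunger <- ifelse(loss > 0, pmin(co$assim / loss, 2), 1)
  co$starving <- (actual < loss) | (co$hunger < params$hungerThreshold)
  ledger <- c(metabolismLoss = sum(co$abundance * actual))
  co$assim <- NULL
  list(cohorts = co, ledger = ledger)
}

#' Growth and reproduction
#'
#' Allocates each cohort's net surplus (assimilate minus metabolic cost,
#' from \code{\link{metabolise}}): a deficit is taken from body mass;
#' pre-maturity surplus grows current mass toward maturity mass; beyond
#' maturity, a configured fraction accrues to the per-individual
#' reproductive pool. When the pool reaches birth mass, an offspring cohort
#' is spawned: current mass = birth mass, abundance = parent abundance x
#' pool / birth mass (conserving mass exactly), categorical traits and mass
#' traits inherited, flagged natal. Semelparous parents die on spawning;
#' iteroparous parents persist with an emptied pool.
#'
#' @param co cohort table with a \code{surplus} column.
#' @param params a \code{\link{processParams}} list.
#' @return list(cohorts, ledger): offspring rows appended; ledger entry
#'   semelparousLoss (kg of post-spawning parent biomass).
#' @export
growAndReproduce <- function(co, params = processParams()) {
  ledger <- c(semelparousLoss = 0)
  if (nrow(co) == 0L) return(list(cohorts = co, ledger = ledger))
  s <- co$surplus
  neg <- s < 0
  co$mass[neg] <- co$mass[neg] + s[neg]
  pos <- which(s > 0)
  if (length(pos)) {
    toMaturity <- pmax(0, co$maturityMass[pos] - co$mass[pos])
    dm <- pmin(s[pos], toMaturity)
    leftover <- s[pos] - dm
    co$mass[pos] <- co$mass[pos] + dm + (1 - params$reproFraction) * leftover
    co$reproPool[pos] <- co$reproPool[pos] + params$reproFraction * leftover
  }
  co$surplus <- NULL

  spawn <- which(co$reproPool >= co$birthMass & co$abundance > 0)
  if (length(spawn)) {
    par <- co[spawn, ]
    off <- par
    off$abundance <- par$abundance * par$reproPool / par$birthMass
    off$mass <- par$birthMass
    off$reproPool <- 0
    off$age <- 0
    off$hunger <- 1
    off$natal <- TRUE
    if (!is.null(off$starving)) off$starving <- FALSE
    co$reproPool[spawn] <- 0
    semel <- spawn[co$repro[spawn] == 2L]
    if (length(semel)) {
      ledger["semelparousLoss"] <-
        sum(co$abundance[semel] * co$mass[semel])
      co$abundance[semel] <- 0
    }
    rownames(co) <- NULL
    rownames(off) <- NULL
    co <- rbind(co, off)
  }
  list(cohorts = co, ledger = ledger)
}

#' Background, senescence, starvation, and crowding mortality
#'
#' Multiplies abundance by exp(-(mu_bg + mu_sen + mu_starv * starving +
#' mu_crowd)) for the month, where senescence mortality grows linearly with
#' age relative to an allometric lifespan (lifespanCoef x
#' maturityMass^0.25 months), and crowding mortality — a self-limitation
#' term that damps consumer-resource boom-bust cycles — rises linearly
#' with the cohort's own trophic group's biomass density in its cell
#' (mortCrowding x density/crowdingReference; applied only when
#' \code{cellArea} is supplied).
#'
#' @param co cohort table; a \code{starving} logical column is honoured if
#'   present (defaults to not starving).
#' @param params a \code{\link{processParams}} list.
#' @param cellArea optional per-cell areas (km^2) enabling the crowding
#'   term.
#' @return list(cohorts, ledger) with ledger entry mortalityLoss (kg,
#'   including reproductive-pool biomass of the dead).
#' @export
applyMortality <- function(co, params = processParams(), cellArea = NULL) {
  if (nrow(co) == 0L)
    return(list(cohorts = co, ledger = c(mortalityLoss = 0)))
  starving <- if (is.null(co$starving)) rep(FALSE, nrow(co)) else co$starving
  lifespan <- params$lifespanCoef * co$maturityMass^0.25
  mu <- params$mortBackground +
    params$mortSenescenceRate * co$age / lifespan +
    params$mortStarvation * starving
  if (!is.null(cellArea) && params$mortCrowding > 0) {
    key <- (co$cell - 1L) * 3L + co$trophic
    bio <- rowsum(co$abundance * (co$mass + co$reproPool), key,
                  reorder = FALSE)
    dens <- (bio[, 1] / cellArea[(as.integer(rownames(bio)) - 1L) %/% 3L +
                                   1L])[match(key, as.integer(rownames(bio)))]
    ref <- params$crowdingReference[TROPHIC_LEVELS[co$trophic]]
    mu <- mu + params$mortCrowding * dens / ref
  }
  surv <- exp(-mu)
  loss <- sum(co$abundance * (1 - surv) * (co$mass + co$reproPool))
  co$abundance <- co$abundance * surv
  list(cohorts = co, ledger = c(mortalityLoss = loss))
}

#' Dispersal on the bounded grid
#'
#' Natal dispersal moves newly spawned cohorts with a configured
#' probability; responsive dispersal moves cohorts whose realized
#' intake/requirement ratio fell below the hunger threshold. A mover's
#' destination is drawn uniformly among cells whose centres lie within its
#' allometric dispersal radius d = d0 x m^exponent (km) of the current cell;
#' the grid boundary is closed, so candidates outside the grid simply do not
#' exist, and a radius smaller than the cell spacing leaves the cohort in
#' place. Cohorts relocate wholesale.
#'
#' @param co cohort table (columns natal, hunger used).
#' @param land a \linkS4class{Landscape}.
#' @param params a \code{\link{processParams}} list.
#' @return the cohort table with updated cells and natal flags cleared.
#' @export
disperse <- function(co, land, params = processParams()) {
  if (nrow(co) == 0L) return(co)
  wantNatal <- co$natal & runif(nrow(co)) < params$natalDispersalProb
  wantResp <- !co$natal & co$hunger < params$hungerThreshold &
    runif(nrow(co)) < params$responsiveDispersalProb
  movers <- which((wantNatal | wantResp) & co$abundance > 0)
  if (length(movers)) {
    d <- params$dispersalCoef * co$mass[movers]^params$dispersalExp
    D <- cellDistanceMatrix(land)
    byCell <- split(seq_along(movers), co$cell[movers])
    for (cellName in names(byCell)) {
      cc <- as.integer(cellName)
      mi <- byCell[[cellName]]
      o <- order(D[, cc])
      sds <- D[o, cc]
      ## number of candidate cells within each mover's radius (the origin
      ## itself is always within, at distance 0)
      m <- findInterval(d[mi], sds)
      dest <- o[pmin(floor(runif(length(mi)) * m) + 1L, m)]
      co$cell[movers[mi]] <- dest
    }
  }
  co$natal <- FALSE
  co
}

## memoized inter-cell-centre distance matrix (km)
distanceCache <- new.env(parent = emptyenv())
cellDistanceMatrix <- function(land) {
  key <- paste(land@nRows, land@nCols, land@cellSize,
               land@centre[1], land@centre[2], sep = "_")
  D <- distanceCache[[key]]
  if (is.null(D)) {
    D <- as.matrix(stats::dist(cbind(land@cellX, land@cellY)))
    distanceCache[[key]] <- D
  }
  D
}

#' Merge cohorts down to the per-cell cap
#'
#' When a cell holds more cohorts than the cap, cohorts with identical
#' categorical traits (same functional group) are merged nearest-neighbour
#' in log body mass: within the (group, mass)-sorted cell the excess
#' count of smallest same-group log-mass gaps is closed, so the closest
#' pairs merge first (closing adjacent gaps can chain several cohorts into
#' one cluster). Merging conserves total abundance and total biomass —
#' merged mass and the other quantitative traits are abundance-weighted
#' means. Only if too few same-group neighbours exist are
#' lowest-total-biomass cohorts removed instead, and their biomass
#' reported in the ledger.
#'
#' @param co cohort table.
#' @param cap maximum cohorts per cell (>= 1).
#' @return list(cohorts, ledger) with ledger entry mergeCullLoss (kg).
#' @export
mergeCohorts <- function(co, cap = 64L) {
  stopifnot2(cap >= 1, "cap must be >= 1")
  ledger <- c(mergeCullLoss = 0)
  n <- nrow(co)
  if (n == 0L) return(list(cohorts = co, ledger = ledger))
  counts <- tabulate(co$cell)
  if (!any(counts > cap)) return(list(cohorts = co, ledger = ledger))
  ## plain vectors: this is the engine's hottest path
  groupV <- co$group; massV <- co$mass; birthV <- co$birthMass
  matV <- co$maturityMass; abundV <- co$abundance; poolV <- co$reproPool
  ageV <- co$age; hungerV <- co$hunger; natalV <- co$natal
  drop <- logical(n)
  idxByCell <- split(seq_len(n), co$cell)
  for (cc in which(counts > cap)) {
    s <- idxByCell[[as.character(cc)]]
    s <- s[order(groupV[s], massV[s])]
    k <- length(s)
    g <- groupV[s]
    lm <- log(massV[s])
    ## gap[i]: log-mass gap between sorted neighbours i-1 and i (same
    ## group only); close the excess count of smallest gaps
    gap <- c(Inf, lm[-1] - lm[-k])
    gap[c(FALSE, g[-1] != g[-k])] <- Inf
    pick <- order(gap)[seq_len(k - cap)]
    pick <- pick[is.finite(gap[pick])]
    closeGap <- logical(k)
    closeGap[pick] <- TRUE
    cl <- cumsum(!closeGap)  # cluster id along the sorted cell
    starts <- which(!closeGap)
    N <- abundV[s]
    sums <- rowsum(cbind(N, N * massV[s], N * birthV[s], N * matV[s],
                         N * poolV[s], N * ageV[s], N * hungerV[s],
                         natalV[s], massV[s], birthV[s], matV[s],
                         poolV[s], ageV[s], hungerV[s]),
                   cl, reorder = FALSE)
    wsum <- sums[, 1]
    size <- tabulate(cl)
    z <- wsum == 0  # zero-abundance clusters: plain mean of traits
    wgt <- function(j, jz) {
      out <- sums[, j]
      out[!z] <- out[!z] / wsum[!z]
      out[z] <- sums[z, jz] / size[z]
      out
    }
    first <- s[starts]
    massV[first] <- wgt(2, 9)
    birthV[first] <- wgt(3, 10)
    matV[first] <- wgt(4, 11)
    poolV[first] <- wgt(5, 12)
    ageV[first] <- wgt(6, 13)
    hungerV[first] <- wgt(7, 14)
    abundV[first] <- wsum
    natalV[first] <- sums[, 8] > 0
    drop[s[closeGap]] <- TRUE
    ## if same-group gaps ran out, cull lowest-biomass clusters
    nLeft <- length(starts) - cap
    if (nLeft > 0) {
      bio <- abundV[first] * (massV[first] + poolV[first])
      worst <- order(bio)[seq_len(nLeft)]
      ledger["mergeCullLoss"] <- ledger["mergeCullLoss"] + sum(bio[worst])
      drop[first[worst]] <- TRUE
    }
  }
  co$mass <- massV; co$birthMass <- birthV; co$maturityMass <- matV
  co$abundance <- abundV; co$reproPool <- poolV; co$age <- ageV
  co$hunger <- hungerV; co$natal <- natalV
  list(cohorts = co[!drop, , drop = FALSE], ledger = ledger)
}

#' Advance the simulation one month
#'
#' Applies, in fixed order: autotroph growth, eating (herbivory and
#' predation), metabolism, growth and reproduction, mortality, dispersal,
#' and cohort merging; cohorts whose abundance falls below the cull
#' threshold (including exactly zero) are removed at the end of the step.
#' Uses the current RNG stream; set a seed for reproducibility. A NaN
#' appearing in any biomass aborts with an error naming the process.
#'
#' @param state a \linkS4class{SimState}.
#' @param env an \linkS4class{EnvironmentGrid}.
#' @param params a \code{\link{processParams}} list.
#' @return list(state, ledger): the advanced state and the itemized mass
#'   ledger (kg) for the month, with entries nppInput, climateLoss,
#'   shedLoss, herbDebit, herbAssim, predDebit, predAssim, metabolismLoss,
#'   semelparousLoss, mortalityLoss, mergeCullLoss, cullLoss.
#' @export
stepMonth <- function(state, env, params = processParams()) {
  land <- state@landscape
  calMonth <- state@month %% 12L + 1L
  npp <- env@npp[calMonth, ]
  temp <- env@temperature[calMonth, ]
  dry <- npp < colMeans(env@npp)

  g <- autotrophGrowth(state@stocks, npp, land@cellArea, dry, params)
  checkFinite("autotroph_growth", g$stocks$leaf, g$stocks$structural)

  e <- eat(state@cohorts, g$stocks, land@cellArea, params)
  checkFinite("eating", e$stocks$leaf, e$cohorts$abundance, e$cohorts$assim)

  m <- metabolise(e$cohorts, temp[e$cohorts$cell], params)
  checkFinite("metabolism", m$cohorts$mass, m$cohorts$surplus)

  r <- growAndReproduce(m$cohorts, params)
  checkFinite("reproduction", r$cohorts$mass, r$cohorts$abundance)

  mo <- applyMortality(r$cohorts, params, land@cellArea)
  checkFinite("mortality", mo$cohorts$abundance)

  co <- disperse(mo$cohorts, land, params)
  co$starving <- NULL

  mg <- mergeCohorts(co, params$cohortCap)
  co <- mg$cohorts

  tiny <- co$abundance < params$minAbundance
  cullLoss <- sum(co$abundance[tiny] * (co$mass[tiny] + co$reproPool[tiny]))
  co <- co[!tiny, , drop = FALSE]
  rownames(co) <- NULL
  co$age <- co$age + 1

  ledger <- c(g$ledger, e$ledger, m$ledger, r$ledger, mo$ledger,
              mg$ledger, cullLoss = cullLoss)

  state@cohorts <- co
  state@stocks <- e$stocks
  state@month <- state@month + 1L
  list(state = state, ledger = ledger)
}

checkFinite <- function(process, ...) {
  for (v in list(...)) {
    if (length(v) && anyNA(v <- as.numeric(v)) || any(!is.finite(v)))
      stop(sprintf("non-finite biomass in process '%s'", process),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Net biomass change implied by a step ledger
#'
#' The conservation identity audited by the test suite: the change in total
#' system biomass over one month equals NPP input minus climate loss, leaf
#' shed, unassimilated (wasted) herbivory and predation, metabolic loss,
#' deaths, and merge/cull losses, minus any scenario removal applied that
#' month.
#'
#' @param ledger a ledger vector from \code{\link{stepMonth}}.
#' @param removed biomass removed by the land-use scenario this month, kg.
#' @return expected change in total biomass, kg.
#' @export
ledgerNetChange <- function(ledger, removed = 0) {
  unname(ledger["nppInput"] - ledger["climateLoss"] - ledger["shedLoss"] -
           (ledger["herbDebit"] - ledger["herbAssim"]) -
           (ledger["predDebit"] - ledger["predAssim"]) -
           ledger["metabolismLoss"] - ledger["semelparousLoss"] -
           ledger["mortalityLoss"] - ledger["mergeCullLoss"] -
           ledger["cullLoss"] - removed)
}
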