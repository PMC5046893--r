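params <- processParams()

test_that("autotroph growth follows the logistic closed form and its contracts", {
  land <- tinyLandscape(1L, 1L)
  area <- land@cellArea
  p <- processParams(climateMortality = 0.1)

  ## one month from a part-filled stock equals the hand-evaluated update:
  ## growth = r * (npp/nppRef) * L * (1 - L/K), split by allocation, then
  ## climate mortality on both pools
  K <- p$carryingCapacityDensity * area
  L0 <- K / 4
  st <- data.frame(cell = 1L, leaf = L0, structural = 1000, strategy = 2L)
  npp <- 2.5e4  # half the reference NPP
  g <- autotrophGrowth(st, npp, area, dry = FALSE, params = p)
  growth <- p$autotrophGrowthRate *
    (npp / p$nppReference)^p$nppSensitivity * L0 * (1 - L0 / K)
  expect_equal(g$stocks$leaf, (L0 + p$leafAllocation * growth) * 0.9)
  expect_equal(g$stocks$structural,
               (1000 + (1 - p$leafAllocation) * growth) *
                 (1 - p$structuralTurnover))
  expect_equal(unname(g$ledger["nppInput"]), growth)

  ## zero NPP, zero turnover: unchanged
  p0 <- processParams(climateMortality = 0, structuralTurnover = 0)
  st1 <- data.frame(cell = 1L, leaf = 100, structural = 50, strategy = 2L)
  g0 <- autotrophGrowth(st1, 0, area, dry = FALSE, params = p0)
  expect_equal(g0$stocks$leaf, 100)
  expect_equal(g0$stocks$structural, 50)

  ## an emptied leaf pool is absorbing: no regrowth from zero
  stE <- data.frame(cell = 1L, leaf = 0, structural = 0, strategy = 2L)
  gE <- autotrophGrowth(stE, 5e4, area, dry = FALSE, params = p)
  expect_equal(gE$stocks$leaf, 0)
  expect_equal(unname(gE$ledger["nppInput"]), 0)

  ## at or above carrying capacity, net growth <= 0
  stK <- data.frame(cell = 1L, leaf = K, structural = 0, strategy = 2L)
  gK <- autotrophGrowth(stK, 5e4, area, dry = FALSE, params = p)
  expect_lte(gK$stocks$leaf, K)
  expect_equal(unname(gK$ledger["nppInput"]), 0)

  ## deciduous stocks shed leaf in dry months; evergreens do not
  p2 <- processParams(climateMortality = 0)
  std <- data.frame(cell = 1L, leaf = 100, structural = 50, strategy = 1L)
  gd <- autotrophGrowth(std, 0, area, dry = TRUE, params = p2)
  expect_equal(gd$stocks$leaf, 100 * (1 - p2$deciduousShedFraction))
  ge <- autotrophGrowth(st1, 0, area, dry = TRUE, params = p2)
  expect_equal(ge$stocks$leaf, 100)
})

test_that("herbivores gain nothing from an empty leaf pool", {
  land <- tinyLandscape(1L, 1L)
  co <- makeCohort(trophic = 1L)
  st <- data.frame(cell = 1L, leaf = 0, structural = 1e6, strategy = 2L)
  e <- eat(co, st, land@cellArea, params)
  expect_equal(e$cohorts$assim, 0)
  expect_equal(unname(e$ledger["herbDebit"]), 0)
})

test_that("two identical herbivore cohorts competing for scarce leaf split it equally", {
  land <- tinyLandscape(1L, 1L)
  co <- rbind(makeCohort(abundance = 1e10), makeCohort(abundance = 1e10))
  st <- data.frame(cell = 1L, leaf = 10, structural = 0, strategy = 2L)
  e <- eat(co, st, land@cellArea, params)
  ## rationing: the grazeable fraction is consumed, half by each cohort
  consumed <- params$grazeableFraction * 10
  expect_equal(e$stocks$leaf, 10 - consumed, tolerance = 1e-12)
  expect_equal(unname(e$ledger["herbDebit"]), consumed, tolerance = 1e-12)
  expect_equal(e$cohorts$assim[1], e$cohorts$assim[2])
  expect_equal(sum(e$cohorts$assim * co$abundance),
               consumed * params$assimEffHerbivory, tolerance = 1e-10)
})

test_that("leaf debit times assimilation efficiency is credited to herbivores", {
  land <- tinyLandscape(1L, 1L)
  co <- rbind(makeCohort(mass = 5, abundance = 40),
              makeCohort(mass = 2, abundance = 10))
  st <- data.frame(cell = 1L, leaf = 1e6, structural = 1e5, strategy = 2L)
  e <- eat(co, st, land@cellArea, params)
  debit <- 1e6 - e$stocks$leaf
  credit <- sum(e$cohorts$assim * e$cohorts$abundance)
  expect_equal(credit, debit * params$assimEffHerbivory, tolerance = 1e-9)
})

test_that("the prey-preference kernel peaks at the optimal prey mass", {
  predMass <- 100
  opt <- params$optimalPreyRatio * predMass
  masses <- opt * 10^seq(-2, 2, by = 0.25)
  w <- trophicscape:::preyKernel(masses, predMass, params)
  expect_equal(masses[which.max(w)], opt)
  expect_equal(max(w), 1)
})

test_that("predation removes prey abundance and credits predators at efficiency", {
  land <- tinyLandscape(1L, 1L)
  co <- rbind(
    makeCohort(trophic = 1L, mass = 1, abundance = 1e5),      # prey
    makeCohort(trophic = 3L, mass = 100, abundance = 50))     # predator
  st <- data.frame(cell = 1L, leaf = 0, structural = 0, strategy = 2L)
  e <- eat(co, st, land@cellArea, params)
  killed <- (co$abundance[1] - e$cohorts$abundance[1]) * co$mass[1]
  expect_gt(killed, 0)
  credit <- e$cohorts$assim[2] * e$cohorts$abundance[2]
  expect_equal(credit, killed * params$assimEffPredation, tolerance = 1e-9)
  expect_equal(unname(e$ledger["predDebit"]), killed, tolerance = 1e-9)
})

test_that("metabolic loss scales as m^0.75 and endotherms pay more", {
  p <- processParams()
  co <- rbind(makeCohort(mass = 10, birthMass = 1e-3),
              makeCohort(mass = 20, birthMass = 1e-3))
  m <- metabolise(co, temperature = p$refTemp, params = p)
  loss <- -(m$cohorts$surplus)  # no intake, so surplus = -actual loss
  expect_equal(loss[2] / loss[1], 2^0.75, tolerance = 1e-9)

  ## endotherm vs ectotherm at reference temperature
  co2 <- rbind(makeCohort(thermo = 1L), makeCohort(thermo = 2L))
  m2 <- metabolise(co2, temperature = p$refTemp, params = p)
  expect_gt(-m2$cohorts$surplus[1], -m2$cohorts$surplus[2])

  ## ectotherm loss is Q10-scaled with temperature; endotherm is not
  m2c <- metabolise(co2, temperature = p$refTemp + 10, params = p)
  expect_equal(m2c$cohorts$surplus[2] / m2$cohorts$surplus[2], p$q10,
               tolerance = 1e-9)
  expect_equal(m2c$cohorts$surplus[1], m2$cohorts$surplus[1])
})

test_that("metabolism never drives mass below the floor and flags starvation", {
  p <- processParams()
  co <- makeCohort(mass = 1.001e-3, birthMass = 2e-3, maturityMass = 1)
  floorMass <- p$massFloorFraction * co$birthMass
  m <- metabolise(co, temperature = 20, params = p)
  g <- growAndReproduce(m$cohorts, p)
  expect_gte(g$cohorts$mass, floorMass)
  expect_true(m$cohorts$starving)
})

test_that("growth allocates surplus to mass before maturity and to the pool after", {
  p <- processParams()
  ## juvenile with surplus below the maturity deficit: all to mass
  co <- makeCohort(mass = 5, maturityMass = 10)
  co$surplus <- 2
  g <- growAndReproduce(co, p)
  expect_equal(g$cohorts$mass, 7)
  expect_equal(g$cohorts$reproPool, 0)

  ## adult: reproFraction of surplus to the pool
  co2 <- makeCohort(mass = 10, maturityMass = 10, birthMass = 1e3)
  co2$surplus <- 1
  g2 <- growAndReproduce(co2, p)
  expect_equal(g2$cohorts$reproPool, p$reproFraction)
  expect_equal(g2$cohorts$mass, 10 + (1 - p$reproFraction))
})

test_that("spawning conserves mass and semelparous parents die", {
  p <- processParams()
  co <- rbind(
    makeCohort(repro = 1L, mass = 10, birthMass = 1, abundance = 100),
    makeCohort(repro = 2L, mass = 10, birthMass = 1, abundance = 50))
  co$reproPool <- c(2.5, 3)
  co$surplus <- 0
  g <- growAndReproduce(co, p)
  out <- g$cohorts
  expect_equal(nrow(out), 4L)
  off <- out[3:4, ]
  ## parent pool debit equals offspring abundance x birth mass
  expect_equal(off$abundance * off$birthMass, c(100 * 2.5, 50 * 3))
  expect_equal(off$mass, c(1, 1))
  expect_true(all(off$natal))
  expect_equal(off$age, c(0, 0))
  ## iteroparous parent persists, semelparous dies
  expect_equal(out$abundance[1], 100)
  expect_equal(out$abundance[2], 0)
  expect_equal(unname(g$ledger["semelparousLoss"]), 50 * 10)
  ## traits inherited
  expect_equal(off$maturityMass, c(10, 10))
})

test_that("mortality follows the closed-form exponential and additivity contracts", {
  ## all rates zero: abundance unchanged
  p0 <- processParams(mortBackground = 0, mortSenescenceRate = 0,
                      mortStarvation = 0)
  co <- makeCohort(abundance = 123)
  expect_equal(applyMortality(co, p0)$cohorts$abundance, 123)

  ## background ln(2) per month halves abundance
  pHalf <- processParams(mortBackground = log(2), mortSenescenceRate = 0,
                         mortStarvation = 0)
  expect_equal(applyMortality(co, pHalf)$cohorts$abundance, 61.5)

  ## starving cohorts lose abundance strictly faster
  p <- processParams()
  co2 <- rbind(makeCohort(), makeCohort())
  co2$starving <- c(TRUE, FALSE)
  out <- applyMortality(co2, p)$cohorts
  expect_lt(out$abundance[1], out$abundance[2])

  ## older cohorts senesce faster
  co3 <- rbind(makeCohort(age = 100), makeCohort(age = 0))
  out3 <- applyMortality(co3, p)$cohorts
  expect_lt(out3$abundance[1], out3$abundance[2])
})

test_that("dispersal respects the closed boundary and the allometric radius", {
  land <- tinyLandscape(3L, 3L)  # 0.1 deg cells, ~11 km spacing
  p <- processParams(natalDispersalProb = 1, responsiveDispersalProb = 1)

  ## radius below one cell width: cannot leave the cell
  tiny <- makeCohort(mass = 1e-6, natal = TRUE, cell = 5L)
  set.seed(1)
  expect_equal(disperse(tiny, land, p)$cell, 5L)

  ## a huge disperser from the corner stays inside the grid
  big <- makeCohort(mass = 5000, natal = TRUE, cell = 1L)
  set.seed(2)
  moved <- replicate(20, disperse(big, land, p)$cell)
  expect_true(all(moved >= 1L & moved <= 9L))
  expect_gt(length(unique(moved)), 1L)  # it does move

  ## radius is monotone in mass
  d <- p$dispersalCoef * c(0.1, 10, 1000)^p$dispersalExp
  expect_true(all(diff(d) > 0))

  ## hungry cohorts move; satiated non-natal cohorts stay
  hungry <- makeCohort(mass = 5000, hunger = 0.1, cell = 5L)
  sated <- makeCohort(mass = 5000, hunger = 1, cell = 5L)
  set.seed(3)
  expect_false(all(replicate(10, disperse(hungry, land, p)$cell) == 5L))
  expect_true(all(replicate(10, disperse(sated, land, p)$cell) == 5L))
})

test_that("merging conserves abundance and biomass and respects the cap", {
  ## below the cap: unchanged
  co <- rbind(makeCohort(mass = 1), makeCohort(mass = 2))
  expect_identical(mergeCohorts(co, 64L)$cohorts, co)

  ## merging two equal cohorts: one cohort, same mass, doubled abundance
  co2 <- rbind(makeCohort(mass = 3, abundance = 10),
               makeCohort(mass = 3, abundance = 10))
  m2 <- mergeCohorts(co2, 1L)$cohorts
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$mass, 3)
  expect_equal(m2$abundance, 20)

  ## biomass conserved to 1e-9 relative under heavy merging
  set.seed(5)
  n <- 40
  co3 <- do.call(rbind, lapply(seq_len(n), function(i)
    makeCohort(group = sample(3, 1), mass = exp(rnorm(1)),
               abundance = runif(1, 1, 100),
               reproPool = runif(1, 0, 0.5))))
  before <- sum(co3$abundance * (co3$mass + co3$reproPool))
  m3 <- mergeCohorts(co3, 5L)
  after <- sum(m3$cohorts$abundance *
                 (m3$cohorts$mass + m3$cohorts$reproPool)) +
    m3$ledger["mergeCullLoss"]
  expect_equal(unname(after), before, tolerance = 1e-9)
  expect_lte(nrow(m3$cohorts), 5L)

  ## the closest same-group pair merges first
  co4 <- rbind(makeCohort(group = 1L, mass = 1),
               makeCohort(group = 1L, mass = 1.05),
               makeCohort(group = 1L, mass = 100))
  m4 <- mergeCohorts(co4, 2L)$cohorts
  expect_equal(sort(m4$mass), c(1.025, 100))
})

test_that("a state with no cohorts and zero NPP changes only by stock climate mortality", {
  land <- tinyLandscape()
  env <- flatEnvironment(land, meanNpp = 0)
  p <- processParams()
  st <- tinyState(makeCohort()[0, ], land = land)
  before <- st@stocks
  r <- stepMonth(st, env, p)
  expect_equal(r$state@stocks$leaf, before$leaf * (1 - p$climateMortality))
  expect_equal(r$state@stocks$structural,
               before$structural * (1 - p$structuralTurnover))
  expect_identical(nrow(r$state@cohorts), 0L)
})

test_that("a lone herbivore with ample leaf gains mass in one step", {
  land <- tinyLandscape(1L, 1L)
  env <- flatEnvironment(land)
  co <- makeCohort(trophic = 1L, mass = 5, maturityMass = 50,
                   abundance = 10)
  st <- tinyState(co, land = land,
                  st = data.frame(cell = 1L, leaf = 1e8, structural = 1e8,
                                  strategy = 2L))
  set.seed(1)
  r <- stepMonth(st, env, processParams())
  expect_gt(r$state@cohorts$mass[1], 5)
})

test_that("the monthly mass ledger balances to 1e-9 relative", {
  land <- tinyLandscape()
  env <- tinyEnvironment(land)
  p <- processParams()
  st <- seedCohorts(land, functionalGroupTable(), 2L, p, seed = 8L)
  set.seed(8)
  for (k in 1:24) {
    before <- totalBiomass(st)
    r <- stepMonth(st, env, p)
    st <- r$state
    after <- totalBiomass(st)
    expect_lt(abs((after - before) - ledgerNetChange(r$ledger)) /
                max(1, abs(before)), 1e-9)
  }
})

test_that("no negative biomass or abundance ever appears over a stochastic run", {
  land <- tinyLandscape()
  env <- tinyEnvironment(land)
  p <- processParams()
  st <- seedCohorts(land, functionalGroupTable(), 2L, p, seed = 9L)
  set.seed(9)
  for (k in 1:36) {
    st <- stepMonth(st, env, p)$state
    expect_identical(validateState(st), character(0))
    expect_true(all(st@cohorts$abundance >= 0))
    expect_true(all(st@stocks$leaf >= 0))
  }
})

test_that("identical seeds give identical trajectories", {
  land <- tinyLandscape()
  env <- tinyEnvironment(land)
  p <- processParams()
  st <- seedCohorts(land, functionalGroupTable(), 2L, p, seed = 12L)
  set.seed(21)
  r1 <- runSimulation(st, env, p, 18L)
  set.seed(21)
  r2 <- runSimulation(st, env, p, 18L)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$state@cohorts, r2$state@cohorts)
  set.seed(22)
  r3 <- runSimulation(st, env, p, 18L)
  expect_false(identical(r1$records, r3$records))
})

test_that("an unimpacted run reaches a dynamic steady state with a biomass pyramid", {
  land <- makeLandscape(5, 5, 0.1)
  p <- processParams()
  okCV <- 0
  okPyr <- 0
  for (s in 1:3) {
    env <- generateEnvironment(land, savannaParams(), seed = s * 11)
    st <- seedCohorts(land, functionalGroupTable(), 2L, p, seed = s)
    set.seed(s)
    r <- runSimulation(st, env, p, 240L)
    last <- tail(r$records, 48)  # final 20% of the run
    cv <- sd(last[, "total"]) / mean(last[, "total"])
    m <- colMeans(last)
    if (cv < 0.2) okCV <- okCV + 1
    if (m[["autotroph"]] > m[["herbivore"]] &&
        m[["herbivore"]] >= m[["omnivore"]] + m[["carnivore"]])
      okPyr <- okPyr + 1
  }
  expect_gte(okCV, 2L)
  expect_gte(okPyr, 2L)
})
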