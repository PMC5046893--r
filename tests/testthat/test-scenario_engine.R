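test_that("default factorial enumerates 29 treatments with one pristine control", {
  tr <- enumerateTreatments()
  expect_equal(nrow(tr), 29L)
  expect_equal(sum(tr$configuration == "pristine"), 1L)
  ## full extent appears once per intensity, not once per configuration
  expect_equal(sum(tr$extent == 1), 4L)
  expect_false(any(duplicated(tr$label)))
})

test_that("treatment counts match a brute-force enumerator with mask-based dedup", {
  bruteCount <- function(extents, intensities, configs) {
    ## independent oracle: enumerate all combos, deduplicate by the set of
    ## distinct masks a combo can produce (full extent = all cells for
    ## either configuration), add the pristine control
    seen <- character()
    for (cf in configs) for (e in extents) for (i in intensities) {
      key <- paste(if (e == 1) "all" else cf, e, i)
      seen <- union(seen, key)
    }
    length(seen) + 1L
  }
  cases <- list(
    list(e = c(0.25, 0.5, 0.75, 1), i = c(0.25, 0.5, 0.75, 1),
         c = c("random", "continuous")),
    list(e = 1, i = 0.5, c = c("random", "continuous")),
    list(e = c(0.5, 1), i = c(0.25, 1), c = "random"),
    list(e = c(0.2, 0.4, 0.6), i = c(0.1, 0.9),
         c = c("random", "continuous")))
  for (cs in cases) {
    expect_equal(nrow(enumerateTreatments(cs$e, cs$i, cs$c)),
                 bruteCount(cs$e, cs$i, cs$c))
  }
  ## full-extent dedup example: one impacted + pristine
  expect_equal(nrow(enumerateTreatments(1, 0.5)), 2L)
})

test_that("invalid factor levels are rejected", {
  expect_error(enumerateTreatments(c(0, 0.5), 0.5), "\\(0, 1\\]")
  expect_error(enumerateTreatments(0.5, 1.5), "\\(0, 1\\]")
})

test_that("impacted-cell masks honour configuration and quota", {
  land <- makeLandscape(10, 10, 0.1)
  ## full extent: all cells either way
  expect_true(all(selectImpactedCells(land, 1, "random", seed = 1)))
  expect_true(all(selectImpactedCells(land, 1, "continuous")))

  ## 50% continuous on 10x10: rows 0-4 exactly, edge-connected block
  m <- selectImpactedCells(land, 0.5, "continuous")
  expect_identical(which(m), 1:50)

  ## random masks: exact cardinality, seed-reproducible, seed-sensitive
  r1 <- selectImpactedCells(land, 0.25, "random", seed = 9)
  r2 <- selectImpactedCells(land, 0.25, "random", seed = 9)
  r3 <- selectImpactedCells(land, 0.25, "random", seed = 10)
  expect_equal(sum(r1), 25L)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))

  ## random partial masks are generally not edge-connected, continuous are
  isConnected <- function(mask, nr, nc) {
    cells <- which(mask)
    if (length(cells) <= 1) return(TRUE)
    seen <- cells[1]
    frontier <- cells[1]
    while (length(frontier)) {
      nb <- unlist(lapply(frontier, function(x) {
        r <- (x - 1) %/% nc; c <- (x - 1) %% nc
        cand <- c(if (r > 0) x - nc, if (r < nr - 1) x + nc,
                  if (c > 0) x - 1, if (c < nc - 1) x + 1)
        cand
      }))
      frontier <- setdiff(intersect(nb, cells), seen)
      seen <- union(seen, frontier)
    }
    length(seen) == length(cells)
  }
  expect_true(isConnected(m, 10, 10))
  conn <- vapply(1:6, function(s)
    isConnected(selectImpactedCells(land, 0.25, "random", seed = s),
                10, 10), logical(1))
  expect_false(all(conn))

  ## pristine: empty mask
  expect_equal(sum(selectImpactedCells(land, 0, "pristine")), 0L)

  ## non-integral quota warns and rounds half up
  land5 <- makeLandscape(5, 5, 0.1)
  expect_warning(m5 <- selectImpactedCells(land5, 0.5, "continuous"),
                 "rounding")
  expect_equal(sum(m5), 13L)
})

test_that("impact removal debits both pools proportionally and fills the ledger", {
  land <- tinyLandscape(1L, 1L)
  st <- tinyState(makeCohort(),
                  st = data.frame(cell = 1L, leaf = 80, structural = 20,
                                  strategy = 2L), land = land)
  r <- applyImpact(st, mask = TRUE, intensity = 0.25)
  expect_equal(r$state@stocks$leaf, 60)
  expect_equal(r$state@stocks$structural, 15)
  expect_equal(r$removed, 25)

  ## intensity 1: both pools emptied
  r2 <- applyImpact(st, mask = TRUE, intensity = 1)
  expect_equal(r2$state@stocks$leaf, 0)
  expect_equal(r2$state@stocks$structural, 0)

  ## empty mask: unchanged, ledger 0
  r3 <- applyImpact(st, mask = FALSE, intensity = 0.75)
  expect_identical(r3$state@stocks, st@stocks)
  expect_equal(r3$removed, 0)

  ## heterotrophs untouched
  expect_identical(r2$state@cohorts, st@cohorts)

  ## leaf-only removal mode leaves the structural pool intact
  r4 <- applyImpact(st, mask = TRUE, intensity = 0.25, pools = "leaf")
  expect_equal(r4$state@stocks$leaf, 60)
  expect_equal(r4$state@stocks$structural, 20)
  expect_equal(r4$removed, 20)
})

test_that("the removal ledger equals intensity x pre-removal masked biomass, exactly", {
  land <- tinyLandscape()
  env <- tinyEnvironment(land)
  p <- processParams()
  st <- seedCohorts(land, functionalGroupTable(), 1L, p, seed = 4L)
  tr <- makeTreatment(land, "random", 1 / 3, 0.5, seed = 5L)
  state <- st
  set.seed(6)
  for (m in 1:6) {
    pre <- state@stocks
    expectRemoved <- 0.5 * sum(pre$leaf[tr@mask] + pre$structural[tr@mask])
    imp <- applyImpact(state, tr@mask, tr@intensity)
    expect_identical(imp$removed, expectRemoved)
    expect_true(all(imp$removedPerCell[!tr@mask] == 0))
    state <- stepMonth(imp$state, env, p)$state
  }
})

test_that("a short experiment is paired, windowed, and deterministic", {
  plan <- experimentPlan(
    "desk", baseSeed = 11, replicates = 2L,
    extents = 1 / 3, intensities = c(0.5, 1),
    configurations = "continuous",
    scales = list(list(label = "tiny", nRows = 3L, nCols = 3L,
                       cellSize = 0.1, centre = c(0.05, 38))),
    burnInMonths = 6L, impactMonths = 6L, recordWindowMonths = 3L,
    engine = list(params = processParams(), envParams = savannaParams(),
                  nCohortsPerCell = 1L))
  expect_equal(planSize(plan), 3L * 2L)
  res <- runExperiment(plan)
  s <- res$summaries
  expect_equal(nrow(s), 6L)
  ## every run reports non-negative biomasses and T = C+O+H+A
  expect_true(all(s$T >= 0))
  expect_equal(s$T, s$C + s$O + s$H + s$A, tolerance = 1e-9)
  ## pristine control present per replicate
  expect_equal(sum(s$configuration == "pristine"), 2L)
  ## removal only in impacted runs
  expect_true(all(s$removed[s$configuration == "pristine"] == 0))
  expect_true(all(s$removed[s$configuration != "pristine"] > 0))

  ## identical plan: identical tables (determinism)
  res2 <- runExperiment(plan)
  expect_identical(res2$summaries, s)

  ## different base seed: different numbers
  res3 <- runExperiment(experimentPlan(
    "desk", baseSeed = 12, replicates = 2L,
    extents = 1 / 3, intensities = c(0.5, 1),
    configurations = "continuous",
    scales = plan@scales, burnInMonths = 6L, impactMonths = 6L,
    recordWindowMonths = 3L, engine = plan@engine))
  expect_false(identical(res3$summaries$A, s$A))
})

test_that("pristine and impacted runs of one replicate share the end-of-burn-in state", {
  ## replay the experiment's seed policy by hand for one replicate
  plan <- experimentPlan("desk", baseSeed = 21)
  sc <- plan@scales[[1]]
  land <- makeLandscape(sc$nRows, sc$nCols, sc$cellSize, sc$centre)
  env <- generateEnvironment(land, plan@engine$envParams,
                             seed = trophicscape:::deriveSeed(21L, 1L, 7L))
  p <- plan@engine$params
  st0 <- seedCohorts(land, functionalGroupTable(),
                     plan@engine$nCohortsPerCell, p,
                     seed = trophicscape:::deriveSeed(21L, 1L, 2L, 1L))
  set.seed(trophicscape:::deriveSeed(21L, 1L, 1L, 1L))
  b1 <- runSimulation(st0, env, p, 12L)
  set.seed(trophicscape:::deriveSeed(21L, 1L, 1L, 1L))
  b2 <- runSimulation(st0, env, p, 12L)
  expect_identical(b1$state@cohorts, b2$state@cohorts)
  expect_identical(b1$state@stocks, b2$state@stocks)
})

test_that("burn-in length follows the plan (100 simulated years = 1200 steps)", {
  plan <- experimentPlan("paper")
  expect_identical(plan@burnInMonths, 1200L)
  expect_identical(plan@impactMonths, 1200L)
  ## the desk preset keeps the record window inside the impact phase
  desk <- experimentPlan("desk")
  expect_lte(desk@recordWindowMonths, desk@impactMonths)
})
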