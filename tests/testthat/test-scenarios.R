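# RuBisCO lumping, the Vc/Vo and light scans, the feasibility
# threshold, and the derived photon metrics.

carbSt <- c(RuBP = -1, CO2 = -1, PGA = 2)
oxySt <- c(RuBP = -1, O2 = -1, PGA = 1, PGLY = 1)

makeRubiscoToy <- function() {
  defs <- list(
    list(id = "carb", stoichiometry = carbSt, lower = 0, upper = 1e6,
         category = "metabolic", genes = character(0)),
    list(id = "oxy", stoichiometry = oxySt, lower = 0, upper = 1e6,
         category = "metabolic", genes = character(0)),
    list(id = "RuBP_tx", stoichiometry = c(RuBP = 1), lower = 0,
         upper = 1e6, category = "exchange", genes = character(0)),
    list(id = "CO2_tx", stoichiometry = c(CO2 = 1), lower = 0,
         upper = 1e6, category = "exchange", genes = character(0)),
    list(id = "O2_tx", stoichiometry = c(O2 = 1), lower = 0,
         upper = 1e6, category = "exchange", genes = character(0)),
    list(id = "PGA_tx", stoichiometry = c(PGA = -1), lower = 0,
         upper = 1e6, category = "exchange", genes = character(0)),
    list(id = "PGLY_tx", stoichiometry = c(PGLY = -1), lower = 0,
         upper = 1e6, category = "exchange", genes = character(0)))
  leafFBA:::.buildModel(defs)
}

test_that("lumping matches the coefficient-wise weighted-sum oracle", {
  toy <- makeRubiscoToy()
  ## 1:0 leaves carboxylation unchanged
  m10 <- lumpRubisco(toy, "carb", "oxy", c(1, 0))
  expect_equal(reactionStoichiometry(m10, "RuBisCO_lumped")[names(carbSt)],
               carbSt)
  ## 1:1 is the direct sum
  m11 <- lumpRubisco(toy, "carb", "oxy", c(1, 1))
  expect_equal(reactionStoichiometry(m11, "RuBisCO_lumped"),
               c(RuBP = -2, CO2 = -1, PGA = 3, O2 = -1, PGLY = 1)[
                 names(reactionStoichiometry(m11, "RuBisCO_lumped"))])
  ## every ratio 1:1..5:1 against an independently computed sum
  for (a in 1:5) {
    ml <- lumpRubisco(toy, "carb", "oxy", c(a, 1))
    oracle <- c(RuBP = 0, CO2 = 0, PGA = 0, O2 = 0, PGLY = 0)
    for (nm in names(carbSt)) oracle[nm] <- oracle[nm] + a * carbSt[nm]
    for (nm in names(oxySt)) oracle[nm] <- oracle[nm] + oxySt[nm]
    got <- reactionStoichiometry(ml, "RuBisCO_lumped")
    expect_equal(got, oracle[names(got)], info = paste0(a, ":1"))
    ## originals removed, everything else untouched
    expect_false(any(c("carb", "oxy") %in% reactionIds(ml)))
    expect_setequal(setdiff(reactionIds(ml), "RuBisCO_lumped"),
                    setdiff(reactionIds(toy), c("carb", "oxy")))
  }
  expect_error(lumpRubisco(toy, "nope", "oxy", c(1, 1)), "missing")
  expect_error(lumpRubisco(toy, "carb", "oxy", c(0, 0)), "positive")
})

test_that("lumping conserves atoms at every ratio", {
  core <- buildCoreLeafModel()
  for (a in 1:5) {
    ml <- lumpRubisco(core$model, "chl_RuBisCO_carb",
                      "chl_RuBisCO_oxy", c(a, 1))
    expect_length(elementalBalanceAudit(ml), 0)
  }
})

test_that("lumping is linear: a:b equals b * (a/b : 1)", {
  toy <- makeRubiscoToy()
  m62 <- lumpRubisco(toy, "carb", "oxy", c(6, 2))
  m31 <- lumpRubisco(toy, "carb", "oxy", c(3, 1))
  s62 <- reactionStoichiometry(m62, "RuBisCO_lumped")
  s31 <- reactionStoichiometry(m31, "RuBisCO_lumped")
  expect_equal(s62, 2 * s31[names(s62)])
})

test_that("vcvo scan reproduces the photorespiratory flux patterns", {
  core <- buildCoreLeafModel()
  sc <- vcvoScan(core$model, core$constraints,
                 lapply(1:5, function(a) c(a, 1)))
  expect_identical(sc@parameterName, "vcvo")
  expect_equal(scanValues(sc), 1:5)
  for (i in seq_along(scanSolutions(sc))) {
    sol <- scanSolutions(sc)[[i]]
    expect_identical(solutionStatus(sol), "optimal")
    ml <- lumpRubisco(core$model, "chl_RuBisCO_carb",
                      "chl_RuBisCO_oxy", c(i, 1))
    expect_lte(steadyStateResidual(ml, sol), 1e-6)
  }
  fm <- fluxMatrix(sc)
  ## malate valve exports reductant under high photorespiration and
  ## winds down monotonically toward 5:1
  valve <- abs(fm["chl_MalOxAc_tx", ])
  expect_true(all(diff(valve) <= 1e-9))
  expect_gt(valve[1], 1e-3)
  ## cytosolic GAPDH/PGK: silent at 1:1, active at 3:1
  expect_equal(unname(fm["GAPDH", "1"]), 0, tolerance = 1e-9)
  expect_equal(unname(fm["PGK", "1"]), 0, tolerance = 1e-9)
  expect_gt(fm["GAPDH", "3"], 1e-3)
  expect_gt(fm["PGK", "3"], 1e-3)
  ## photorespiratory ammonia is fully refixed by GS2 at 1:1
  expect_equal(unname(fm["mit_GDC", "1"]), unname(fm["chl_NH3_tx", "1"]),
               tolerance = 1e-8)
  expect_equal(unname(fm["chl_NH3_tx", "1"]), unname(fm["chl_GS2", "1"]),
               tolerance = 1e-8)
  ## GAPN carries the lipid NADPH demand, constant across ratios
  expect_true(all(abs(fm["GAPN", ] - 0.1) < 1e-8))
  ## photon demand falls as photorespiration declines
  expect_true(all(diff(fm["Photon_tx", ]) < 0))
})

test_that("light scan honours the coupling and drives photorespiration", {
  core <- buildCoreLeafModel()
  grid <- seq(5, 10, by = 0.5)
  sc <- lightScan(core$model, core$constraints, grid)
  expect_identical(sc@parameterName, "photon_flux")
  fm <- fluxMatrix(sc)
  statuses <- vapply(scanSolutions(sc), solutionStatus, "")
  expect_true(all(statuses == "optimal"))
  ## photon influx is pinned to the grid
  expect_equal(unname(fm["Photon_tx", ]), grid, tolerance = 1e-7)
  ## cyclic <= non-cyclic at every point
  expect_true(all(fm["chl_LightCyc", ] <=
                    fm["chl_LightNonCyc", ] + 1e-9))
  ## HPR1 (photorespiration) non-decreasing with light
  expect_true(all(diff(fm["per_HPR1", ]) >= -1e-9))
  expect_gt(fm["per_HPR1", ncol(fm)], fm["per_HPR1", 1])
})

test_that("grid below the feasibility limit is flagged infeasible", {
  core <- buildCoreLeafModel()
  sc <- lightScan(core$model, core$constraints, c(0.5, 1, 2))
  expect_true(all(vapply(scanSolutions(sc), solutionStatus, "") ==
                    "infeasible"))
})

test_that("weighted total flux is non-increasing in the photon cap", {
  core <- buildCoreLeafModel()
  objs <- vapply(c(5, 6, 8, 10), function(cap) {
    cs <- constraintSet(fixedFluxes = core$constraints@fixedFluxes,
                        boundOverrides = data.frame(id = "Photon_tx",
                                                    lower = 0,
                                                    upper = cap))
    objectiveValue(minimizeWeightedFlux(core$model, cs))
  }, 0)
  expect_true(all(diff(objs) <= 1e-7))
})

test_that("photon feasibility threshold is found by bisection", {
  fx <- buildFixtureNetwork("photon_toy", photons_per_biomass = 2,
                            demand = 0.5)
  thr <- minFeasiblePhotonFlux(fx$model, fx$constraints,
                               bracket = c(0.1, 3))
  expect_equal(thr, 1, tolerance = 1e-4)
  ## brute-force fine grid agrees within 2e-3
  grid <- seq(0.9, 1.1, by = 1e-3)
  sc <- lightScan(fx$model, fx$constraints, grid, photonId = "Photon_tx",
                  cyclicId = NULL, noncyclicId = NULL)
  st <- vapply(scanSolutions(sc), solutionStatus, "")
  bf <- grid[match("optimal", st)]
  expect_lt(abs(thr - bf), 2e-3)
  ## invalid brackets are rejected
  expect_error(minFeasiblePhotonFlux(fx$model, fx$constraints,
                                     bracket = c(1.5, 3)),
               "feasible at lower end")
  expect_error(minFeasiblePhotonFlux(fx$model, fx$constraints,
                                     bracket = c(0.1, 0.2)),
               "infeasible at upper end")
})

test_that("derived metrics follow the yield arithmetic", {
  mkSol <- function(v) new("FluxSolution", fluxes = v,
                           objectiveValue = sum(abs(v)),
                           status = "optimal")
  y <- photophosphorylationYields("nc", "cyc")
  s <- mkSol(c(nc = 1, cyc = 0, Photon_tx = 8, CO2_tx = 1))
  dm <- derivedMetrics(s, y)
  expect_equal(dm$atpTotal, 3)
  expect_equal(dm$nadphTotal, 2)
  expect_equal(dm$atpNadphRatio, 1.5)
  expect_equal(dm$quantumDemand, 8)
  ## no CO2 fixation: quantum demand undefined
  s0 <- mkSol(c(nc = 1, cyc = 1, Photon_tx = 8, CO2_tx = 0))
  expect_true(is.na(derivedMetrics(s0, y)$quantumDemand))
  ## no NADPH production: ratio undefined
  s1 <- mkSol(c(nc = 0, cyc = 1, Photon_tx = 4, CO2_tx = 1))
  expect_true(is.na(derivedMetrics(s1, y)$atpNadphRatio))
})
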