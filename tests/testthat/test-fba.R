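# The weighted L1 flux minimizer against route enumeration and its
# invariants.

test_that("chain and diamond optima match route enumeration", {
  fx <- buildFixtureNetwork("chain", n = 3, demand = 1)
  sol <- minimizeWeightedFlux(fx$model, fx$constraints)
  expect_identical(solutionStatus(sol), "optimal")
  expect_equal(objectiveValue(sol),
               enumerateRouteOptimum(list(c("in_tx", "R1", "out_tx")), 1),
               tolerance = 1e-9)
  expect_true(all(abs(fluxes(sol) - 1) < 1e-9))

  dm <- buildFixtureNetwork("diamond", demand = 1)
  routes <- list(short = c("in_tx", "R1", "out_tx"),
                 long = c("in_tx", "R2", "R3", "out_tx"))
  ds <- minimizeWeightedFlux(dm$model, dm$constraints)
  expect_equal(objectiveValue(ds), enumerateRouteOptimum(routes, 1),
               tolerance = 1e-9)   # 3 beats 4
  v <- fluxes(ds)
  expect_equal(unname(v["R1"]), 1, tolerance = 1e-9)
  expect_equal(unname(v["R2"]), 0, tolerance = 1e-9)
  expect_equal(unname(v["R3"]), 0, tolerance = 1e-9)
})

test_that("weights redirect the diamond onto the long route", {
  dm <- buildFixtureNetwork("diamond", demand = 1)
  w <- c(R1 = 10)
  sol <- minimizeWeightedFlux(dm$model, dm$constraints, weights = w)
  routes <- list(short = c("in_tx", "R1", "out_tx"),
                 long = c("in_tx", "R2", "R3", "out_tx"))
  expect_equal(objectiveValue(sol),
               enumerateRouteOptimum(routes, 1, weights = w),
               tolerance = 1e-9)   # 4 beats 12
  v <- fluxes(sol)
  expect_equal(unname(v["R1"]), 0, tolerance = 1e-9)
  expect_equal(unname(v["R2"]), 1, tolerance = 1e-9)
})

test_that("returned optimum is certified against random feasible points", {
  dm <- buildFixtureNetwork("diamond", demand = 1)
  opt <- minimizeWeightedFlux(dm$model, dm$constraints)
  w <- rep(1, length(fluxes(opt)))
  set.seed(5)
  for (i in 1:100) {
    ## random linear objectives generate scattered feasible vertices
    robj <- stats::setNames(runif(length(w), 0.01, 1),
                            reactionIds(dm$model))
    alt <- minimizeWeightedFlux(dm$model, dm$constraints, weights = robj)
    expect_identical(solutionStatus(alt), "optimal")
    expect_lte(objectiveValue(opt),
               sum(abs(fluxes(alt))) + 1e-6)
  }
})

test_that("weight scaling leaves the argmin pattern unchanged", {
  dm <- buildFixtureNetwork("diamond", demand = 1)
  s1 <- minimizeWeightedFlux(dm$model, dm$constraints)
  w <- stats::setNames(rep(7, length(reactionIds(dm$model))),
                       reactionIds(dm$model))
  s7 <- minimizeWeightedFlux(dm$model, dm$constraints, weights = w)
  expect_equal(fluxes(s7), fluxes(s1), tolerance = 1e-9)
  expect_equal(objectiveValue(s7), 7 * objectiveValue(s1),
               tolerance = 1e-9)
})

test_that("zero demand with zero maintenance yields the zero flux vector", {
  fx <- buildFixtureNetwork("diamond", demand = 0)
  sol <- minimizeWeightedFlux(fx$model, fx$constraints)
  expect_identical(solutionStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 0)
  expect_true(all(fluxes(sol) == 0))
})

test_that("every optimal solution satisfies steady state", {
  models <- list(buildFixtureNetwork("chain", n = 5),
                 buildFixtureNetwork("k_parallel", k = 4),
                 buildCoreLeafModel())
  for (fx in models) {
    m <- if (is.null(fx$model@annotations$generator) ||
             fx$model@annotations$generator != "core_leaf") fx$model
         else lumpRubisco(fx$model, "chl_RuBisCO_carb",
                          "chl_RuBisCO_oxy", c(3, 1))
    sol <- minimizeWeightedFlux(m, fx$constraints)
    expect_identical(solutionStatus(sol), "optimal")
    expect_lte(steadyStateResidual(m, sol), 1e-6)
  }
})

test_that("biomass composition fixes transporters and maintenance", {
  core <- buildCoreLeafModel()
  cs <- applyBiomassComposition(core$model,
                                c(biomass_GAP_tx = 0.2,
                                  biomass_Lipid_tx = 0.01))
  m31 <- lumpRubisco(core$model, "chl_RuBisCO_carb", "chl_RuBisCO_oxy",
                     c(3, 1))
  sol <- minimizeWeightedFlux(m31, cs)
  v <- fluxes(sol)
  expect_equal(unname(v["biomass_GAP_tx"]), 0.2, tolerance = 1e-9)
  expect_equal(unname(v["ATPase_maintenance"]), 0.1, tolerance = 1e-9)
  ## unknown / non-biomass ids and negative fluxes are rejected
  expect_error(applyBiomassComposition(core$model, c(nope_tx = 1)),
               "unknown")
  expect_error(applyBiomassComposition(core$model, c(GAPDH = 1)),
               "not a biomass transporter")
  expect_error(applyBiomassComposition(core$model,
                                       c(biomass_GAP_tx = -0.1)),
               "nonnegative")
})

test_that("maintenance-only demand pulls exactly the hand-computed photons", {
  ## toy yields 1 ATP per 2 photons, so maintenance 0.1 needs 0.2
  toy <- makePhotonAtpToy()
  sol <- minimizeWeightedFlux(toy, constraintSet(maintenanceFlux = 0.1))
  expect_identical(solutionStatus(sol), "optimal")
  expect_equal(unname(fluxes(sol)["Photon_tx"]), 0.2, tolerance = 1e-9)
})

test_that("unachievable composition under a photon cap is infeasible", {
  toy <- makePhotonAtpToy()
  cs <- constraintSet(maintenanceFlux = 1,
                      boundOverrides = data.frame(id = "Photon_tx",
                                                  lower = 0, upper = 1))
  sol <- minimizeWeightedFlux(toy, cs)
  expect_identical(solutionStatus(sol), "infeasible")
})
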