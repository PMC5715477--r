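# Random-weight ensembles: draw determinism, exclusion rules, mode
# signatures, and recovery of analytic mode frequencies on symmetric
# fixtures.

test_that("weight draws are seeded, bounded and exclusion-aware", {
  core <- buildCoreLeafModel()
  w1 <- drawWeights(core$model, seed = 42)
  w2 <- drawWeights(core$model, seed = 42)
  expect_identical(w1$weights, w2$weights)
  w3 <- drawWeights(core$model, seed = 43)
  expect_false(identical(w1$weights, w3$weights))
  expect_true(all(w1$weights >= 0 & w1$weights <= 1000))
  ## transporters, exchanges, photophosphorylation, maintenance are
  ## pinned at the baseline
  cats <- reactionCategories(core$model)
  excluded <- names(cats)[cats != "metabolic"]
  expect_true(all(w1$weights[excluded] == 1))
  expect_setequal(w1$excluded, excluded)
  ## a model made only of transporters draws no random weights
  fx <- buildFixtureNetwork("chain", n = 2)   # import + drain only
  wAll <- drawWeights(fx$model, seed = 1)
  expect_true(all(wAll$weights == 1))
})

test_that("uniform draws have the right moments", {
  fx <- buildFixtureNetwork("chain", n = 3)
  draws <- vapply(seq_len(1e4), function(i)
    drawWeights(fx$model, seed = i)$weights[["R1"]], 0)
  ## mean within 3 sigma of 500 (sigma = 1000 / sqrt(12 n))
  se <- 1000 / sqrt(12 * 1e4)
  expect_lt(abs(mean(draws) - 500), 3 * se)
})

test_that("mode signatures apply the dead zone componentwise", {
  sol <- new("FluxSolution",
             fluxes = c(T1 = 0.5, T2 = 0, T3 = -1e-12, T4 = -0.2),
             objectiveValue = 0, status = "optimal")
  expect_identical(computeModeSignature(sol, c("T1", "T2", "T3")),
                   "+00")
  expect_identical(computeModeSignature(sol, c("T4", "T1")), "-+")
  neg <- new("FluxSolution", fluxes = -fluxes(sol),
             objectiveValue = 0, status = "optimal")
  expect_identical(computeModeSignature(neg, c("T1", "T2", "T3", "T4")),
                   "-00+")
  zero <- new("FluxSolution", fluxes = c(T1 = 0, T2 = 0),
              objectiveValue = 0, status = "optimal")
  expect_identical(computeModeSignature(zero, c("T1", "T2")), "00")
  expect_error(computeModeSignature(sol, "T9"), "missing")
})

test_that("single iteration on a chain gives exactly one mode", {
  fx <- buildFixtureNetwork("chain", n = 3)
  ms <- runEnsemble(fx$model, fx$constraints, n = 1, masterSeed = 1,
                    tracked = "R1")
  expect_equal(sum(ms@counts), 1)
  expect_identical(ms@signatures, "+")
})

test_that("ensembles are reproducible and conserve counts", {
  fx <- buildFixtureNetwork("k_parallel", k = 3)
  a <- runEnsemble(fx$model, fx$constraints, n = 50, masterSeed = 123,
                   tracked = c("R1", "R2", "R3"))
  b <- runEnsemble(fx$model, fx$constraints, n = 50, masterSeed = 123,
                   tracked = c("R1", "R2", "R3"))
  expect_identical(modeCounts(a), modeCounts(b))
  expect_equal(sum(a@counts) + a@infeasibleCount, a@nIterations)
})

test_that("equal-cost two-path frequencies match the symmetry argument", {
  ## the optimizer picks the arm with the smaller iid uniform weight,
  ## so P(R1 active) = 1/2
  fx <- buildFixtureNetwork("equal_parallel")
  n <- 2000
  ms <- runEnsemble(fx$model, fx$constraints, n = n, masterSeed = 99,
                    tracked = "R1")
  expect_equal(ms@infeasibleCount, 0L)
  f <- modeCounts(ms)[["+"]] / n
  se <- sqrt(0.25 / n)
  expect_lt(abs(f - 0.5), 3 * se)
})

test_that("three equal arms are each active about a third of the time", {
  fx <- buildFixtureNetwork("k_parallel", k = 3)
  n <- 3000
  ms <- runEnsemble(fx$model, fx$constraints, n = n, masterSeed = 7,
                    tracked = c("R1", "R2", "R3"))
  mc <- modeCounts(ms)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  for (sig in c("+00", "0+0", "00+"))
    expect_lt(abs(mc[[sig]] / n - 1 / 3), 3 * se)
})

test_that("equal weights give the same objective every iteration", {
  fx <- buildFixtureNetwork("diamond")
  ms <- runEnsemble(fx$model, fx$constraints, n = 5, masterSeed = 1,
                    tracked = "R1", range = c(1, 1), archive = TRUE)
  arch <- attr(ms, "archive")
  objs <- colSums(abs(arch))
  expect_true(all(abs(objs - objs[1]) < 1e-9))
})
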