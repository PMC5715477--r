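# Flux-parameter correlation, strength bands and strong-set
# comparison.

mkScan <- function(param, fluxMat) {
  sols <- lapply(seq_along(param), function(j)
    new("FluxSolution", fluxes = fluxMat[, j],
        objectiveValue = sum(abs(fluxMat[, j])), status = "optimal"))
  new("ScanResult", parameterName = "vcvo", values = param,
      solutions = sols)
}

test_that("linear, anti-linear and orthogonal series correlate as expected", {
  p <- 1:5
  fm <- rbind(lin = c(2, 4, 6, 8, 10),
              anti = c(10, 8, 6, 4, 2),
              orth = c(1, 2, 1, 2, 1),
              const = rep(3, 5))
  ct <- correlateScan(mkScan(p, fm))
  expect_equal(ct$entries[["lin"]], 1, tolerance = 1e-12)
  expect_equal(ct$entries[["anti"]], 1, tolerance = 1e-12)
  expect_equal(ct$entries[["orth"]], 0, tolerance = 1e-12)
  expect_identical(ct$excludedConstant, "const")
  expect_true(all(ct$entries >= 0 & ct$entries <= 1))
})

test_that("correlation agrees with a two-pass covariance oracle", {
  set.seed(31)
  p <- sort(runif(8, 1, 10))
  fm <- matrix(rnorm(5 * 8), 5, 8,
               dimnames = list(paste0("R", 1:5), NULL))
  ct <- correlateScan(mkScan(p, fm))
  for (i in 1:5)
    expect_equal(ct$entries[[paste0("R", i)]],
                 abs(twoPassPearson(fm[i, ], p)), tolerance = 1e-12)
})

test_that("|r| is invariant under affine rescaling of either series", {
  p <- 1:6
  x <- c(3, 1, 4, 1, 5, 9)
  fm <- rbind(a = x, b = 2.5 * x - 7)
  ct <- correlateScan(mkScan(p, fm))
  expect_equal(ct$entries[["a"]], ct$entries[["b"]], tolerance = 1e-12)
  ## negative slope flips the sign but not |r|
  fm2 <- rbind(a = x, b = -0.3 * x + 2)
  ct2 <- correlateScan(mkScan(p, fm2))
  expect_equal(ct2$entries[["a"]], ct2$entries[["b"]], tolerance = 1e-12)
})

test_that("infeasible points are dropped pairwise and 3 points required", {
  p <- 1:4
  fm <- rbind(lin = c(1, 2, 3, 4))
  scan <- mkScan(p, fm)
  scan@solutions[[2]] <- new("FluxSolution",
                             fluxes = c(lin = NA_real_),
                             objectiveValue = NA_real_,
                             status = "infeasible")
  ct <- correlateScan(scan)
  expect_equal(ct$entries[["lin"]], 1, tolerance = 1e-12)
  scan@solutions[[3]] <- scan@solutions[[2]]
  expect_error(correlateScan(scan), "at least 3")
})

test_that("strength bands classify with a closed lower strong edge", {
  ct <- structure(list(entries = c(a = 0.95, b = 0.9, c = 0.6,
                                   d = 0.1, e = 0.8999),
                       excludedConstant = character(0)),
                  class = "CorrelationTable")
  cls <- classifyCorrelationStrength(ct)
  expect_identical(unname(cls[c("a", "b", "c", "d", "e")]),
                   c("strong", "strong", "moderate", "weak", "moderate"))
})

test_that("strong-set comparison partitions deterministically", {
  ta <- structure(list(entries = c(x = 0.99, y = 0.95, z = 0.2),
                       excludedConstant = character(0)),
                  class = "CorrelationTable")
  expect_identical(compareStrongSets(ta, ta),
                   list(onlyA = character(0), onlyB = character(0),
                        both = c("x", "y")))
  tb <- structure(list(entries = c(x = 0.1, y = 0.2, w = 0.95),
                       excludedConstant = character(0)),
                  class = "CorrelationTable")
  out <- compareStrongSets(ta, tb)
  expect_identical(out$onlyA, c("x", "y"))
  expect_identical(out$onlyB, "w")
  expect_identical(out$both, character(0))
})

test_that("scan correlations on the core model are computed end to end", {
  core <- buildCoreLeafModel()
  sc <- vcvoScan(core$model, core$constraints,
                 lapply(1:5, function(a) c(a, 1)))
  ct <- correlateScan(sc)
  ## photorespiratory fluxes fall hyperbolically in Vc/Vo, so the
  ## linear correlation is substantial but below the strong band
  expect_gt(ct$entries[["per_HPR1"]], 0.7)
  expect_gt(ct$entries[["mit_GDC"]], 0.7)
  ## fixed drains and the lipid-coupled GAPN are constant -> excluded
  expect_true("biomass_GAP_tx" %in% ct$excludedConstant)
  expect_true("GAPN" %in% ct$excludedConstant)
  ## against light the photorespiratory response is linear: strong
  ls <- lightScan(core$model, core$constraints, seq(5, 10, by = 1))
  cl <- correlateScan(ls)
  expect_gt(cl$entries[["per_HPR1"]], 0.99)
  both <- compareStrongSets(ct, cl)
  expect_true("per_HPR1" %in% c(both$onlyB, both$both))
})
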