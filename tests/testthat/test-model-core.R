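# Equation parsing, compartment inference, model construction,
# tabular and SBML round trips, and count statistics.

test_that("reaction equations parse per the grammar", {
  p <- parseReactionEquation("A + 2 B -> C")
  expect_equal(p$stoichiometry, c(A = -1, B = -2, C = 1))
  expect_false(p$reversible)

  p2 <- parseReactionEquation("A <> B")
  expect_equal(p2$stoichiometry, c(A = -1, B = 1))
  expect_true(p2$reversible)

  ## fractions are exact; both-side species are summed
  p3 <- parseReactionEquation("1/2 A + B -> A + C")
  expect_equal(p3$stoichiometry, c(A = 0.5, B = -1, C = 1))

  expect_error(parseReactionEquation("A -> A"), "zero net")
  expect_error(parseReactionEquation("A -- B"), "arrow")
  expect_error(parseReactionEquation("A + -> B"), "malformed")
})

test_that("parse/unparse are mutually inverse", {
  eqs <- c("A + 2 B -> C", "A <> B", "3 chl_X + 0.25 Y -> 2 Z",
           "GAP ->", "-> chl_Photon", "2 per_H2O2 -> 2 per_H2O + per_O2")
  for (eq in eqs) {
    p <- parseReactionEquation(eq)
    round <- parseReactionEquation(
      buildReactionEquation(p$stoichiometry, p$reversible))
    expect_equal(sort(names(round$stoichiometry)),
                 sort(names(p$stoichiometry)))
    expect_equal(round$stoichiometry[names(p$stoichiometry)],
                 p$stoichiometry)
    expect_identical(round$reversible, p$reversible)
  }
})

test_that("compartment inference is total and prefix-driven", {
  ids <- c("chl_GAP", "mit_NADH", "per_H2O2", "GAP", "ext_X", "weird")
  cc <- compartmentFromId(ids)
  expect_identical(cc, c("chloroplast", "mitochondrion", "peroxisome",
                         "cytosol", "external", "cytosol"))
  core <- buildCoreLeafModel()
  expect_false(anyNA(metaboliteCompartments(core$model)))
})

test_that("model tables load with defaults, and reject bad input", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\tlower_bound\tupper_bound\tcategory\tgenes",
               "in_tx\t-> A\t\t\texchange\t",
               "R1\tA -> B\t\t\t\tg1|g2",
               "out_tx\tB ->\t\t\tbiomass_transporter\t"), tf)
  m <- readModelTable(tf)
  expect_s4_class(m, "MetabolicModel")
  expect_equal(length(reactionIds(m)), 3)
  expect_equal(length(metaboliteIds(m)), 2)
  expect_equal(unname(reactionBounds(m)$lower), c(0, 0, 0))
  expect_identical(unname(reactionCategories(m)["R1"]), "metabolic")

  writeLines(c("reaction_id\tequation", "R1\tA -> B", "R1\tB -> C"), tf)
  expect_error(readModelTable(tf), "duplicate")
  writeLines(c("reaction_id\tequation\tlower_bound\tupper_bound",
               "R1\tA -> B\t5\t1"), tf)
  expect_error(readModelTable(tf), "inverted")
})

test_that("tabular serialization round-trips generated models", {
  for (fx in list(buildFixtureNetwork("diamond"),
                  buildCoreLeafModel())) {
    m <- fx$model
    tf <- tempfile(); mf <- tempfile()
    writeModelTable(m, tf, mf)
    m2 <- readModelTable(tf, mf)
    expect_setequal(reactionIds(m2), reactionIds(m))
    expect_setequal(metaboliteIds(m2), metaboliteIds(m))
    S1 <- as.matrix(stoichiometricMatrix(m))
    S2 <- as.matrix(stoichiometricMatrix(m2))[rownames(S1), colnames(S1)]
    expect_equal(S2, S1)
    b1 <- reactionBounds(m); b2 <- reactionBounds(m2)
    expect_equal(b2[match(b1$id, b2$id), c("lower", "upper")],
                 b1[, c("lower", "upper")], ignore_attr = TRUE)
    expect_identical(reactionCategories(m2)[reactionIds(m)],
                     reactionCategories(m))
    ## compositions survive the sidecar
    expect_equal(elementalCompositions(m2)[["CO2"]],
                 elementalCompositions(m)[["CO2"]])
  }
})

test_that("SBML export/import preserves stoichiometry, bounds, category", {
  m <- buildCoreLeafModel()$model
  sf <- tempfile(fileext = ".xml")
  writeSBML(m, sf)
  m2 <- readSBML(sf)
  S1 <- as.matrix(stoichiometricMatrix(m))
  S2 <- as.matrix(stoichiometricMatrix(m2))[rownames(S1), colnames(S1)]
  expect_equal(S2, S1)
  b1 <- reactionBounds(m); b2 <- reactionBounds(m2)
  expect_equal(b2[match(b1$id, b2$id), c("lower", "upper")],
               b1[, c("lower", "upper")], ignore_attr = TRUE)
  expect_identical(reactionCategories(m2)[reactionIds(m)],
                   reactionCategories(m))
})

test_that("model statistics count exactly", {
  empty <- leafFBA:::.buildModel(list())
  st0 <- modelStatistics(empty)
  expect_equal(st0$reactionCountTotal, 0)
  expect_equal(st0$metaboliteCountTotal, 0)

  core <- buildCoreLeafModel()
  st <- modelStatistics(core$model)
  mf <- core$manifest$counts
  expect_equal(st$reactionCountTotal, mf$reactions)
  expect_equal(st$metaboliteCountTotal, mf$metabolites)
  for (cat in names(mf$per_category))
    expect_equal(st$perCategoryCounts[[cat]], mf$per_category[[cat]],
                 info = cat)
  for (cp in names(mf$metabolic_per_compartment))
    expect_equal(st$perCompartmentCounts[[cp]],
                 mf$metabolic_per_compartment[[cp]], info = cp)
  ## per-compartment metabolic counts sum to the metabolic total
  expect_equal(Reduce(`+`, st$perCompartmentCounts),
               st$perCategoryCounts$metabolic)
})

test_that("duplicate reaction ids and empty stoichiometries are rejected", {
  defs <- list(list(id = "R1", stoichiometry = c(A = -1, B = 1),
                    lower = 0, upper = 10, category = "metabolic",
                    genes = character(0)))
  expect_error(leafFBA:::.buildModel(c(defs, defs)), "duplicate")
  bad <- list(list(id = "R0", stoichiometry = numeric(0), lower = 0,
                   upper = 1, category = "metabolic",
                   genes = character(0)))
  expect_error(leafFBA:::.buildModel(bad), "empty stoichiometry")
})
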