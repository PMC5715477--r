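#' @include fba.R consistency.R
NULL

## ---------------------------------------------------------------------
## Synthetic test-bed generators: a curated four-compartment core leaf
## network engineered to exhibit the qualitative behaviors of
## photorespiratory leaf metabolism, plus micro-fixtures with
## analytically known optima and deliberately broken variants.
## ---------------------------------------------------------------------

## Simplified elemental formulas (C,H,N,O,P,S only; redox couples
## balanced as NAD(P)H = NAD(P) + H2, phosphoryl transfer as
## ATP = ADP + HPO3, Pi = H3PO4).  Photons and the proton-motive-force
## quantum are massless.
.CORE_FORMULAS <- c(
  Photon = "", PMF = "",
  CO2 = "CO2", O2 = "O2", H2O = "H2O", H2O2 = "H2O2",
  NH3 = "H3N", NO3 = "HNO3", SO4 = "H2O4S", Pi = "H3O4P",
  ATP = "C10H14N5O13P3", ADP = "C10H13N5O10P2",
  NAD = "C21H26N7O14P2", NADH = "C21H28N7O14P2",
  NADP = "C21H25N7O17P3", NADPH = "C21H27N7O17P3",
  GAP = "C3H7O6P", DHAP = "C3H7O6P", BPGA = "C3H8O10P2",
  PGA = "C3H7O7P", RuBP = "C5H12O11P2", Ru5P = "C5H11O8P",
  PGLY = "C2H5O6P", Glycolate = "C2H4O3", Glyoxylate = "C2H2O3",
  Gly = "C2H5NO2", Ser = "C3H7NO3", OHPyr = "C3H4O4",
  Glycerate = "C3H6O4", Mal = "C4H6O5", OAA = "C4H4O5",
  AKG = "C5H6O5", Glu = "C5H9NO4", Gln = "C5H10N2O3",
  Asc = "C6H8O6", MDA = "C6H7O6", Lipid = "C12H24O2")

#' Options for the synthetic core leaf model
#'
#' @param include_gs1 add the cytosolic glutamine synthetase isoform
#'   (GS1).  Off by default so the photorespiratory ammonia refixation
#'   route through chloroplastic GS2 is unique in plain FBA; switch on
#'   for ensemble analyses of the Glu-Gln transporter modes.
#' @param include_glutathione_ascorbate add the peroxisomal
#'   ascorbate-peroxidase / monodehydroascorbate-reductase pair as the
#'   alternative to catalase for photorespiratory H2O2.
#' @param include_aox add the mitochondrial alternative oxidase, which
#'   dissipates NADH without proton pumping.
#' @param biomass named fixed fluxes of the biomass transporters
#'   (carbon-only drains: triose phosphate and a lipid precursor).
#' @param maintenanceFlux maintenance ATPase demand, default 0.1.
#' @return list of options for [buildCoreLeafModel()].
#' @export
coreLeafOptions <- function(include_gs1 = FALSE,
                            include_glutathione_ascorbate = TRUE,
                            include_aox = TRUE,
                            biomass = c(biomass_GAP_tx = 0.11,
                                        biomass_Lipid_tx = 0.01),
                            maintenanceFlux = 0.1) {
  list(include_gs1 = include_gs1,
       include_glutathione_ascorbate = include_glutathione_ascorbate,
       include_aox = include_aox,
       biomass = biomass,
       maintenanceFlux = maintenanceFlux)
}

#' Build the synthetic four-compartment core leaf model
#'
#' A curated ~70-reaction network spanning cytosol, chloroplast,
#' mitochondrion and peroxisome: lumped cyclic/non-cyclic
#' photophosphorylation, RuBisCO carboxylation and oxygenation, a
#' condensed Calvin cycle (PGK, NADP-GAPDH, TPI, a lumped regeneration
#' step, Ru5P kinase), glycerate kinase, GS2/GOGAT, the NADP-malate
#' valve, triose-phosphate transporters, the full photorespiratory
#' chain (phosphoglycolate phosphatase, glycolate oxidase with H2O2
#' production, catalase and an optional glutathione-ascorbate
#' alternative, SGAT/GGT aminotransferases, HPR1, glycine
#' decarboxylase), a mitochondrial ETC with COX and optional AOX
#' branches and complex V, cytosolic GAPDH/PGK, GAPN, malate
#' dehydrogenases in all four compartments with Mal-OAA shuttles, a
#' Glu-Gln antiporter with optional cytosolic GS1, nutrient exchanges
#' and carbon-only biomass drains plus a maintenance ATPase.  All
#' metabolites carry simplified elemental formulas so the network is
#' fully auditable; in balanced mode it has no leaks and no
#' energy-generating cycle.
#'
#' @param options list from [coreLeafOptions()].
#' @return list with elements \code{model} (a
#'   [MetabolicModel-class]), \code{constraints} (the default
#'   [ConstraintSet-class] fixing the biomass composition), and
#'   \code{manifest} (declared counts and expected behaviors).
#' @seealso [buildFixtureNetwork()], [makeBrokenVariant()]
#' @export
buildCoreLeafModel <- function(options = coreLeafOptions()) {
  B <- .BIG
  rx <- function(id, eq, cat, lo = NULL, hi = B) {
    pe <- parseReactionEquation(eq)
    if (is.null(lo)) lo <- if (pe$reversible) -B else 0
    list(id = id, stoichiometry = pe$stoichiometry, lower = lo,
         upper = hi, category = cat, genes = character(0))
  }
  defs <- list(
    ## --- exchanges ---------------------------------------------------
    rx("Photon_tx", "-> chl_Photon", "exchange"),
    rx("CO2_tx", "-> CO2", "exchange"),
    rx("O2_tx", "<> O2", "exchange"),
    rx("H2O_tx", "<> H2O", "exchange"),
    rx("NH3_tx", "-> NH3", "exchange"),
    rx("NO3_tx", "-> NO3", "exchange"),
    rx("Pi_tx", "-> Pi", "exchange"),
    rx("SO4_tx", "-> SO4", "exchange"),
    ## --- biomass + maintenance --------------------------------------
    rx("biomass_GAP_tx", "GAP ->", "biomass_transporter"),
    rx("biomass_Lipid_tx", "Lipid ->", "biomass_transporter"),
    rx("ATPase_maintenance", "ATP + H2O -> ADP + Pi", "maintenance"),
    ## --- chloroplast: photophosphorylation (lumped) -----------------
    rx("chl_LightNonCyc",
       paste("8 chl_Photon + 2 chl_NADP + 3 chl_ADP + 3 chl_Pi ->",
             "2 chl_NADPH + 3 chl_ATP + chl_O2 + chl_H2O"),
       "photophosphorylation"),
    rx("chl_LightCyc",
       "4 chl_Photon + 2 chl_ADP + 2 chl_Pi -> 2 chl_ATP + 2 chl_H2O",
       "photophosphorylation"),
    ## --- chloroplast: Calvin cycle + photorespiration entry ---------
    rx("chl_RuBisCO_carb",
       "chl_RuBP + chl_CO2 + chl_H2O -> 2 chl_PGA", "metabolic"),
    rx("chl_RuBisCO_oxy",
       "chl_RuBP + chl_O2 -> chl_PGA + chl_PGLY", "metabolic"),
    rx("chl_PGP", "chl_PGLY + chl_H2O -> chl_Glycolate + chl_Pi",
       "metabolic"),
    rx("chl_PGK", "chl_PGA + chl_ATP -> chl_BPGA + chl_ADP",
       "metabolic"),
    rx("chl_GAPDH",
       "chl_BPGA + chl_NADPH -> chl_GAP + chl_NADP + chl_Pi",
       "metabolic"),
    rx("chl_TPI", "chl_GAP <> chl_DHAP", "metabolic"),
    rx("chl_CalvinRegen",
       "3 chl_GAP + 2 chl_DHAP + 2 chl_H2O -> 3 chl_Ru5P + 2 chl_Pi",
       "metabolic"),
    rx("chl_Ru5Pk", "chl_Ru5P + chl_ATP -> chl_RuBP + chl_ADP",
       "metabolic"),
    rx("chl_GLYK", "chl_Glycerate + chl_ATP -> chl_PGA + chl_ADP",
       "metabolic"),
    ## --- chloroplast: malate valve + nitrogen ------------------------
    ## NADP-MDH is light-activated and operates in the reduction
    ## direction only, so the malate valve can export but not import
    ## reducing equivalents
    rx("chl_MalDH", "chl_OAA + chl_NADPH -> chl_Mal + chl_NADP",
       "metabolic"),
    rx("chl_GS2", "chl_Glu + chl_NH3 + chl_ATP -> chl_Gln + chl_ADP + chl_Pi",
       "metabolic"),
    rx("chl_GOGAT",
       "chl_Gln + chl_AKG + chl_NADPH -> 2 chl_Glu + chl_NADP",
       "metabolic"),
    ## --- chloroplast envelope transporters ---------------------------
    rx("chl_CO2_tx", "CO2 <> chl_CO2", "intracellular_transporter"),
    rx("chl_O2_tx", "O2 <> chl_O2", "intracellular_transporter"),
    rx("chl_H2O_tx", "H2O <> chl_H2O", "intracellular_transporter"),
    rx("chl_GAP_tx", "GAP + chl_Pi <> chl_GAP + Pi",
       "intracellular_transporter"),
    rx("chl_DHAP_tx", "DHAP + chl_Pi <> chl_DHAP + Pi",
       "intracellular_transporter"),
    rx("chl_PGA_tx", "PGA + chl_Pi <> chl_PGA + Pi",
       "intracellular_transporter"),
    rx("chl_MalOxAc_tx", "OAA + chl_Mal <> chl_OAA + Mal",
       "intracellular_transporter"),
    rx("chl_Mal2OG_tx", "AKG + chl_Mal <> chl_AKG + Mal",
       "intracellular_transporter"),
    rx("chl_MalGlu_tx", "Glu + chl_Mal <> chl_Glu + Mal",
       "intracellular_transporter"),
    rx("chl_GlnGlu_tx", "Glu + chl_Gln <> chl_Glu + Gln",
       "intracellular_transporter"),
    rx("chl_NH3_tx", "NH3 <> chl_NH3", "intracellular_transporter"),
    rx("chl_Glycolate_tx", "Glycolate <> chl_Glycolate",
       "intracellular_transporter"),
    rx("chl_Glycerate_tx", "Glycerate <> chl_Glycerate",
       "intracellular_transporter"),
    ## --- peroxisome ---------------------------------------------------
    rx("per_GOX", "per_Glycolate + per_O2 -> per_Glyoxylate + per_H2O2",
       "metabolic"),
    rx("per_CAT", "2 per_H2O2 -> 2 per_H2O + per_O2", "metabolic"),
    rx("per_SGAT", "per_Glyoxylate + per_Ser -> per_Gly + per_OHPyr",
       "metabolic"),
    rx("per_GGT", "per_Glyoxylate + per_Glu -> per_Gly + per_AKG",
       "metabolic"),
    rx("per_HPR1", "per_OHPyr + per_NADH -> per_Glycerate + per_NAD",
       "metabolic"),
    rx("per_MDH", "per_Mal + per_NAD <> per_OAA + per_NADH",
       "metabolic"),
    rx("per_Glycolate_tx", "Glycolate <> per_Glycolate",
       "intracellular_transporter"),
    rx("per_Glycerate_tx", "Glycerate <> per_Glycerate",
       "intracellular_transporter"),
    rx("per_Gly_tx", "Gly <> per_Gly", "intracellular_transporter"),
    rx("per_Ser_tx", "Ser <> per_Ser", "intracellular_transporter"),
    rx("per_MalOxAc_tx", "Mal + per_OAA <> per_Mal + OAA",
       "intracellular_transporter"),
    rx("per_GluAKG_tx", "Glu + per_AKG <> per_Glu + AKG",
       "intracellular_transporter"),
    rx("per_O2_tx", "O2 <> per_O2", "intracellular_transporter"),
    rx("per_H2O_tx", "H2O <> per_H2O", "intracellular_transporter"),
    ## --- mitochondrion ------------------------------------------------
    rx("mit_GDC",
       "2 mit_Gly + mit_NAD + mit_H2O -> mit_Ser + mit_CO2 + mit_NH3 + mit_NADH",
       "metabolic"),
    rx("mit_MalDH", "mit_Mal + mit_NAD <> mit_OAA + mit_NADH",
       "metabolic"),
    rx("mit_ETC_COX",
       "2 mit_NADH + mit_O2 -> 2 mit_NAD + 2 mit_H2O + 10 mit_PMF",
       "metabolic"),
    rx("mit_ComplexV", "3 mit_PMF + mit_ADP + mit_Pi -> mit_ATP + mit_H2O",
       "metabolic"),
    rx("mit_Gly_tx", "Gly <> mit_Gly", "intracellular_transporter"),
    rx("mit_Ser_tx", "Ser <> mit_Ser", "intracellular_transporter"),
    rx("mit_NH3_tx", "NH3 <> mit_NH3", "intracellular_transporter"),
    rx("mit_CO2_tx", "CO2 <> mit_CO2", "intracellular_transporter"),
    rx("mit_O2_tx", "O2 <> mit_O2", "intracellular_transporter"),
    rx("mit_H2O_tx", "H2O <> mit_H2O", "intracellular_transporter"),
    rx("mit_Pi_tx", "Pi <> mit_Pi", "intracellular_transporter"),
    rx("mit_MalOxAc_tx", "Mal + mit_OAA <> mit_Mal + OAA",
       "intracellular_transporter"),
    rx("mit_ATP_tx", "ATP + mit_ADP <> mit_ATP + ADP",
       "intracellular_transporter"),
    ## --- cytosol ------------------------------------------------------
    rx("GAPDH", "GAP + NAD + Pi <> BPGA + NADH", "metabolic"),
    rx("PGK", "BPGA + ADP <> PGA + ATP", "metabolic"),
    rx("GAPN", "GAP + NADP + H2O -> PGA + NADPH", "metabolic"),
    rx("MDH", "OAA + NADH <> Mal + NAD", "metabolic"),
    rx("FAS",
       "4 GAP + 10 NADPH -> Lipid + 4 Pi + 6 H2O + 10 NADP",
       "metabolic"),
    rx("Glutaminase", "Gln + H2O -> Glu + NH3", "metabolic"))
  if (options$include_glutathione_ascorbate)
    defs <- c(defs, list(
      rx("per_APX", "per_H2O2 + 2 per_Asc -> 2 per_MDA + 2 per_H2O",
         "metabolic"),
      rx("per_MDAR", "2 per_MDA + per_NADH -> 2 per_Asc + per_NAD",
         "metabolic")))
  if (options$include_aox)
    defs <- c(defs, list(
      rx("mit_AOX", "2 mit_NADH + mit_O2 -> 2 mit_NAD + 2 mit_H2O",
         "metabolic")))
  if (options$include_gs1)
    defs <- c(defs, list(
      rx("GS1", "Glu + NH3 + ATP -> Gln + ADP + Pi", "metabolic")))

  ## compositions: every compartmental instance shares the base formula
  metIds <- unique(unlist(lapply(defs, function(d) names(d$stoichiometry))))
  base <- sub("^(chl_|mit_|per_)", "", metIds)
  comp <- lapply(base, function(b) .parseFormula(.CORE_FORMULAS[[b]]))
  names(comp) <- metIds

  model <- .buildModel(defs, composition = comp,
                       annotations = list(generator = "core_leaf",
                                          options = options))
  validObject(model)
  constraints <- applyBiomassComposition(model, options$biomass,
                                         options$maintenanceFlux)

  ## manifest counts tallied independently from the definition list
  cats <- vapply(defs, `[[`, "", "category")
  compartmentOfRxn <- vapply(defs, function(d) {
    cc <- unique(compartmentFromId(names(d$stoichiometry)))
    if (length(cc) == 1) cc else "mixed"
  }, "")
  manifest <- list(
    model_id = "core_leaf",
    options = options,
    counts = list(
      reactions = length(defs),
      metabolites = length(metIds),
      per_category = as.list(table(cats)),
      metabolic_per_compartment =
        as.list(table(compartmentOfRxn[cats == "metabolic"]))),
    behaviors = list(
      list(id = "balanced",
           description = "no leaking metabolites, no energy-generating cycle in the closed system",
           regime = "consistency checks on the unmodified model"),
      list(id = "malate-valve-vs-vcvo",
           description = "|chl_MalOxAc_tx| non-increasing as Vc/Vo goes 1:1 -> 5:1",
           regime = "vcvo scan, default biomass"),
      list(id = "gapdh-pgk-switch",
           description = "cytosolic GAPDH and PGK carry zero flux at Vc/Vo = 1:1 and positive flux at 3:1",
           regime = "vcvo scan, default biomass"),
      list(id = "gs2-refixation",
           description = "at Vc/Vo = 1:1 the GDC ammonia production equals the chloroplast NH3 import and the GS2 flux",
           regime = "vcvo scan point 1:1, include_gs1 = FALSE"),
      list(id = "gapn-constant",
           description = "GAPN flux equals 10 x lipid drain at every Vc/Vo ratio",
           regime = "vcvo scan, default biomass"),
      list(id = "hpr1-light",
           description = "per_HPR1 flux non-decreasing across the upper light grid",
           regime = "light scan, photon flux 5..10"),
      list(id = "cyclic-coupling",
           description = "cyclic photophosphorylation flux <= non-cyclic at every optimal light point",
           regime = "light scan with coupling"),
      list(id = "catalase-alternative",
           description = "the glutathione-ascorbate pair is a feasible alternative to catalase: with catalase closed the LP stays optimal and APX/MDAR carry the photorespiratory H2O2 flux; under random enzymatic costs catalase dominates",
           regime = "Vc/Vo 3:1, include_glutathione_ascorbate = TRUE"),
      list(id = "glu-gln-modes",
           description = "the chloroplastic Glu-Gln transporter shows multiple ensemble modes and whenever GS1 is active it imports Gln into the chloroplast",
           regime = "ensemble at Vc/Vo 3:1, include_gs1 = TRUE")))
  list(model = model, constraints = constraints, manifest = manifest)
}

#' Build a micro fixture network with a known optimum
#'
#' Five named micro-networks whose flux-minimizing optima are known in
#' closed form; the manifest records the expected objective so tests
#' can assert against enumeration rather than the solver itself.
#'
#' \describe{
#'   \item{chain}{\code{n} reactions in a line (import, n-2
#'     conversions, demand drain); optimum \code{n * demand}.}
#'   \item{diamond}{two routes A->B, one direct (1 step) and one via C
#'     (2 steps); optimum \code{3 * demand} through the short arm.}
#'   \item{equal_parallel}{two identical single reactions A->B;
#'     degenerate optimum \code{3 * demand}, each arm's FVA range is
#'     \code{[0, demand]}.}
#'   \item{k_parallel}{\code{k} identical arms.}
#'   \item{photon_toy}{biomass requires
#'     \code{photons_per_biomass} photons each; a photon-dissipation
#'     drain keeps high fixed photon fluxes feasible, so the minimal
#'     feasible photon flux is exactly
#'     \code{photons_per_biomass * demand}.}
#' }
#'
#' @param kind fixture name.
#' @param n chain length (chain only), default 3.
#' @param k number of arms (k_parallel only), default 3.
#' @param demand fixed demand flux, default 1.
#' @param photons_per_biomass photon cost per biomass unit
#'   (photon_toy), default 2.
#' @return list with \code{model}, \code{constraints} (fixing the
#'   demand), and \code{manifest}.
#' @export
buildFixtureNetwork <- function(kind = c("chain", "diamond",
                                         "equal_parallel", "k_parallel",
                                         "photon_toy"),
                                n = 3, k = 3, demand = 1,
                                photons_per_biomass = 2) {
  kind <- match.arg(kind)
  rx <- function(id, eq, cat = "metabolic", lo = NULL, hi = .BIG) {
    pe <- parseReactionEquation(eq)
    if (is.null(lo)) lo <- if (pe$reversible) -.BIG else 0
    list(id = id, stoichiometry = pe$stoichiometry, lower = lo,
         upper = hi, category = cat, genes = character(0))
  }
  defs <- switch(kind,
    chain = {
      stopifnot(n >= 2)
      mets <- paste0("M", seq_len(n - 1))
      c(list(rx("in_tx", paste("->", mets[1]), "exchange")),
        if (n > 2) lapply(seq_len(n - 2), function(i)
          rx(paste0("R", i), paste(mets[i], "->", mets[i + 1]))),
        list(rx("out_tx", paste(mets[n - 1], "->"),
                "biomass_transporter")))
    },
    diamond = list(
      rx("in_tx", "-> A", "exchange"),
      rx("R1", "A -> B"),
      rx("R2", "A -> C"),
      rx("R3", "C -> B"),
      rx("out_tx", "B ->", "biomass_transporter")),
    equal_parallel = list(
      rx("in_tx", "-> A", "exchange"),
      rx("R1", "A -> B"),
      rx("R2", "A -> B"),
      rx("out_tx", "B ->", "biomass_transporter")),
    k_parallel = c(
      list(rx("in_tx", "-> A", "exchange")),
      lapply(seq_len(k), function(i) rx(paste0("R", i), "A -> B")),
      list(rx("out_tx", "B ->", "biomass_transporter"))),
    photon_toy = list(
      rx("Photon_tx", "-> Light", "exchange"),
      rx("C_tx", "-> C", "exchange"),
      rx("SYN", paste(photons_per_biomass, "Light + C -> Bio")),
      rx("NPQ_diss", "Light ->", "exchange"),
      rx("biomass_tx", "Bio ->", "biomass_transporter")))
  drainId <- switch(kind, photon_toy = "biomass_tx", "out_tx")
  model <- .buildModel(defs,
                       annotations = list(generator = kind))
  validObject(model)
  constraints <- constraintSet(
    fixedFluxes = stats::setNames(demand, drainId),
    maintenanceFlux = 0)
  optimum <- switch(kind,
    chain = n * demand,
    diamond = 3 * demand,
    equal_parallel = 3 * demand,
    k_parallel = 3 * demand,
    photon_toy = NA_real_)
  manifest <- list(
    model_id = kind,
    counts = list(reactions = length(defs),
                  metabolites = nrow(model@metabolites)),
    expected_objective = optimum,
    feasibility_threshold = if (kind == "photon_toy")
      photons_per_biomass * demand else NA_real_,
    demand = demand)
  list(model = model, constraints = constraints, manifest = manifest)
}

#' Inject a seeded defect into a consistent model
#'
#' \code{"leak"} adds an unbalanced creation reaction for one randomly
#' chosen internal metabolite; \code{"energy_cycle"} adds a free
#' ATP-regenerating reaction (\code{ADP + Pi -> ATP + H2O} with no
#' energy source); \code{"none"} returns the model unchanged.  The defect is
#' recorded in the model's annotations.
#'
#' @param model a [MetabolicModel-class] that passes the consistency
#'   checks in balanced mode.
#' @param defect \code{"leak"}, \code{"energy_cycle"} or
#'   \code{"none"}.
#' @param seed integer seed for the leak-target choice.
#' @return the modified [MetabolicModel-class]; the annotation entry
#'   \code{defect} describes what was injected.
#' @export
makeBrokenVariant <- function(model,
                              defect = c("leak", "energy_cycle", "none"),
                              seed = 1) {
  defect <- match.arg(defect)
  if (defect == "none") return(model)
  rxns <- .modelToRxnList(model)
  if (defect == "leak") {
    internal <- model@metabolites$id[model@metabolites$compartment !=
                                       "external"]
    ## restrict to metabolites whose only consumers sit on the system
    ## boundary, so the injected creation reaction leaks exactly the
    ## seeded species and nothing downstream of it
    S <- model@stoichiometry
    cats <- model@reactions$category
    boundary <- cats %in% c("exchange", "biomass_transporter")
    lo <- model@reactions$lower; hi <- model@reactions$upper
    sinkOnly <- vapply(internal, function(met) {
      row <- as.vector(S[met, ])
      consumers <- which((row < 0 & hi > 0) | (row > 0 & lo < 0))
      all(boundary[consumers])
    }, TRUE)
    pool <- internal[sinkOnly]
    if (!length(pool)) pool <- internal
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
    target <- sample(pool, 1)
    add <- list(id = paste0("defect_creation_", target),
                stoichiometry = stats::setNames(1, target),
                lower = 0, upper = .BIG, category = "metabolic",
                genes = character(0))
    info <- list(kind = "leak", target = target)
  } else {
    need <- c("ADP", "Pi", "ATP")
    miss <- setdiff(need, metaboliteIds(model))
    if (length(miss)) stop("model lacks currency species: ",
                           paste(miss, collapse = ", "))
    ## the condensation releases water, so the loop with the ATPase
    ## discharge is mass-balanced yet thermodynamically free
    add <- list(id = "defect_free_ATP_regen",
                stoichiometry = c(ADP = -1, Pi = -1, ATP = 1, H2O = 1),
                lower = 0, upper = .BIG, category = "metabolic",
                genes = character(0))
    info <- list(kind = "energy_cycle", target = "ATP")
  }
  ann <- model@annotations
  ann$defect <- info
  m <- .buildModel(c(rxns, list(add)), composition = model@composition,
                   annotations = ann)
  validObject(m)
  m
}
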