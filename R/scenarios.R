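#' @include fba.R
NULL

#' @noRd
.modelToRxnList <- function(model) {
  rx <- model@reactions
  lapply(seq_len(nrow(rx)), function(j)
    list(id = rx$id[j],
         stoichiometry = reactionStoichiometry(model, rx$id[j]),
         lower = rx$lower[j], upper = rx$upper[j],
         category = rx$category[j],
         genes = if (nzchar(rx$genes[j]))
           strsplit(rx$genes[j], "|", fixed = TRUE)[[1]] else character(0)))
}

#' Lump RuBisCO carboxylation and oxygenation at a fixed Vc/Vo ratio
#'
#' Replaces the separate carboxylation and oxygenation reactions by a
#' single irreversible reaction whose stoichiometry is the
#' coefficient-wise sum \eqn{a \cdot \mathrm{carb} + b \cdot
#' \mathrm{oxy}} for the ratio \eqn{V_c : V_o = a : b}.  Coefficients
#' are the raw sum (not normalized by \eqn{a+b}), so one unit of
#' lumped flux performs exactly \eqn{a} carboxylations and \eqn{b}
#' oxygenations: \eqn{V_c = a v} and \eqn{V_o = b v} hold exactly.
#' All other reactions are untouched.
#'
#' @param model a [MetabolicModel-class].
#' @param carbId,oxyId ids of the carboxylation and oxygenation
#'   reactions.
#' @param ratio numeric \code{c(a, b)} with \code{a > 0}, \code{b >=
#'   0} (integer ratios such as \code{c(3, 1)} are exact).
#' @param lumpedId id of the new reaction, default
#'   \code{"RuBisCO_lumped"}.
#' @return the lumped [MetabolicModel-class].
#' @examples
#' fx <- buildCoreLeafModel()
#' m31 <- lumpRubisco(fx$model, "chl_RuBisCO_carb", "chl_RuBisCO_oxy",
#'                    c(3, 1))
#' @export
lumpRubisco <- function(model, carbId, oxyId, ratio,
                        lumpedId = "RuBisCO_lumped") {
  stopifnot(length(ratio) == 2, all(ratio >= 0))
  a <- ratio[1]; b <- ratio[2]
  if (a <= 0) stop("carboxylation part a must be positive")
  ids <- reactionIds(model)
  if (!carbId %in% ids) stop("missing reaction id: ", carbId)
  if (!oxyId %in% ids) stop("missing reaction id: ", oxyId)
  if (carbId == oxyId) stop("carbId and oxyId must differ")
  carb <- reactionStoichiometry(model, carbId)
  oxy <- reactionStoichiometry(model, oxyId)
  st <- stats::setNames(rep(0, length(union(names(carb), names(oxy)))),
                        union(names(carb), names(oxy)))
  st[names(carb)] <- st[names(carb)] + a * carb
  st[names(oxy)] <- st[names(oxy)] + b * oxy
  st <- st[st != 0]
  rxns <- .modelToRxnList(model)
  pos <- match(carbId, ids)
  keep <- !(ids %in% c(carbId, oxyId))
  lumped <- list(id = lumpedId, stoichiometry = st, lower = 0,
                 upper = .BIG, category = "metabolic",
                 genes = character(0))
  out <- c(rxns[keep & seq_along(rxns) < pos], list(lumped),
           rxns[keep & seq_along(rxns) > pos])
  m <- .buildModel(out, composition = model@composition,
                   annotations = model@annotations)
  validObject(m)
  m
}

#' Scan metabolism over RuBisCO Vc/Vo ratios
#'
#' For each ratio the carboxylation and oxygenation reactions are
#' lumped with [lumpRubisco()] and the weighted total-flux minimum
#' computed.  Points are recorded in increasing \eqn{V_c/V_o} order;
#' infeasible points keep their status and are skipped by downstream
#' correlation.
#'
#' @param model a [MetabolicModel-class] containing separate
#'   carboxylation and oxygenation reactions.
#' @param constraints a [ConstraintSet-class] (biomass composition and
#'   maintenance).
#' @param ratios list of \code{c(a, b)} ratios, e.g.
#'   \code{list(c(1,1), c(2,1), c(3,1))}.
#' @param carbId,oxyId reaction ids to lump.
#' @param weights optional objective weights.
#' @return a [ScanResult-class] with \code{parameterName "vcvo"} and
#'   parameter values \eqn{a/b}.
#' @seealso [lightScan()], [correlateScan()]
#' @export
vcvoScan <- function(model, constraints, ratios,
                     carbId = "chl_RuBisCO_carb",
                     oxyId = "chl_RuBisCO_oxy", weights = NULL) {
  if (!length(ratios)) stop("ratios must be non-empty")
  vals <- vapply(ratios, function(r) r[1] / r[2], 0)
  if (any(!is.finite(vals)))
    stop("vcvo scan requires oxygenation part b > 0 for every ratio")
  ord <- order(vals)
  if (anyDuplicated(vals)) stop("duplicate Vc/Vo ratios")
  sols <- lapply(ord, function(i) {
    lm <- lumpRubisco(model, carbId, oxyId, ratios[[i]])
    minimizeWeightedFlux(lm, constraints, weights)
  })
  new("ScanResult", parameterName = "vcvo", values = vals[ord],
      solutions = sols)
}

#' Scan metabolism over fixed photon fluxes (light scan)
#'
#' For each grid value the photon influx is fixed there, the coupling
#' \eqn{v_{cyclic} - v_{noncyclic} \le 0} (cyclic photophosphorylation
#' cannot exceed non-cyclic) is enforced, and the flux-minimizing LP
#' solved.  Grid points below the feasibility limit are recorded as
#' infeasible.
#'
#' @param model a [MetabolicModel-class].
#' @param constraints a [ConstraintSet-class].
#' @param photonGrid increasing numeric vector of photon fluxes.
#' @param photonId photon exchange reaction id.
#' @param cyclicId,noncyclicId cyclic / non-cyclic
#'   photophosphorylation reaction ids; set either to NULL to skip the
#'   coupling.
#' @param weights optional objective weights.
#' @return a [ScanResult-class] with \code{parameterName
#'   "photon_flux"}.
#' @export
lightScan <- function(model, constraints, photonGrid,
                      photonId = "Photon_tx",
                      cyclicId = "chl_LightCyc",
                      noncyclicId = "chl_LightNonCyc", weights = NULL) {
  if (any(diff(photonGrid) <= 0)) stop("photon grid must be increasing")
  if (!photonId %in% reactionIds(model))
    stop("photon influx reaction not in model: ", photonId)
  couple <- if (!is.null(cyclicId) && !is.null(noncyclicId))
    c(constraints@couplings,
      list(stats::setNames(c(1, -1), c(cyclicId, noncyclicId))))
  else constraints@couplings
  sols <- lapply(photonGrid, function(v) {
    cs <- constraintSet(
      fixedFluxes = c(constraints@fixedFluxes,
                      stats::setNames(v, photonId)),
      boundOverrides = constraints@boundOverrides,
      couplings = couple,
      maintenanceFlux = constraints@maintenanceFlux)
    minimizeWeightedFlux(model, cs, weights)
  })
  new("ScanResult", parameterName = "photon_flux",
      values = photonGrid, solutions = sols)
}

#' Minimal feasible photon flux
#'
#' Bisects for the photon flux below which no feasible solution for
#' biomass synthesis exists under the given constraints (the lower
#' limit of the light scan).  The LP must be infeasible at
#' \code{bracket[1]} and feasible at \code{bracket[2]}.
#'
#' @param model a [MetabolicModel-class].
#' @param constraints a [ConstraintSet-class].
#' @param bracket numeric \code{c(lo, hi)}.
#' @param photonId photon exchange reaction id.
#' @param cyclicId,noncyclicId optional photophosphorylation coupling
#'   as in [lightScan()].
#' @param tolerance bisection half-width, default 1e-4.
#' @param weights optional objective weights.
#' @return the threshold (a feasible photon flux within
#'   \code{tolerance} of the infeasibility boundary).
#' @export
minFeasiblePhotonFlux <- function(model, constraints, bracket,
                                  photonId = "Photon_tx",
                                  cyclicId = NULL, noncyclicId = NULL,
                                  tolerance = 1e-4, weights = NULL) {
  feasAt <- function(v) {
    s <- lightScan(model, constraints, v, photonId, cyclicId,
                   noncyclicId, weights)
    solutionStatus(scanSolutions(s)[[1]]) == "optimal"
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (lo >= hi) stop("bracket invalid: lo must be below hi")
  if (feasAt(lo)) stop("bracket invalid: feasible at lower end")
  if (!feasAt(hi)) stop("bracket invalid: infeasible at upper end")
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (feasAt(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Photophosphorylation yield table
#'
#' ATP and NADPH produced per unit flux of the lumped cyclic and
#' non-cyclic photophosphorylation reactions.  The defaults match the
#' lumped reactions used by [buildCoreLeafModel()]: non-cyclic 3 ATP +
#' 2 NADPH, cyclic 2 ATP + 0 NADPH per unit.
#'
#' @param noncyclicId,cyclicId reaction ids.
#' @param noncyclic,cyclic numeric \code{c(atp, nadph)} yields.
#' @return data.frame with columns \code{id}, \code{atp},
#'   \code{nadph}.
#' @export
photophosphorylationYields <- function(noncyclicId = "chl_LightNonCyc",
                                       cyclicId = "chl_LightCyc",
                                       noncyclic = c(3, 2),
                                       cyclic = c(2, 0)) {
  data.frame(id = c(noncyclicId, cyclicId),
             atp = c(noncyclic[1], cyclic[1]),
             nadph = c(noncyclic[2], cyclic[2]),
             stringsAsFactors = FALSE)
}

#' Quantum demand and ATP:NADPH ratio of a solution
#'
#' Quantum demand is photons consumed per net CO2 fixed,
#' \eqn{QD = v_{photon} / v_{CO_2}}, defined only for positive CO2
#' uptake.  Total ATP and NADPH production are the yield-weighted
#' photophosphorylation fluxes and their ratio is reported.
#'
#' @param solution a [FluxSolution-class].
#' @param yields yield table from [photophosphorylationYields()].
#' @param photonId,co2Id exchange reaction ids.
#' @return list with \code{quantumDemand} (NA when CO2 uptake is not
#'   positive), \code{atpTotal}, \code{nadphTotal}, \code{atpNadphRatio}
#'   (NA when NADPH production is zero).
#' @export
derivedMetrics <- function(solution, yields = photophosphorylationYields(),
                           photonId = "Photon_tx", co2Id = "CO2_tx") {
  v <- fluxes(solution)
  miss <- setdiff(c(yields$id, photonId, co2Id), names(v))
  if (length(miss)) stop("solution lacks reactions: ",
                         paste(miss, collapse = ", "))
  atp <- sum(yields$atp * v[yields$id])
  nadph <- sum(yields$nadph * v[yields$id])
  co2 <- v[[co2Id]]
  list(quantumDemand = if (co2 > 1e-9) v[[photonId]] / co2 else NA_real_,
       atpTotal = atp, nadphTotal = nadph,
       atpNadphRatio = if (abs(nadph) > 1e-12) atp / nadph else NA_real_)
}
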