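# Shared fixtures and independent oracles for the test suite.

# Tiny photosynthesis toy with an explicit maintenance ATPase:
#   2 photons -> 1 ATP; hydrolysis closes the loop.  The photon influx
#   needed to drive a maintenance demand m is exactly 2 m.
makePhotonAtpToy <- function() {
  defs <- list(
    list(id = "Photon_tx", stoichiometry = c(hv = 1), lower = 0,
         upper = 1e6, category = "exchange", genes = character(0)),
    list(id = "H2O_tx", stoichiometry = c(H2O = 1), lower = -1e6,
         upper = 1e6, category = "exchange", genes = character(0)),
    list(id = "Pi_tx", stoichiometry = c(Pi = 1), lower = -1e6,
         upper = 1e6, category = "exchange", genes = character(0)),
    list(id = "photophos",
         stoichiometry = c(hv = -2, ADP = -1, Pi = -1, ATP = 1, H2O = 1),
         lower = 0, upper = 1e6, category = "photophosphorylation",
         genes = character(0)),
    list(id = "ATPase_maintenance",
         stoichiometry = c(ATP = -1, H2O = -1, ADP = 1, Pi = 1),
         lower = 0, upper = 1e6, category = "maintenance",
         genes = character(0)),
    list(id = "ADP_seed_tx", stoichiometry = c(ADP = 1), lower = -1e6,
         upper = 1e6, category = "exchange", genes = character(0)))
  leafFBA:::.buildModel(defs)
}

# Route-enumeration oracle for the micro fixtures: the optimum of the
# unit-weight total-flux LP is demand times the cheapest route length
# (every fixture is a union of simple source->sink routes).
enumerateRouteOptimum <- function(routes, demand, weights = NULL) {
  cost <- vapply(routes, function(r) {
    sum(vapply(r, function(id)
      if (!is.null(weights) && id %in% names(weights)) weights[[id]]
      else 1, 0))
  }, 0)
  min(cost) * demand
}

# Two-pass covariance Pearson correlation, independent of stats::cor.
twoPassPearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Feasibility of a flux vector for a model (bounds + steady state).
isFeasibleFlux <- function(model, v, tol = 1e-6) {
  b <- reactionBounds(model)
  all(v >= b$lower - tol) && all(v <= b$upper + tol) &&
    steadyStateResidual(model,
      new("FluxSolution", fluxes = v, objectiveValue = 0,
          status = "optimal")) <= tol
}
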