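#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

## Sentinel used for "unconstrained" bounds: large but finite so every
## LP stays bounded after flux splitting.
.BIG <- 1e6

.CATEGORIES <- c("metabolic", "intracellular_transporter",
                 "biomass_transporter", "exchange",
                 "photophosphorylation", "maintenance")

.COMPARTMENTS <- c("cytosol", "chloroplast", "mitochondrion",
                   "peroxisome", "external")

#' MetabolicModel: a compartmentalized stoichiometric model
#'
#' Container for a steady-state metabolic network: a sparse
#' stoichiometric matrix \eqn{S} (rows are metabolites, columns are
#' reactions; negative entries are consumed, positive produced), flux
#' bounds, a reaction category (metabolic, intracellular transporter,
#' biomass transporter, exchange, photophosphorylation, maintenance),
#' optional gene associations, and optional elemental compositions of
#' the metabolites.
#'
#' Metabolite compartments follow the id prefix convention used in
#' compartmentalized leaf models: \code{chl_} chloroplast, \code{mit_}
#' mitochondrion, \code{per_} peroxisome, \code{ext_} external, no
#' prefix cytosol.  Intracellular transporter ids conventionally end in
#' \code{_tx}; for those reactions a negative flux means export toward
#' the cytosol.
#'
#' @slot reactions data.frame with columns \code{id}, \code{lower},
#'   \code{upper}, \code{category}, \code{genes} (pipe-separated).
#' @slot stoichiometry sparse \code{Matrix} (metabolites x reactions)
#'   with dimnames.
#' @slot metabolites data.frame with columns \code{id},
#'   \code{compartment}.
#' @slot composition named list mapping metabolite id to a named
#'   numeric vector of element counts (may cover only some
#'   metabolites).
#' @slot annotations free-form list.
#'
#' @seealso [readModelTable()], [buildCoreLeafModel()],
#'   [minimizeWeightedFlux()]
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(reactions = "data.frame",
                 stoichiometry = "Matrix",
                 metabolites = "data.frame",
                 composition = "list",
                 annotations = "list"))

setValidity("MetabolicModel", function(object) {
  rx <- object@reactions
  mets <- object@metabolites
  S <- object@stoichiometry
  msgs <- character(0)
  if (anyDuplicated(rx$id)) msgs <- c(msgs, "duplicate reaction ids")
  if (anyDuplicated(mets$id)) msgs <- c(msgs, "duplicate metabolite ids")
  chr0 <- function(x) if (is.null(x)) character(0) else x
  if (!identical(chr0(colnames(S)), rx$id))
    msgs <- c(msgs, "stoichiometry columns must match reaction ids")
  if (!identical(chr0(rownames(S)), mets$id))
    msgs <- c(msgs, "stoichiometry rows must match metabolite ids")
  if (any(rx$lower > rx$upper))
    msgs <- c(msgs, "lower bound exceeds upper bound")
  if (!all(rx$category %in% .CATEGORIES))
    msgs <- c(msgs, paste("unknown category:",
                          paste(setdiff(rx$category, .CATEGORIES),
                                collapse = ", ")))
  if (nrow(rx) > 0 && any(Matrix::colSums(S != 0) == 0))
    msgs <- c(msgs, "reaction with empty stoichiometry")
  if (length(msgs)) msgs else TRUE
})

#' FluxSolution: result of one flux-balance LP
#'
#' @slot fluxes named numeric vector of reaction fluxes \eqn{v}.
#' @slot objectiveValue achieved objective \eqn{Z} (weighted total
#'   flux), \code{NA} when not optimal.
#' @slot status one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}, \code{"error"}.
#'
#' @exportClass FluxSolution
setClass("FluxSolution",
  representation(fluxes = "numeric", objectiveValue = "numeric",
                 status = "character"))

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded", "error"))
    return("invalid status")
  TRUE
})

#' ConstraintSet: scenario constraints for the flux minimizer
#'
#' Bundles everything a simulation scenario imposes on top of the model:
#' fixed fluxes (biomass transporters, a fixed photon influx during a
#' light scan), bound overrides, linear coupling inequalities
#' \eqn{\sum_i a_i v_i \le 0} (used for the cyclic \eqn{\le} non-cyclic
#' photophosphorylation constraint), and the maintenance ATPase demand
#' (default 0.1 flux units).
#'
#' @slot fixedFluxes named numeric, reaction id to fixed flux value.
#' @slot boundOverrides data.frame with columns \code{id},
#'   \code{lower}, \code{upper}.
#' @slot couplings list of named numeric vectors \eqn{a}; each imposes
#'   \eqn{a \cdot v \le 0}.
#' @slot maintenanceFlux nonnegative numeric scalar.
#'
#' @seealso [constraintSet()], [applyBiomassComposition()]
#' @exportClass ConstraintSet
setClass("ConstraintSet",
  representation(fixedFluxes = "numeric", boundOverrides = "data.frame",
                 couplings = "list", maintenanceFlux = "numeric"))

setValidity("ConstraintSet", function(object) {
  if (length(object@maintenanceFlux) != 1 || object@maintenanceFlux < 0)
    return("maintenanceFlux must be a single nonnegative number")
  if (length(object@fixedFluxes) &&
      is.null(names(object@fixedFluxes)))
    return("fixedFluxes must be named by reaction id")
  TRUE
})

#' Construct a ConstraintSet
#'
#' @param fixedFluxes named numeric vector, reaction id -> fixed flux.
#' @param boundOverrides data.frame with columns \code{id},
#'   \code{lower}, \code{upper}, or \code{NULL}.
#' @param couplings list of named numeric coefficient vectors, each
#'   enforcing \code{sum(a * v) <= 0}.
#' @param maintenanceFlux maintenance ATPase demand, default 0.1.
#' @return A [ConstraintSet-class] object.
#' @examples
#' constraintSet(fixedFluxes = c(biomass_GAP_tx = 0.25))
#' @export
constraintSet <- function(fixedFluxes = numeric(0), boundOverrides = NULL,
                          couplings = list(), maintenanceFlux = 0.1) {
  if (is.null(boundOverrides))
    boundOverrides <- data.frame(id = character(0), lower = numeric(0),
                                 upper = numeric(0))
  new("ConstraintSet", fixedFluxes = fixedFluxes,
      boundOverrides = boundOverrides, couplings = couplings,
      maintenanceFlux = maintenanceFlux)
}

#' ScanResult: an ordered series of flux solutions along a parameter
#'
#' @slot parameterName \code{"vcvo"} or \code{"photon_flux"}.
#' @slot values strictly increasing numeric parameter values.
#' @slot solutions list of [FluxSolution-class], one per value
#'   (infeasible grid points keep their non-optimal status).
#'
#' @seealso [vcvoScan()], [lightScan()], [fluxMatrix()]
#' @exportClass ScanResult
setClass("ScanResult",
  representation(parameterName = "character", values = "numeric",
                 solutions = "list"))

setValidity("ScanResult", function(object) {
  if (length(object@values) != length(object@solutions))
    return("values and solutions differ in length")
  if (length(object@values) > 1 && any(diff(object@values) <= 0))
    return("parameter values must be strictly increasing")
  TRUE
})

#' ModeSummary: transporter mode signatures across an ensemble
#'
#' A mode is a distinct vector of activity signs (+, 0, -) of the
#' tracked reactions across alternative optimal solutions obtained
#' under different random enzymatic-cost weightings.
#'
#' @slot tracked ordered character vector of tracked reaction ids.
#' @slot signatures character vector of sign strings (e.g. "+0-"),
#'   one per distinct mode.
#' @slot counts integer vector parallel to \code{signatures}.
#' @slot infeasibleCount iterations whose LP failed.
#' @slot nIterations total iterations requested.
#'
#' @seealso [runEnsemble()]
#' @exportClass ModeSummary
setClass("ModeSummary",
  representation(tracked = "character", signatures = "character",
                 counts = "integer", infeasibleCount = "integer",
                 nIterations = "integer"))

setValidity("ModeSummary", function(object) {
  if (length(object@signatures) != length(object@counts))
    return("signatures and counts differ in length")
  if (sum(object@counts) + object@infeasibleCount != object@nIterations)
    return("mode counts plus infeasible count must equal nIterations")
  TRUE
})
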