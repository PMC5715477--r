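#' @include AllClasses.R model-methods.R
NULL

## Zero threshold applied to reported fluxes; kept three orders below
## the mode-classification tolerance so transporter signs never flicker.
.FLUX_ZERO <- 1e-9

## Assemble effective per-reaction bounds from model bounds, overrides,
## maintenance demand and fixed fluxes (in that order of application).
#' @noRd
.effectiveBounds <- function(model, constraints) {
  rx <- model@reactions
  lo <- stats::setNames(rx$lower, rx$id)
  hi <- stats::setNames(rx$upper, rx$id)
  maint <- rx$id[rx$category == "maintenance"]
  for (id in maint) {
    lo[id] <- constraints@maintenanceFlux
    hi[id] <- constraints@maintenanceFlux
  }
  ## overrides come after the maintenance demand so a scenario (or the
  ## consistency probes) can deliberately release it
  bo <- constraints@boundOverrides
  if (nrow(bo)) {
    bad <- setdiff(bo$id, rx$id)
    if (length(bad)) stop("bound override for unknown reaction: ",
                          paste(bad, collapse = ", "))
    lo[bo$id] <- bo$lower
    hi[bo$id] <- bo$upper
  }
  ff <- constraints@fixedFluxes
  if (length(ff)) {
    bad <- setdiff(names(ff), rx$id)
    if (length(bad)) stop("fixed flux for unknown reaction: ",
                          paste(bad, collapse = ", "))
    out <- names(ff)[ff < lo[names(ff)] - 1e-9 | ff > hi[names(ff)] + 1e-9]
    if (length(out))
      stop("fixed flux outside bounds for: ", paste(out, collapse = ", "))
    lo[names(ff)] <- ff
    hi[names(ff)] <- ff
  }
  list(lower = lo, upper = hi)
}

## Build the split-variable LP:
##   variables [p_1..p_R, q_1..q_R, slacks...],  v = p - q
##   rows: S v = 0 over internal metabolites; one row per coupling
##   a.v + s = 0 with slack s >= 0; optional extra budget row.
#' @noRd
.splitProblem <- function(model, constraints, weights,
                          budget = NULL) {
  rx <- model@reactions
  R <- nrow(rx)
  bb <- .effectiveBounds(model, constraints)
  lo <- bb$lower; hi <- bb$upper
  lbp <- pmax(lo, 0); ubp <- pmax(hi, 0)
  lbq <- pmax(-hi, 0); ubq <- pmax(-lo, 0)

  internal <- model@metabolites$compartment != "external"
  S <- as.matrix(model@stoichiometry[internal, , drop = FALSE])
  m <- nrow(S)

  nSlack <- length(constraints@couplings) + (!is.null(budget))
  n <- 2L * R + nSlack
  A <- matrix(0, m + nSlack, n)
  if (m > 0) {
    A[seq_len(m), seq_len(R)] <- S
    A[seq_len(m), R + seq_len(R)] <- -S
  }
  rhs <- rep(0, m + nSlack)
  row <- m
  for (cp in constraints@couplings) {
    row <- row + 1L
    idx <- match(names(cp), rx$id)
    if (anyNA(idx)) stop("coupling references unknown reaction: ",
                         paste(names(cp)[is.na(idx)], collapse = ", "))
    A[row, idx] <- cp
    A[row, R + idx] <- -cp
    A[row, 2L * R + (row - m)] <- 1   # slack: a.v + s = 0, s >= 0
  }
  if (!is.null(budget)) {
    row <- row + 1L
    A[row, seq_len(2L * R)] <- c(weights, weights)
    A[row, n] <- 1
    rhs[row] <- budget
  }
  lb <- c(lbp, lbq, rep(0, nSlack))
  ub <- c(ubp, ubq, rep(Inf, nSlack))
  list(A = A, rhs = rhs, lb = lb, ub = ub, R = R, n = n)
}

#' @noRd
.resolveWeights <- function(model, weights) {
  rx <- model@reactions
  w <- stats::setNames(rep(1, nrow(rx)), rx$id)
  if (!is.null(weights)) {
    if (is.null(names(weights)) && length(weights) == nrow(rx)) {
      w[] <- weights
    } else {
      bad <- setdiff(names(weights), rx$id)
      if (length(bad)) stop("weight for unknown reaction: ",
                            paste(bad, collapse = ", "))
      w[names(weights)] <- weights
    }
  }
  if (any(w < 0)) stop("objective weights must be nonnegative")
  w
}

#' @noRd
.asFluxSolution <- function(model, lpres, w) {
  rx <- model@reactions
  R <- nrow(rx)
  if (lpres$status != "optimal")
    return(new("FluxSolution",
               fluxes = stats::setNames(rep(NA_real_, R), rx$id),
               objectiveValue = NA_real_, status = lpres$status))
  v <- lpres$x[seq_len(R)] - lpres$x[R + seq_len(R)]
  v[abs(v) < .FLUX_ZERO] <- 0
  new("FluxSolution", fluxes = stats::setNames(v, rx$id),
      objectiveValue = sum(w * abs(v)), status = "optimal")
}

#' Weighted L1-minimizing flux balance analysis
#'
#' Solves the core flux-balance program
#' \deqn{\min_v \sum_i w_i |v_i| \quad \mathrm{s.t.}\quad S v = 0,\;
#'   LB \le v \le UB}
#' with the scenario constraints applied: fixed fluxes (biomass
#' transporters, photon influx), bound overrides, linear couplings
#' \eqn{a \cdot v \le 0}, and the maintenance ATPase fixed at the
#' maintenance demand.  The absolute values are linearized exactly by
#' splitting every flux into nonnegative forward and backward parts
#' \eqn{v = v^+ - v^-}.
#'
#' Flux-minimizing LPs are typically degenerate: when alternative
#' optima exist, one optimal vertex is returned deterministically
#' (fixed variable order, deterministic pivoting).  Use [runFVA()] to
#' certify which fluxes are unique across the optimal set.
#'
#' @param model a [MetabolicModel-class].
#' @param constraints a [ConstraintSet-class]; default has no fixed
#'   fluxes and maintenance 0.1.
#' @param weights optional nonnegative objective weights \eqn{w}:
#'   either a named vector overriding the default weight 1 per
#'   reaction, or a full vector in reaction order.
#' @return a [FluxSolution-class]; reported fluxes below 1e-9 in
#'   magnitude are snapped to zero.
#' @examples
#' fx <- buildFixtureNetwork("chain", n = 3, demand = 1)
#' sol <- minimizeWeightedFlux(fx$model, fx$constraints)
#' objectiveValue(sol)   # 3: one unit through each of 3 reactions
#' @export
minimizeWeightedFlux <- function(model, constraints = constraintSet(),
                                 weights = NULL) {
  w <- .resolveWeights(model, weights)
  prob <- .splitProblem(model, constraints, w)
  obj <- c(w, w, rep(0, prob$n - 2L * prob$R))
  res <- .lpSolve(obj, prob$A, prob$rhs, prob$lb, prob$ub)
  .asFluxSolution(model, res, w)
}

#' Fix biomass-transporter fluxes in experimentally defined proportions
#'
#' Builds the standard simulation [ConstraintSet-class]: each listed
#' biomass transporter carries exactly its stated flux so biomass
#' components are produced in fixed proportion, and the maintenance
#' ATPase carries the maintenance demand.
#'
#' @param model a [MetabolicModel-class].
#' @param composition named numeric vector, biomass transporter id ->
#'   nonnegative flux.
#' @param maintenanceFlux maintenance demand, default 0.1 flux units.
#' @return a [ConstraintSet-class].
#' @export
applyBiomassComposition <- function(model, composition,
                                    maintenanceFlux = 0.1) {
  if (is.null(composition)) composition <- numeric(0)
  if (length(composition)) {
    cats <- reactionCategories(model)
    bad <- setdiff(names(composition), names(cats))
    if (length(bad)) stop("unknown transporter id: ",
                          paste(bad, collapse = ", "))
    notBm <- names(composition)[cats[names(composition)] !=
                                  "biomass_transporter"]
    if (length(notBm)) stop("not a biomass transporter: ",
                            paste(notBm, collapse = ", "))
    if (any(composition < 0)) stop("biomass fluxes must be nonnegative")
  }
  constraintSet(fixedFluxes = composition,
                maintenanceFlux = maintenanceFlux)
}

#' Steady-state residual of a solution
#'
#' Convenience check of the conservation invariant
#' \eqn{\|S v\|_\infty} over internal metabolites.
#'
#' @param model a [MetabolicModel-class].
#' @param solution a [FluxSolution-class].
#' @return max absolute residual (numeric scalar).
#' @export
steadyStateResidual <- function(model, solution) {
  internal <- model@metabolites$compartment != "external"
  S <- model@stoichiometry[internal, , drop = FALSE]
  v <- fluxes(solution)[reactionIds(model)]
  max(abs(as.vector(S %*% v)))
}
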