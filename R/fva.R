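#' @include fba.R
NULL

#' Flux variability analysis at the fixed optimum
#'
#' First solves the weighted total-flux minimization, then for each
#' reaction maximizes and minimizes its flux subject to all original
#' constraints plus the optimality side-constraint
#' \eqn{\sum_i w_i |v_i| \le Z^* (1 + \mathrm{tol}) + \epsilon},
#' where \eqn{Z^*} is the primary optimum, \code{tol} is
#' \code{optimumTolerance} (default 0, strict optimality) and
#' \eqn{\epsilon} is a small absolute slack (default 1e-7) that keeps
#' the optimal face numerically nonempty.
#'
#' @param model a [MetabolicModel-class].
#' @param constraints a [ConstraintSet-class].
#' @param weights optional objective weights as in
#'   [minimizeWeightedFlux()].
#' @param reactions reaction ids to analyze (default all).
#' @param optimumTolerance relative slack on the optimum; \code{Inf}
#'   reduces FVA to plain bound-constrained flux min/max.
#' @param absSlack absolute slack added to the budget.
#' @return data.frame with columns \code{id}, \code{fbaValue},
#'   \code{fvaMin}, \code{fvaMax}; per-reaction LP failures yield NA
#'   rows rather than an error.  The sandwich property
#'   \code{fvaMin <= fbaValue <= fvaMax} holds within solver tolerance.
#' @examples
#' fx <- buildFixtureNetwork("equal_parallel", demand = 1)
#' rng <- runFVA(fx$model, fx$constraints)
#' subset(rng, id %in% c("R1", "R2"))   # both arms range over [0, 1]
#' @export
runFVA <- function(model, constraints = constraintSet(), weights = NULL,
                   reactions = NULL, optimumTolerance = 0,
                   absSlack = 1e-7) {
  w <- .resolveWeights(model, weights)
  base <- minimizeWeightedFlux(model, constraints, weights)
  if (solutionStatus(base) != "optimal")
    stop("primary optimization not optimal: ", solutionStatus(base))
  zstar <- objectiveValue(base)
  ids <- if (is.null(reactions)) reactionIds(model) else reactions
  bad <- setdiff(ids, reactionIds(model))
  if (length(bad)) stop("unknown reaction id: ", paste(bad, collapse = ", "))

  budget <- if (is.finite(optimumTolerance))
    zstar * (1 + optimumTolerance) + absSlack else NULL
  prob <- .splitProblem(model, constraints, w, budget = budget)
  R <- prob$R
  allIds <- reactionIds(model)
  fba <- fluxes(base)

  one <- function(id, sense) {
    j <- match(id, allIds)
    obj <- rep(0, prob$n)
    obj[j] <- sense
    obj[R + j] <- -sense
    res <- .lpSolve(obj, prob$A, prob$rhs, prob$lb, prob$ub)
    if (res$status != "optimal") return(NA_real_)
    v <- res$x[j] - res$x[R + j]
    if (abs(v) < .FLUX_ZERO) 0 else v
  }
  fvaMin <- vapply(ids, function(id) one(id, +1), 0)
  fvaMax <- vapply(ids, function(id) one(id, -1), 0)
  out <- data.frame(id = ids, fbaValue = unname(fba[ids]),
                    fvaMin = unname(fvaMin), fvaMax = unname(fvaMax),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify FVA flux ranges
#'
#' Deterministic classification of each reaction's allowable flux
#' range at the optimum, with \eqn{|x| <} \code{tolerance} treated as
#' zero, applied in this precedence order:
#' \describe{
#'   \item{zero}{\code{min = max = 0}: never active at the optimum.}
#'   \item{essential_fixed}{\code{min = max = fba}, nonzero: uniquely
#'     determined, essentially required for biomass synthesis.}
#'   \item{reversible_bidirectional}{\code{min < 0 < max}: can operate
#'     in either direction.}
#'   \item{essential_lower_bounded}{the whole range lies strictly on
#'     one side of zero (\code{min > 0} or \code{max < 0}) with
#'     \code{min < max}: flux is required, magnitude flexible.}
#'   \item{alternate_route}{\code{min = 0 <= fba <= max}: the reaction
#'     is dispensable because alternate metabolic routes exist.}
#' }
#'
#' @param ranges data.frame from [runFVA()].
#' @param tolerance dead-zone half width, default 1e-6.
#' @return the input data.frame with an added \code{class} column.
#' @export
classifyFluxRanges <- function(ranges, tolerance = 1e-6) {
  cls <- vapply(seq_len(nrow(ranges)), function(i) {
    mn <- ranges$fvaMin[i]; mx <- ranges$fvaMax[i]
    if (is.na(mn) || is.na(mx)) return(NA_character_)
    z <- function(x) abs(x) <= tolerance
    if (z(mn) && z(mx)) return("zero")
    if (mx - mn <= tolerance) return("essential_fixed")
    if (mn < -tolerance && mx > tolerance)
      return("reversible_bidirectional")
    if (mn > tolerance || mx < -tolerance)
      return("essential_lower_bounded")
    "alternate_route"
  }, "")
  ranges$class <- cls
  ranges
}
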