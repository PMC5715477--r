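#' @include fba.R
NULL

## Closed-system copy: all exchange and biomass-transporter bounds set
## to zero and the maintenance demand released (a fixed maintenance
## drain would mask leaks by forcing infeasibility or hiding capacity).
#' @noRd
.closedConstraints <- function(model, freeIds = character(0)) {
  rx <- model@reactions
  closeIds <- rx$id[rx$category %in% c("exchange", "biomass_transporter")]
  closeIds <- setdiff(closeIds, freeIds)
  bo <- data.frame(id = closeIds, lower = 0, upper = 0,
                   stringsAsFactors = FALSE)
  if (length(freeIds))
    bo <- rbind(bo, data.frame(id = freeIds, lower = 0, upper = 1000,
                               stringsAsFactors = FALSE))
  constraintSet(boundOverrides = bo, maintenanceFlux = 0)
}

## Maximize one probe column added to the closed system.  Returns the
## optimum (capped at `cap`) or NA on solver failure.
#' @noRd
.maxProbe <- function(model, constraints, probe, cap = 1000) {
  w <- .resolveWeights(model, NULL)
  prob <- .splitProblem(model, constraints, w)
  internal <- which(model@metabolites$compartment != "external")
  metIds <- model@metabolites$id[internal]
  col <- rep(0, nrow(prob$A))
  idx <- match(names(probe), metIds)
  if (anyNA(idx)) stop("probe references unknown metabolite: ",
                       paste(names(probe)[is.na(idx)], collapse = ", "))
  col[idx] <- probe
  A <- cbind(prob$A, col)
  n <- ncol(A)
  res <- .lpSolve(c(rep(0, prob$n), -1), A, prob$rhs,
                  c(prob$lb, 0), c(prob$ub, cap))
  if (res$status != "optimal") return(NA_real_)
  res$x[n]
}

#' Detect leaking metabolites in a closed system
#'
#' A stoichiometrically consistent model cannot produce any internal
#' metabolite from nothing.  With every exchange and biomass
#' transporter closed and the maintenance demand released, a temporary
#' drain is added for each internal metabolite in turn and its flux
#' maximized; metabolites whose drain can exceed \code{tolerance} are
#' reported as leaks (mass created by an unbalanced or miswired
#' reaction).
#'
#' @param model a [MetabolicModel-class].
#' @param tolerance leak flux threshold, default 1e-6.
#' @param metabolites subset of metabolite ids to probe (default all
#'   internal).
#' @return object of class \code{LeakReport}: list with
#'   \code{leakingMetabolites} (character) and \code{maxLeakFlux}
#'   (named numeric; NA for per-metabolite LP failures, which are
#'   reported rather than fatal).
#' @seealso [detectEnergyCycle()], [elementalBalanceAudit()]
#' @export
findLeaks <- function(model, tolerance = 1e-6, metabolites = NULL) {
  closed <- .closedConstraints(model)
  internal <- model@metabolites$id[model@metabolites$compartment !=
                                     "external"]
  ids <- if (is.null(metabolites)) internal else
    intersect(metabolites, internal)
  mx <- vapply(ids, function(met)
    .maxProbe(model, closed, stats::setNames(-1, met)), 0)
  leaking <- ids[!is.na(mx) & mx > tolerance]
  out <- list(leakingMetabolites = leaking,
              maxLeakFlux = mx[!is.na(mx) & mx > tolerance])
  class(out) <- "LeakReport"
  out
}

#' @export
print.LeakReport <- function(x, ...) {
  if (!length(x$leakingMetabolites)) {
    cat("No leaking metabolites detected\n")
  } else {
    cat(length(x$leakingMetabolites), "leaking metabolite(s):\n")
    for (m in x$leakingMetabolites)
      cat(sprintf("  %-20s max closed-system production %g\n",
                  m, x$maxLeakFlux[[m]]))
  }
  invisible(x)
}

#' Detect an energy-generating cycle
#'
#' A thermodynamically impossible model can regenerate a currency
#' metabolite (typically ATP) with all exchanges closed.  The check
#' maximizes the flux of a currency discharge reaction (e.g.
#' \code{ATP + H2O -> ADP + Pi}) in the closed system; any positive
#' optimum means some internal loop recharges the currency for free.
#'
#' @param model a [MetabolicModel-class].
#' @param discharge either the id of an existing discharge reaction
#'   (default: the model's maintenance reaction), or a named numeric
#'   stoichiometry (e.g. \code{c(ATP = -1, H2O = -1, ADP = 1, Pi = 1)})
#'   from which a temporary discharge reaction is synthesized.
#' @param tolerance cycle flux threshold, default 1e-6.
#' @return object of class \code{EnergyCycleReport}: list with
#'   \code{dischargeId}, \code{maxClosedDemand}, \code{hasCycle}.
#' @export
detectEnergyCycle <- function(model, discharge = NULL, tolerance = 1e-6) {
  rx <- model@reactions
  if (is.null(discharge)) {
    discharge <- rx$id[rx$category == "maintenance"][1]
    if (is.na(discharge))
      stop("no maintenance reaction found; supply `discharge`")
  }
  if (is.character(discharge)) {
    if (!discharge %in% rx$id)
      stop("unknown discharge reaction: ", discharge)
    closed <- .closedConstraints(model, freeIds = discharge)
    w <- .resolveWeights(model, NULL)
    ## maximize the discharge flux itself
    prob <- .splitProblem(model, closed, w)
    j <- match(discharge, rx$id)
    obj <- rep(0, prob$n)
    obj[j] <- -1; obj[prob$R + j] <- 1
    ub <- prob$ub
    ub[j] <- min(ub[j], 1000)
    res <- .lpSolve(obj, prob$A, prob$rhs, prob$lb, ub)
    mx <- if (res$status == "optimal")
      res$x[j] - res$x[prob$R + j] else NA_real_
    dischargeId <- discharge
  } else {
    if (is.null(names(discharge)))
      stop("discharge stoichiometry must be named by metabolite id")
    miss <- setdiff(names(discharge), metaboliteIds(model))
    if (length(miss)) stop("currency species absent from model: ",
                           paste(miss, collapse = ", "))
    closed <- .closedConstraints(model)
    mx <- .maxProbe(model, closed, discharge)
    dischargeId <- "<synthesized discharge>"
  }
  out <- list(dischargeId = dischargeId, maxClosedDemand = mx,
              hasCycle = !is.na(mx) && mx > tolerance)
  class(out) <- "EnergyCycleReport"
  out
}

#' @export
print.EnergyCycleReport <- function(x, ...) {
  cat("Energy cycle check via", x$dischargeId, "-",
      if (isTRUE(x$hasCycle)) sprintf("CYCLE (closed demand %g)",
                                      x$maxClosedDemand)
      else "clean", "\n")
  invisible(x)
}

#' Audit elemental balance of the reactions
#'
#' For every reaction whose participating metabolites all carry an
#' elemental composition, checks that
#' \eqn{\sum_i c_i \cdot \mathrm{composition}_i = 0} for every element.
#' Reactions with any unannotated species are skipped, as are exchange
#' and biomass transporters (they cross the system boundary by
#' design).
#'
#' @param model a [MetabolicModel-class].
#' @param tolerance per-element imbalance threshold.
#' @return character vector of unbalanced reaction ids.
#' @export
elementalBalanceAudit <- function(model, tolerance = 1e-6) {
  comp <- model@composition
  rx <- model@reactions
  check <- rx$category %in% c("metabolic", "intracellular_transporter",
                              "photophosphorylation", "maintenance")
  bad <- character(0)
  for (j in which(check)) {
    st <- reactionStoichiometry(model, rx$id[j])
    if (!all(names(st) %in% names(comp))) next
    tot <- numeric(0)
    for (k in seq_along(st)) {
      cc <- comp[[names(st)[k]]]
      for (el in names(cc))
        tot[el] <- (if (is.na(tot[el])) 0 else tot[el]) + st[k] * cc[el]
    }
    if (length(tot) && any(abs(tot) > tolerance))
      bad <- c(bad, rx$id[j])
  }
  bad
}
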